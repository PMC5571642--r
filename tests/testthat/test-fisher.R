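test_that("polynomial covariance approximation reproduces hand-computed values", {
  expect_identical(cov_approx(0), 0)
  # pure finite-sample term at rho = 0: -c1/N
  expect_equal(cov_approx(0, N = 1000), -3.9081 / 1000, tolerance = 1e-12)
  # polynomial evaluated at rho = 0.5 by independent arithmetic:
  # sum_l c_l * 0.25^l
  expect_equal(cov_approx(0.5), 0.980132, tolerance = 1e-6)
  # rho = 1: the plain sum of the coefficients
  expect_equal(cov_approx(1), sum(fisher_cov_constants), tolerance = 1e-12)
  expect_equal(cov_approx(1), 3.9979, tolerance = 1e-12)
  # vectorized and even in rho
  expect_equal(cov_approx(c(-0.3, 0.3)), rep(cov_approx(0.3), 2))
  expect_error(cov_approx(1.2), "rho")
  expect_error(cov_approx(0.5, N = 1), "N")
})

test_that("coefficient sum approaches the rho -> 1 limit Var(chi^2_2) = 4", {
  expect_lte(abs(sum(fisher_cov_constants) - 4), 0.01)
})

test_that("quadrature oracle is internally converged and matches known limits", {
  expect_equal(exact_cov_oracle(0), 0, tolerance = 1e-6)
  # doubling the rule leaves the value unchanged far below the 1e-6 budget
  expect_lt(abs(exact_cov_oracle(0.5) - exact_cov_oracle(0.5, nodes = 400L)),
            1e-9)
  expect_lt(abs(exact_cov_oracle(0.85) -
                  exact_cov_oracle(0.85, nodes = 400L, upper = 11)), 1e-9)
  # near-degenerate correlation: -2 log p is chi^2_2, so the limit is 4
  expect_equal(exact_cov_oracle(0.999), 4, tolerance = 0.01)
  # approximation agrees closely at moderate correlation
  expect_lt(abs(exact_cov_oracle(0.5) - cov_approx(0.5)), 1e-4)
  expect_error(exact_cov_oracle(1), "rho")
})

test_that("gamma moment matching handles the classic closed-form cases", {
  # independent traits: Fisher's chi^2_{2R}
  g4 <- gamma_moments(diag(4))
  expect_equal(g4$k, 4, tolerance = 1e-12)
  expect_equal(g4$theta, 2, tolerance = 1e-12)
  # single trait: -2 log p is chi^2_2 = Gamma(1, 2) regardless of N
  g1 <- gamma_moments(matrix(1), N = 50)
  expect_equal(g1$k, 1, tolerance = 1e-12)
  expect_equal(g1$theta, 2, tolerance = 1e-12)
  # fully duplicated pair: V = 8 + 2 * 3.9979 (ordered-pair sum), near
  # Gamma(1, 4), the distribution of 2 * chi^2_2
  g2 <- gamma_moments(matrix(c(1, 1, 1, 1), 2), N = Inf)
  expect_equal(g2$theta, 3.99895, tolerance = 1e-5)
  expect_equal(g2$k, 1.000263, tolerance = 1e-5)
  # mean constraint holds always
  expect_equal(g2$k * g2$theta, 4, tolerance = 1e-12)
})

test_that("gamma calibration rejects malformed correlation matrices", {
  bad <- matrix(c(1, 0.5, 0.2, 1), 2)
  expect_error(gamma_moments(bad), "symmetric")
  expect_error(gamma_moments(exch(2, 0.3) * 2), "diagonal")
})

test_that("implied Fisher variance is non-decreasing in each |rho|", {
  rhos <- seq(0, 0.99, by = 0.03)
  V <- vapply(rhos, function(r) {
    g <- gamma_moments(exch(4, r), N = 1000)
    g$k * g$theta^2
  }, numeric(1))
  expect_true(all(diff(V) >= 0))
})

test_that("Fisher statistic is exact in log space", {
  expect_equal(fisher_stat(c(1, 1, 1, 1)), 0)
  expect_equal(fisher_stat(c(0.05, 0.05)), 11.98293, tolerance = 1e-4)
  # 1e-300 without underflow, via either route
  expect_equal(fisher_stat(1e-300), 1381.55, tolerance = 0.01)
  expect_equal(fisher_stat(log_p = -690.7755), 1381.551, tolerance = 1e-3)
  expect_error(fisher_stat(c(0.5, 0)), "0, 1")
  expect_error(fisher_stat(c(0.5, 1.2)), "0, 1")
  expect_error(fisher_stat(log_p = 0.1), "<= 0")
})

test_that("multivariate p-value behaves as a survival function", {
  gn <- gamma_moments(diag(4))
  expect_equal(multivariate_p(0, gn), 1)
  # chi^2_8 upper 5% point from the independent chi-square routine
  expect_equal(multivariate_p(qchisq(0.95, df = 8), gn), 0.05,
               tolerance = 1e-3)
  xs <- c(0.5, 2, 7, 19, 44)
  expect_true(all(diff(multivariate_p(xs, gn)) < 0))
  expect_error(multivariate_p(-1, gn), "non-negative")
  # log-scale output for deep tails
  expect_equal(multivariate_p(200, gn, log.p = TRUE),
               pchisq(200, 8, lower.tail = FALSE, log.p = TRUE),
               tolerance = 1e-9)
})

test_that("with zero correlations the gamma null is exactly chi-square 2R", {
  for (R in c(1L, 2L, 4L, 8L)) {
    gn <- gamma_moments(diag(R))
    for (xi in c(1, 5, 10, 20, 50)) {
      expect_equal(multivariate_p(xi, gn),
                   pchisq(xi, df = 2 * R, lower.tail = FALSE),
                   tolerance = 1e-12)
    }
  }
})

test_that("combining a p-value matrix matches the scalar path", {
  set.seed(1)
  pm <- matrix(runif(12), 4, 3)
  gn <- gamma_moments(exch(3, 0.3), N = 500)
  out <- combine_pvalues(log(pm), gn)
  expect_equal(out$xi, apply(pm, 1, fisher_stat))
  expect_equal(out$p, multivariate_p(apply(pm, 1, fisher_stat), gn))
  expect_error(combine_pvalues(log(pm), gamma_moments(diag(2))), "trait count")
})
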