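test_that("with lambda = 0 the plug-in Wald test reduces to least squares", {
  g <- tiny_cohort("non-admixed-independent", S = 300, n = 150, seed = 401)
  set.seed(402)
  y <- rnorm(150)
  x <- cbind(cov1 = rnorm(150))
  grm <- compute_grm(g)
  fit <- fit_null(y, covariates = x, grm = grm, lambda = 0)
  snp <- g$dosages[, 7]
  w <- snp_wald(fit, snp)
  ols <- lm(y ~ x + snp)
  expect_equal(w$beta, unname(coef(ols)["snp"]), tolerance = 1e-8)
  # with V = sigma^2 I the standard error is sigma_hat / ||residualized g||,
  # with sigma_hat^2 the null-model REML estimate
  gt <- resid(lm(snp ~ x))
  expect_equal(w$se, sqrt(fit$sigma_e2 / sum(gt^2)), tolerance = 1e-8)
})

test_that("a response inside the covariate span collapses to zero residuals", {
  g <- tiny_cohort("non-admixed-independent", S = 300, n = 150, seed = 401)
  grm <- compute_grm(g)
  set.seed(403)
  x <- cbind(a = rnorm(150), b = runif(150))
  y <- 2 + 3 * x[, 1] - x[, 2]
  fit <- fit_null(y, covariates = x, grm = grm)
  expect_lt(max(abs(fit$residuals)), 1e-6)
  expect_lt(fit$sigma_e2, 1e-8 * var(y))
})

test_that("the returned lambda dominates the REML grid", {
  g <- tiny_cohort("non-admixed-related", S = 400, n = 200, seed = 404)
  grm <- compute_grm(g)
  eig <- pleioscan:::grm_eigen(grm)
  set.seed(405)
  d <- pmax(eig$values, 0)
  y <- eig$vectors %*% (sqrt(0.6 * d) * rnorm(200)) + rnorm(200, sd = sqrt(0.4))
  fit <- fit_null(as.numeric(y), grm = grm, eig = eig)
  expect_gte(fit$reml_loglik, max(fit$grid_logliks) - 1e-8)
  # residual identity: y = Xb + blup + residuals
  recon <- fit$fixed_effects[1] + fit$blup + fit$residuals
  expect_equal(as.numeric(y), recon, tolerance = 1e-8)
})

test_that("heritability-free data pushes lambda to the boundary", {
  g <- tiny_cohort("non-admixed-independent", S = 400, n = 200, seed = 406)
  grm <- compute_grm(g)
  set.seed(407)
  y <- rnorm(200, sd = 2)
  fit <- fit_null(y, grm = grm)
  expect_lt(fit$sigma_g2 / fit$sigma_e2, 0.15)
  expect_equal(fit$sigma_g2 + fit$sigma_e2, var(y), tolerance = 0.15 * var(y))
})

test_that("degenerate inputs are rejected", {
  g <- tiny_cohort("non-admixed-independent", S = 300, n = 150, seed = 401)
  grm <- compute_grm(g)
  set.seed(408)
  y <- rnorm(150)
  expect_error(fit_null(c(y[-1], NA), grm = grm), "finite")
  dup <- cbind(a = y * 0 + 1)              # constant column clashes with intercept
  expect_error(fit_null(y, covariates = dup, grm = grm), "rank")
  fit <- fit_null(y, grm = grm)
  expect_error(snp_wald(fit, rep(1, 150)), "monomorphic")
  expect_error(snp_wald(fit, y[-1]), "length")
})

test_that("the Wald scan is deterministic and order-independent", {
  g <- tiny_cohort("non-admixed-related", S = 300, n = 160, seed = 409)
  grm <- compute_grm(g)
  ph <- simulate_phenotypes(g, R = 1, e = 0.3, rho = 0, seed = 410)
  fit <- fit_null(ph$values[, 1], grm = grm)
  s1 <- snp_wald_scan(fit, g)
  s2 <- snp_wald_scan(fit, g)
  expect_identical(s1, s2)
  perm <- sample(ncol(g$dosages))
  sp <- snp_wald_scan(fit, g$dosages[, perm])
  expect_equal(sp$chi2, s1$chi2[perm], tolerance = 1e-10)
})

test_that("residual correlations track the trait correlation structure", {
  g <- tiny_cohort("non-admixed-independent", S = 300, n = 1000, seed = 411)
  grm <- compute_grm(g)
  eig <- pleioscan:::grm_eigen(grm)
  ph <- simulate_phenotypes(g, R = 2, e = 0, rho = 0.5, seed = 412)
  fits <- lapply(1:2, function(r)
    fit_null(ph$values[, r], grm = grm, eig = eig))
  rh <- estimate_rho(fits)
  expect_equal(dim(rh), c(2L, 2L))
  expect_equal(diag(rh), c(1, 1))
  expect_equal(rh[1, 2], 0.5, tolerance = 0.06)
  # single trait degenerates to the 1x1 identity
  expect_equal(estimate_rho(fits[1]), matrix(1), ignore_attr = TRUE)
  expect_error(naive_rho(cbind(a = rep(1, 10), b = rnorm(10))), "zero-variance")
})

test_that("plug-in and per-SNP-refit tests agree in rejection decisions", {
  g <- tiny_cohort("non-admixed-related", S = 400, n = 400, seed = 413)
  grm <- compute_grm(g)
  eig <- pleioscan:::grm_eigen(grm)
  d <- pmax(eig$values, 0)
  set.seed(414)
  y <- as.numeric(eig$vectors %*% (sqrt(0.5 * d) * rnorm(400))) +
    rnorm(400, sd = sqrt(0.5))
  fit0 <- fit_null(y, grm = grm, eig = eig)
  plug <- snp_wald_scan(fit0, g)
  agree <- vapply(seq_len(400), function(s) {
    gs <- g$dosages[, s]
    lam <- fit_null(y, covariates = cbind(snp = gs), grm = grm, eig = eig)$lambda
    exact <- snp_wald(fit_null(y, grm = grm, eig = eig, lambda = lam), gs)
    (exact$p < 0.05) == (plug$p[s] < 0.05)
  }, logical(1))
  expect_gte(mean(agree), 0.95)
})
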