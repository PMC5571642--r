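test_that("identical genotype rows give identical GRM entries", {
  set.seed(301)
  dos <- matrix(rbinom(4 * 200, 2, runif(200, 0.2, 0.8)), 4, 200, byrow = TRUE)
  dos[2, ] <- dos[1, ]
  K <- compute_grm(genotype_data(dos))$K
  expect_equal(K[1, 2], K[1, 1], tolerance = 1e-12)
  expect_equal(K[1, 2], K[2, 2], tolerance = 1e-12)
})

test_that("GRM is invariant to SNP order and allele relabeling", {
  g <- tiny_cohort("non-admixed-independent", S = 300, n = 80, seed = 302)
  K <- compute_grm(g)$K
  # permute SNPs
  perm <- sample(ncol(g$dosages))
  gp <- genotype_data(g$dosages[, perm], subject_ids = g$subject_ids)
  expect_equal(compute_grm(gp)$K, K, tolerance = 1e-12, ignore_attr = TRUE)
  # flip the counted allele at a random half of the SNPs: g -> 2 - g
  flip <- seq_len(150)
  dos <- g$dosages
  dos[, flip] <- 2L - dos[, flip]
  gf <- genotype_data(dos, subject_ids = g$subject_ids)
  expect_equal(compute_grm(gf)$K, K, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("GRM is positive semi-definite up to numerical tolerance", {
  g <- tiny_cohort("admixed-related", S = 400, n = 120, seed = 303)
  ev <- eigen(compute_grm(g)$K, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(ev))
})

test_that("GRM moments match theory for unrelated and sib samples", {
  g <- simulate_cohort("non-admixed-independent", S = 5000, seed = 304,
                       n_subjects = 400)
  K <- compute_grm(g)$K
  expect_lt(abs(mean(K[upper.tri(K)])), 0.01)
  expect_lt(abs(mean(diag(K)) - 1), 0.05)
  grel <- simulate_cohort("non-admixed-related", S = 2000, seed = 305,
                          n_subjects = 400)
  Kr <- compute_grm(grel)$K
  fam <- grel$pedigree$fid
  sib <- outer(fam, fam, "==") & upper.tri(Kr)
  expect_lt(abs(mean(Kr[sib]) - 0.5), 0.05)
})

test_that("monomorphic-only input is rejected, missing dosages are imputed", {
  dos <- matrix(2L, 5, 10)
  expect_error(compute_grm(genotype_data(dos)), "usable")
  g <- tiny_cohort("non-admixed-independent", S = 200, n = 60, seed = 306)
  dos2 <- g$dosages
  dos2[sample(length(dos2), 100)] <- NA
  gm <- genotype_data(dos2, subject_ids = g$subject_ids)
  K <- compute_grm(gm)$K
  expect_true(all(is.finite(K)))
})

test_that("principal components have the contracted shape and orthogonality", {
  g <- tiny_cohort("admixed-independent", S = 500, n = 150, seed = 307)
  grm <- compute_grm(g)
  pcs <- compute_pcs(grm, n_pcs = 10)
  expect_equal(dim(pcs$scores), c(150L, 10L))
  expect_true(all(diff(pcs$eigenvalues) <= 1e-8))
  crossp <- crossprod(pcs$scores)
  expect_equal(crossp, diag(diag(crossp), 10), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(compute_pcs(grm, n_pcs = 150), "n_pcs")
})

test_that("an isotropic GRM has equal eigenvalues", {
  idK <- structure(list(K = diag(20), n_snps_used = 100L,
                        subject_ids = paste0("s", 1:20)), class = "grm")
  pcs <- compute_pcs(idK, n_pcs = 5)
  expect_equal(pcs$eigenvalues, rep(1, 5), tolerance = 1e-12)
})

test_that("PC1 separates ancestral origin groups in admixed cohorts", {
  g <- simulate_cohort("admixed-independent", S = 2000, seed = 308,
                       n_subjects = 300)
  grm <- compute_grm(g)
  pc1 <- compute_pcs(grm, n_pcs = 2)$scores[, 1]
  origin <- g$pedigree$origin
  between <- var(tapply(pc1, origin, mean))
  within <- mean(tapply(pc1, origin, var))
  expect_gt(between / within, 10)
})
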