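# Genetic relationship matrix (standardized-genotype estimator) and genotype
# principal components derived from its eigendecomposition.

#' Compute the genetic relationship matrix
#'
#' Standardized-genotype (GCTA-style) estimator: with `p_s` the sample
#' reference-allele frequency of SNP s,
#' `K_ij = (1/S') * sum_s (g_is - 2 p_s)(g_js - 2 p_s) / (2 p_s (1 - p_s))`
#' over the S' SNPs whose minor-allele frequency exceeds `maf_floor`. Missing
#' dosages are mean-imputed per SNP before standardization. The estimator is
#' invariant to SNP order and to flipping which allele is counted at any SNP.
#'
#' @param genotypes A `genotype_data`.
#' @param maf_floor SNPs with sample MAF at or below this are excluded
#'   (default 0.01).
#' @return An object of class `grm`: list with `K` (N x N symmetric matrix),
#'   `n_snps_used`, `subject_ids`.
#' @export
compute_grm <- function(genotypes, maf_floor = 0.01) {
  stopifnot(inherits(genotypes, "genotype_data"))
  G <- genotypes$dosages
  if (nrow(G) < 2) stop("need at least 2 subjects")
  storage.mode(G) <- "double"
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2L]]
  }
  p <- colMeans(G) / 2
  maf <- pmin(p, 1 - p)
  keep <- maf > maf_floor
  if (!any(keep)) stop("no usable SNPs: all monomorphic or below the MAF floor")
  G <- G[, keep, drop = FALSE]
  p <- p[keep]
  Z <- sweep(G, 2L, 2 * p, "-")
  Z <- sweep(Z, 2L, sqrt(2 * p * (1 - p)), "/")
  K <- tcrossprod(Z) / ncol(Z)
  K <- (K + t(K)) / 2
  structure(list(K = K, n_snps_used = ncol(Z),
                 subject_ids = genotypes$subject_ids),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("grm:", nrow(x$K), "subjects,", x$n_snps_used, "SNPs used\n")
  cat("  mean diagonal:", round(mean(diag(x$K)), 3),
      " mean off-diagonal:",
      round(mean(x$K[upper.tri(x$K)]), 4), "\n")
  invisible(x)
}

# Eigendecomposition of the GRM, computed once and reused by the REML fits,
# the Wald scan and the principal components.
grm_eigen <- function(grm) {
  stopifnot(inherits(grm, "grm"))
  eig <- eigen(grm$K, symmetric = TRUE)
  list(values = eig$values, vectors = eig$vectors)
}

#' Genotype principal components from the GRM
#'
#' Top eigenvectors of the genetic relationship matrix, scaled by the square
#' root of their eigenvalues so that scores carry the variance of each axis.
#' For standardized genotypes this matches the PCA of the genotype matrix up
#' to scaling, and one decomposition serves both the PCs and the mixed-model
#' rotation.
#'
#' @param grm A `grm` object.
#' @param n_pcs Number of components (default 10; must be < N).
#' @param eig Optional precomputed eigendecomposition (list with `values`,
#'   `vectors`) to avoid repeating the O(N^3) factorization.
#' @return An object of class `grm_pcs`: list with `scores` (N x `n_pcs`),
#'   `eigenvalues` (length `n_pcs`, non-increasing), `n_pcs`.
#' @export
compute_pcs <- function(grm, n_pcs = 10L, eig = NULL) {
  stopifnot(inherits(grm, "grm"))
  N <- nrow(grm$K)
  n_pcs <- as.integer(n_pcs)
  if (n_pcs < 1 || n_pcs >= N) stop("'n_pcs' must be in [1, N-1]")
  if (is.null(eig)) eig <- grm_eigen(grm)
  lam <- eig$values[seq_len(n_pcs)]
  scores <- eig$vectors[, seq_len(n_pcs), drop = FALSE] %*%
    diag(sqrt(pmax(lam, 0)), n_pcs)
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  rownames(scores) <- grm$subject_ids
  structure(list(scores = scores, eigenvalues = lam, n_pcs = n_pcs),
            class = "grm_pcs")
}

#' @export
print.grm_pcs <- function(x, ...) {
  cat("grm_pcs:", nrow(x$scores), "subjects,", x$n_pcs, "components\n")
  cat("  eigenvalues:", paste(round(x$eigenvalues, 2), collapse = " "), "\n")
  invisible(x)
}
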