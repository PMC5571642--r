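# Phenotype simulation: R correlated quantitative traits with an additive
# effect of one causal SNP on every trait mean, residuals multivariate normal
# with unit variances and exchangeable correlation rho.

#' Additive genetic mean of a trait given a dosage
#'
#' Mean contribution of the causal genotype under the additive coding: -e for
#' dosage 0 (AA), 0 for dosage 1 (AB), +e for dosage 2 (BB), i.e.
#' `(dosage - 1) * e`.
#'
#' @param dosage Dosage value(s) in {0, 1, 2}.
#' @param e Effect size (scalar).
#' @return Numeric vector of genetic means.
#' @examples
#' genetic_mean(0:2, e = 0.2)
#' @export
genetic_mean <- function(dosage, e) {
  if (!all(dosage %in% c(0, 1, 2)))
    stop("'dosage' must contain only 0, 1 or 2")
  if (!is.numeric(e) || !all(is.finite(e))) stop("'e' must be finite")
  (dosage - 1) * e
}

# Exchangeable correlation matrix with unit diagonal; positive definite iff
# -1/(R-1) < rho < 1.
.exchangeable_sigma <- function(R, rho) {
  Sigma <- matrix(rho, R, R)
  diag(Sigma) <- 1
  Sigma
}

#' Simulate correlated quantitative phenotypes from a causal SNP
#'
#' Draws, independently for each subject, an R-vector from a multivariate
#' normal whose r-th mean is `(g_i - 1) * e_r` (with `g_i` the subject's
#' dosage at the causal SNP) and whose covariance is an exchangeable matrix
#' with unit diagonal and off-diagonal `rho` (or an arbitrary user-supplied
#' `Sigma`). Subjects are independent given their genotypes: any phenotypic
#' resemblance between relatives arises solely through the shared causal
#' dosage.
#'
#' @param genotypes A `genotype_data` containing the causal SNP.
#' @param R Number of traits.
#' @param e Effect size: scalar (shared by all traits) or vector of length `R`.
#' @param rho Common off-diagonal correlation (ignored when `Sigma` is given).
#' @param Sigma Optional R x R positive-definite covariance matrix.
#' @param causal_snp Column index (or SNP id) of the causal SNP; default 1.
#' @param seed Optional integer seed.
#' @param trait_names Optional character vector of trait names.
#' @return An object of class `phenotype_data`: list with `values` (N x R
#'   matrix), `subject_ids`, `trait_names`.
#' @examples
#' g <- simulate_cohort("non-admixed-independent", S = 20, seed = 1,
#'                      n_subjects = 40)
#' ph <- simulate_phenotypes(g, R = 2, e = 0.5, rho = 0.4, seed = 2)
#' cor(ph$values)
#' @export
simulate_phenotypes <- function(genotypes, R = 2L, e = 0, rho = 0,
                                Sigma = NULL, causal_snp = 1L, seed = NULL,
                                trait_names = NULL) {
  stopifnot(inherits(genotypes, "genotype_data"))
  R <- as.integer(R)
  if (R < 1) stop("'R' must be >= 1")
  if (length(e) == 1L) e <- rep(e, R)
  if (length(e) != R) stop("'e' must have length 1 or R")
  if (!all(is.finite(e))) stop("'e' must be finite")
  if (is.character(causal_snp))
    causal_snp <- match(causal_snp, genotypes$snp_ids)
  if (is.na(causal_snp) || causal_snp < 1 || causal_snp > ncol(genotypes$dosages))
    stop("causal SNP not present in genotype data")
  if (is.null(Sigma)) {
    if (R > 1 && (rho <= -1 / (R - 1) || rho >= 1))
      stop("exchangeable correlation must satisfy -1/(R-1) < rho < 1")
    Sigma <- .exchangeable_sigma(R, rho)
  } else {
    Sigma <- as.matrix(Sigma)
    if (!isTRUE(all.equal(Sigma, t(Sigma))) || nrow(Sigma) != R)
      stop("'Sigma' must be a symmetric R x R matrix")
  }
  U <- tryCatch(chol(Sigma), error = function(err)
    stop("'Sigma' is not positive definite"))
  if (!is.null(seed)) set.seed(seed)

  g <- genotypes$dosages[, causal_snp]
  if (anyNA(g)) stop("causal SNP has missing dosages")
  N <- length(g)
  mu <- outer(g - 1, e)                      # N x R genetic means
  Z <- matrix(stats::rnorm(N * R), N, R)
  values <- mu + Z %*% U
  if (is.null(trait_names)) trait_names <- paste0("trait_", seq_len(R))
  colnames(values) <- trait_names
  rownames(values) <- genotypes$subject_ids
  structure(
    list(values = values,
         subject_ids = genotypes$subject_ids,
         trait_names = trait_names,
         causal_snp = genotypes$snp_ids[causal_snp]),
    class = "phenotype_data"
  )
}

#' Construct phenotype data from a plain matrix
#'
#' @param values N x R numeric matrix of trait values.
#' @param subject_ids Character vector of length N.
#' @param trait_names Character vector of length R.
#' @return An object of class `phenotype_data`.
#' @export
phenotype_data <- function(values, subject_ids = NULL, trait_names = NULL) {
  values <- as.matrix(values)
  if (is.null(subject_ids)) subject_ids <- rownames(values)
  if (is.null(subject_ids)) subject_ids <- paste0("id", seq_len(nrow(values)))
  if (is.null(trait_names)) trait_names <- colnames(values)
  if (is.null(trait_names)) trait_names <- paste0("trait_", seq_len(ncol(values)))
  if (length(subject_ids) != nrow(values))
    stop("'subject_ids' length does not match row count")
  if (length(trait_names) != ncol(values))
    stop("'trait_names' length does not match column count")
  dimnames(values) <- list(subject_ids, trait_names)
  structure(list(values = values, subject_ids = as.character(subject_ids),
                 trait_names = trait_names),
            class = "phenotype_data")
}

#' @export
print.phenotype_data <- function(x, ...) {
  cat("phenotype_data:", nrow(x$values), "subjects x", ncol(x$values),
      "traits (", paste(x$trait_names, collapse = ", "), ")\n")
  invisible(x)
}
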