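# Quality control and the end-to-end two-step multivariate scan:
# QC -> GRM -> PCs -> per-trait null REML fit -> per-SNP Wald per trait ->
# residual correlations -> gamma null -> per-SNP Fisher statistic.

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact (conditional on allele counts) two-sided HWE test p-value: the sum
#' of probabilities of all heterozygote counts no more likely than the one
#' observed. Stable for small counts, where the chi-square test misbehaves.
#'
#' @param n_het Observed heterozygotes.
#' @param n_hom1,n_hom2 Observed counts of the two homozygote classes.
#' @return Exact p-value in (0, 1].
#' @examples
#' hwe_exact_p(50, 25, 25)   # perfectly HWE counts
#' @export
hwe_exact_p <- function(n_het, n_hom1, n_hom2) {
  if (any(c(n_het, n_hom1, n_hom2) < 0)) stop("counts must be non-negative")
  n <- n_het + n_hom1 + n_hom2
  if (n == 0) return(1)
  n_rare <- 2 * min(n_hom1, n_hom2) + n_het
  # heterozygote counts with the parity of n_rare, from 0/1 to n_rare
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  # unnormalized log-probabilities by recurrence over het counts:
  # P(h+2)/P(h) = 4 * hom_rare(h) * hom_common(h) / ((h+2) * (h+1)),
  # with hom_rare(h) = (n_rare - h)/2 and hom_common(h) = n - h - hom_rare(h)
  lp <- numeric(length(hets))
  for (i in seq_along(hets)[-1]) {
    h_prev <- hets[i - 1]
    hr <- (n_rare - h_prev) / 2
    hc <- n - h_prev - hr
    lp[i] <- lp[i - 1] + log(4 * hr * hc) - log(hets[i] * (hets[i] - 1))
  }
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- which(hets == n_het)
  if (length(obs) != 1L) stop("genotype counts inconsistent with allele counts")
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-12)]))
}

#' SNP quality-control filter
#'
#' Drops SNPs failing, in order: per-SNP missingness (frequency of missing
#' genotypes above `miss_ceiling`), minor allele frequency (at or below
#' `maf_floor`), and the exact HWE test (p-value at or below `hwe_p_floor`,
#' computed on complete genotypes).
#'
#' @param genotypes A `genotype_data`.
#' @param maf_floor Minimum MAF, exclusive (default 0.01).
#' @param hwe_p_floor Minimum exact HWE p-value, exclusive (default 1e-5).
#' @param miss_ceiling Maximum missingness, exclusive (default 0.05).
#' @return List with `genotypes` (filtered) and `report` (one-row data frame
#'   of SNP counts dropped per criterion).
#' @export
qc_filter <- function(genotypes, maf_floor = 0.01, hwe_p_floor = 1e-5,
                      miss_ceiling = 0.05) {
  stopifnot(inherits(genotypes, "genotype_data"))
  stopifnot(maf_floor >= 0, maf_floor < 0.5, hwe_p_floor >= 0,
            hwe_p_floor <= 1, miss_ceiling >= 0, miss_ceiling <= 1)
  G <- genotypes$dosages
  S0 <- ncol(G)
  miss <- colMeans(is.na(G))
  keep <- miss < miss_ceiling
  n_miss <- sum(!keep)
  p <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  fail_maf <- keep & !(maf > maf_floor)
  keep <- keep & !fail_maf
  hwe_p <- rep(NA_real_, S0)
  idx <- which(keep)
  for (s in idx) {
    g <- G[, s]
    g <- g[!is.na(g)]
    hwe_p[s] <- hwe_exact_p(sum(g == 1), sum(g == 0), sum(g == 2))
  }
  fail_hwe <- keep & !(hwe_p > hwe_p_floor)
  keep <- keep & !fail_hwe
  if (!any(keep)) stop("quality control removed every SNP")
  out <- genotypes
  out$dosages <- G[, keep, drop = FALSE]
  out$snp_ids <- genotypes$snp_ids[keep]
  report <- data.frame(n_input = S0,
                       dropped_missingness = n_miss,
                       dropped_maf = sum(fail_maf),
                       dropped_hwe = sum(fail_hwe),
                       n_kept = sum(keep))
  list(genotypes = out, report = report)
}

#' Two-step multivariate genome scan
#'
#' Runs the full pipeline on one cohort: subject alignment, SNP quality
#' control, GRM and principal components, per-trait null REML mixed-model
#' fits (with the PCs and any user covariates as fixed effects), per-SNP
#' 1-df Wald tests per trait with plugged-in variance components, residual
#' correlation estimation, gamma-null calibration, and the per-SNP Fisher
#' combination test across traits.
#'
#' @param genotypes A `genotype_data`.
#' @param phenotypes A `phenotype_data` (rows matched to genotype subjects by
#'   id; unmatched subjects and rows with missing traits are dropped with a
#'   message, and the sample size used by the gamma calibration reflects the
#'   final analyzed count).
#' @param covariates Optional numeric covariate matrix with subject ids as
#'   row names.
#' @param n_pcs Number of genotype principal components added as fixed-effect
#'   covariates (default 10; 0 disables).
#' @param maf_floor,hwe_p_floor,miss_ceiling QC thresholds, see [qc_filter()].
#' @param qc Apply SNP quality control (default TRUE)?
#' @param sig_threshold Multivariate p-value threshold for the significance
#'   flag in the combined table (default 1e-6).
#' @return An object of class `pleio_gwas`: list with `combined` (per-SNP
#'   `snp_id`, `xi`, `p`, `significant`), `marginal` (long data frame of
#'   per-trait Wald results), `rho_hat`, `gamma_null`, `fits`, `pcs`,
#'   `qc_report`, `n`, and the applied parameters.
#' @examples
#' g <- simulate_cohort("non-admixed-independent", S = 300, seed = 1,
#'                      n_subjects = 120)
#' ph <- simulate_phenotypes(g, R = 2, e = 0, rho = 0.4, seed = 2)
#' fit <- pleio_gwas(g, ph, n_pcs = 2)
#' fit
#' @export
pleio_gwas <- function(genotypes, phenotypes, covariates = NULL, n_pcs = 10L,
                       maf_floor = 0.01, hwe_p_floor = 1e-5,
                       miss_ceiling = 0.05, qc = TRUE,
                       sig_threshold = 1e-6) {
  stopifnot(inherits(genotypes, "genotype_data"),
            inherits(phenotypes, "phenotype_data"))
  stopifnot(sig_threshold > 0, sig_threshold < 1)

  # subject alignment by id
  Y <- phenotypes$values
  complete <- stats::complete.cases(Y)
  if (!all(complete)) {
    message(sum(!complete), " subject(s) dropped for missing phenotypes ",
            "(no imputation is performed)")
    Y <- Y[complete, , drop = FALSE]
  }
  m <- match(genotypes$subject_ids, rownames(Y))
  keep_subj <- !is.na(m)
  if (!all(keep_subj))
    message(sum(!keep_subj), " genotyped subject(s) without phenotypes excluded")
  if (sum(keep_subj) < 3) stop("fewer than 3 analyzable subjects")
  gdat <- genotypes
  gdat$dosages <- genotypes$dosages[keep_subj, , drop = FALSE]
  gdat$subject_ids <- genotypes$subject_ids[keep_subj]
  if (!is.null(gdat$pedigree))
    gdat$pedigree <- gdat$pedigree[keep_subj, , drop = FALSE]
  Y <- Y[m[keep_subj], , drop = FALSE]
  N <- nrow(Y)
  R <- ncol(Y)

  qc_report <- NULL
  if (qc) {
    qcres <- qc_filter(gdat, maf_floor = maf_floor,
                       hwe_p_floor = hwe_p_floor, miss_ceiling = miss_ceiling)
    gdat <- qcres$genotypes
    qc_report <- qcres$report
  }

  grm <- compute_grm(gdat, maf_floor = maf_floor)
  eig <- grm_eigen(grm)
  X <- NULL
  pcs <- NULL
  if (n_pcs > 0) {
    pcs <- compute_pcs(grm, n_pcs = n_pcs, eig = eig)
    X <- pcs$scores
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (!is.null(rownames(covariates))) {
      cm <- match(gdat$subject_ids, rownames(covariates))
      if (anyNA(cm)) stop("covariate rows missing for some analyzed subjects")
      covariates <- covariates[cm, , drop = FALSE]
    } else if (nrow(covariates) != N) {
      stop("covariate matrix has no ids and the wrong row count")
    }
    X <- cbind(X, covariates)
  }

  fits <- lapply(seq_len(R), function(r)
    fit_null(Y[, r], covariates = X, grm = grm, eig = eig))
  names(fits) <- colnames(Y)

  G <- gdat$dosages
  storage.mode(G) <- "double"
  if (anyNA(G)) {                       # mean-impute for the scan as well
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2L]]
  }
  G_rot <- crossprod(eig$vectors, G)
  scans <- lapply(fits, snp_wald_scan, G = G, G_rot = G_rot, log_p = TRUE)

  rho_hat <- estimate_rho(fits)
  dimnames(rho_hat) <- list(colnames(Y), colnames(Y))
  gnull <- gamma_moments(rho_hat, N = N)
  log_pmat <- vapply(scans, function(s) s$log_p, numeric(ncol(G)))
  log_pmat <- matrix(log_pmat, ncol = R,
                     dimnames = list(gdat$snp_ids, colnames(Y)))
  combined <- combine_pvalues(log_pmat, gnull, snp_ids = gdat$snp_ids)
  combined$significant <- !is.na(combined$p) & combined$p < sig_threshold

  marginal <- do.call(rbind, lapply(seq_len(R), function(r) {
    s <- scans[[r]]
    data.frame(snp_id = s$snp_id, trait = colnames(Y)[r], beta = s$beta,
               se = s$se, chi2 = s$chi2, p = s$p,
               stringsAsFactors = FALSE)
  }))
  rownames(marginal) <- NULL

  structure(
    list(combined = combined, marginal = marginal, rho_hat = rho_hat,
         gamma_null = gnull, fits = fits, pcs = pcs, qc_report = qc_report,
         n = N, n_traits = R, n_snps = ncol(G),
         params = list(n_pcs = n_pcs, maf_floor = maf_floor,
                       hwe_p_floor = hwe_p_floor,
                       miss_ceiling = miss_ceiling,
                       sig_threshold = sig_threshold)),
    class = "pleio_gwas"
  )
}

#' @export
print.pleio_gwas <- function(x, ...) {
  cat("Two-step multivariate scan:", x$n, "subjects,", x$n_traits,
      "traits,", x$n_snps, "SNPs\n")
  cat("  gamma null: k =", signif(x$gamma_null$k, 5),
      " theta =", signif(x$gamma_null$theta, 5), "\n")
  cat("  significant SNPs (p <", x$params$sig_threshold, "):",
      sum(x$combined$significant, na.rm = TRUE), "\n")
  invisible(x)
}

#' @export
summary.pleio_gwas <- function(object, ...) {
  vc <- t(vapply(object$fits, function(f)
    c(sigma_g2 = f$sigma_g2, sigma_e2 = f$sigma_e2, lambda = f$lambda),
    numeric(3)))
  top <- object$combined[order(object$combined$p), ][
    seq_len(min(5L, nrow(object$combined))), ]
  out <- list(n = object$n, n_traits = object$n_traits,
              n_snps = object$n_snps, varcomp = vc,
              rho_hat = object$rho_hat, gamma_null = object$gamma_null,
              qc_report = object$qc_report, top = top)
  class(out) <- "summary.pleio_gwas"
  out
}

#' @export
print.summary.pleio_gwas <- function(x, ...) {
  cat("Two-step multivariate scan\n")
  cat("  subjects:", x$n, "  traits:", x$n_traits, "  SNPs:", x$n_snps, "\n")
  if (!is.null(x$qc_report)) {
    cat("  QC: kept", x$qc_report$n_kept, "of", x$qc_report$n_input,
        "SNPs (missingness", x$qc_report$dropped_missingness,
        ", MAF", x$qc_report$dropped_maf,
        ", HWE", x$qc_report$dropped_hwe, ")\n")
  }
  cat("\nVariance components per trait:\n")
  print(round(x$varcomp, 4))
  cat("\nResidual correlation matrix:\n")
  print(round(x$rho_hat, 3))
  cat("\n")
  print(x$gamma_null)
  cat("\nTop SNPs by multivariate p-value:\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' QQ plot of the multivariate (and marginal) p-values
#'
#' @param x A `pleio_gwas` object.
#' @param which `"combined"` or `"marginal"` (trait 1).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pleio_gwas <- function(x, which = c("combined", "marginal"), ...) {
  which <- match.arg(which)
  p <- if (which == "combined") x$combined$p
       else x$marginal$p[x$marginal$trait == x$marginal$trait[1L]]
  p <- sort(p[!is.na(p)])
  n <- length(p)
  expected <- -log10(stats::ppoints(n))
  observed <- -log10(p)
  graphics::plot(expected, observed,
                 xlab = expression(Expected ~ -log[10](p)),
                 ylab = expression(Observed ~ -log[10](p)),
                 main = paste("QQ plot:", which, "test"), ...)
  graphics::abline(0, 1, col = "grey50")
  invisible(x)
}

#' Write scan results and a run log
#'
#' Writes `prefix`_combined.tsv (per-SNP Fisher statistic, multivariate
#' p-value, the marginal p-values, significance flag), `prefix`_marginal.tsv
#' (long per-trait Wald table) and `prefix`_log.txt recording thresholds,
#' sample sizes, variance components, the residual correlation matrix and
#' the gamma parameters exactly as applied.
#'
#' @param x A `pleio_gwas` object.
#' @param prefix Output prefix.
#' @return Invisibly, the prefix.
#' @export
write_results <- function(x, prefix) {
  stopifnot(inherits(x, "pleio_gwas"))
  wide <- x$combined
  for (tr in unique(x$marginal$trait)) {
    wide[[paste0("p_", tr)]] <- x$marginal$p[x$marginal$trait == tr]
  }
  utils::write.table(wide, paste0(prefix, "_combined.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(x$marginal, paste0(prefix, "_marginal.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  con <- file(paste0(prefix, "_log.txt"), "w")
  on.exit(close(con))
  writeLines(c(
    paste("pleioscan", as.character(utils::packageVersion("pleioscan"))),
    paste("date:", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste("subjects analyzed:", x$n),
    paste("traits:", x$n_traits),
    paste("snps tested:", x$n_snps),
    paste("n_pcs:", x$params$n_pcs),
    paste("maf_floor:", x$params$maf_floor),
    paste("hwe_p_floor:", x$params$hwe_p_floor),
    paste("miss_ceiling:", x$params$miss_ceiling),
    paste("sig_threshold:", x$params$sig_threshold),
    paste("gamma k:", format(x$gamma_null$k, digits = 10)),
    paste("gamma theta:", format(x$gamma_null$theta, digits = 10)),
    "variance components (trait, sigma_g2, sigma_e2):",
    vapply(names(x$fits), function(nm)
      paste(" ", nm, format(x$fits[[nm]]$sigma_g2, digits = 8),
            format(x$fits[[nm]]$sigma_e2, digits = 8)), character(1)),
    "residual correlation matrix:",
    apply(round(x$rho_hat, 6), 1L, paste, collapse = "\t")
  ), con)
  invisible(prefix)
}
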