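# Single-kernel linear mixed model, spectral REML.
#
# Model per trait: y = X b + z + eps, z ~ N(0, sigma_g^2 K), eps ~ N(0,
# sigma^2 I). With K = U D U' the model rotates to independent observations
# with variances sigma^2 (lambda d_i + 1), lambda = sigma_g^2 / sigma^2, so
# the REML log-likelihood is evaluated in O(N p^2) per lambda after one
# eigendecomposition that is shared across traits and covariate sets.

# Restricted log-likelihood profiled over sigma^2 at a given lambda.
# ys, Xs: rotated responses/covariates (U'y, U'X); d: eigenvalues of K.
# Weighted normal equations via Cholesky: cheap enough to call thousands of
# times inside the simulation studies.
.reml_loglik <- function(lambda, ys, Xs, d) {
  N <- length(ys)
  p <- ncol(Xs)
  w <- 1 / (lambda * d + 1)
  Xw <- Xs * w
  XtWX <- crossprod(Xs, Xw)
  XtWy <- crossprod(Xw, ys)
  ch <- chol(XtWX)
  beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
  rss <- sum(ys^2 * w) - sum(beta * XtWy)
  rss <- max(rss, 0)
  sigma2 <- rss / (N - p)
  # -2 log-restricted-likelihood pieces: log|H|, log|X'H^-1 X|, profiled rss
  ll <- -0.5 * ((N - p) * (log(2 * pi * max(sigma2, .Machine$double.xmin)) + 1) -
                  sum(log(w)) + 2 * sum(log(diag(ch))))
  list(loglik = ll, sigma2 = sigma2, beta = as.numeric(beta), w = w)
}

#' Fit the null linear mixed model for one trait
#'
#' REML fit of `y = X b + z + eps` with `z ~ N(0, sigma_g^2 K)` and
#' `eps ~ N(0, sigma^2 I)`, maximizing the restricted likelihood over the
#' variance ratio `lambda = sigma_g^2 / sigma^2` on a bounded log grid with
#' Brent refinement, then profiling out `sigma^2`. No SNP enters the model:
#' this is the null fit whose variance components are later plugged into
#' per-SNP Wald tests, and whose conditional residuals (BLUP subtracted)
#' estimate the cross-trait residual correlation.
#'
#' @param y Numeric response vector of length N.
#' @param covariates Optional N x q matrix of fixed-effect covariates (PCs,
#'   demographics); an intercept is always added.
#' @param grm A `grm` object.
#' @param eig Optional precomputed `eigen` of the GRM (list with `values`,
#'   `vectors`); computed from `grm` when missing. Pass it explicitly when
#'   fitting several traits on the same cohort.
#' @param lambda Optional fixed value of the variance ratio, bypassing the
#'   REML search (used for diagnostics; `lambda = 0` reduces the model to
#'   ordinary least squares).
#' @param lambda_bounds Search interval for lambda (default `c(1e-6, 1e6)`).
#' @param n_grid Number of log-spaced grid points that seed the Brent
#'   refinement (default 33).
#' @return An object of class `null_lmm` with elements `sigma_g2`, `sigma_e2`,
#'   `lambda`, `fixed_effects`, `blup`, `residuals` (conditional residuals
#'   `y - X b - blup`), `reml_loglik`, `grid_logliks`, and the cached rotated
#'   quantities used by [snp_wald()].
#' @seealso [snp_wald()], [estimate_rho()]
#' @export
fit_null <- function(y, covariates = NULL, grm, eig = NULL, lambda = NULL,
                     lambda_bounds = c(1e-6, 1e6), n_grid = 33L) {
  stopifnot(inherits(grm, "grm"))
  y <- as.numeric(y)
  N <- length(y)
  if (N != nrow(grm$K)) stop("length of 'y' does not match the GRM")
  if (!all(is.finite(y))) stop("'y' must be finite")
  X <- cbind(`(Intercept)` = rep(1, N))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != N) stop("covariate rows do not match 'y'")
    X <- cbind(X, covariates)
  }
  if (qr(X)$rank < ncol(X)) stop("covariate matrix is rank deficient")
  p <- ncol(X)
  if (is.null(eig)) eig <- grm_eigen(grm)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  ys <- crossprod(U, y)[, 1L]
  Xs <- crossprod(U, X)

  grid <- exp(seq(log(lambda_bounds[1L]), log(lambda_bounds[2L]),
                  length.out = n_grid))
  grid_ll <- vapply(grid, function(l) .reml_loglik(l, ys, Xs, d)$loglik,
                    numeric(1))
  if (is.null(lambda)) {
    best <- which.max(grid_ll)          # ties resolve to the smaller lambda
    lo <- grid[max(1L, best - 1L)]
    hi <- grid[min(n_grid, best + 1L)]
    opt <- stats::optimize(function(ll)
      .reml_loglik(exp(ll), ys, Xs, d)$loglik,
      lower = log(lo), upper = log(hi), maximum = TRUE, tol = 1e-8)
    lambda_hat <- exp(opt$maximum)
    if (grid_ll[best] >= opt$objective) lambda_hat <- grid[best]
  } else {
    lambda_hat <- lambda
  }

  fit <- .reml_loglik(lambda_hat, ys, Xs, d)
  vy <- stats::var(y)
  sigma2 <- max(fit$sigma2, 1e-12 * vy, .Machine$double.xmin)
  sigma_g2 <- lambda_hat * sigma2
  beta <- fit$beta
  r_rot <- ys - as.numeric(Xs %*% beta)          # rotated marginal residual
  shrink <- lambda_hat * d / (lambda_hat * d + 1)
  blup <- as.numeric(U %*% (shrink * r_rot))
  resid <- as.numeric(U %*% ((1 - shrink) * r_rot))

  structure(
    list(sigma_g2 = sigma_g2, sigma_e2 = sigma2, lambda = lambda_hat,
         fixed_effects = stats::setNames(beta, colnames(X)),
         blup = blup, residuals = resid,
         reml_loglik = fit$loglik,
         grid = grid, grid_logliks = grid_ll,
         n = N, p = p,
         eig = eig, ys = ys, Xs = Xs, d = d),
    class = "null_lmm"
  )
}

#' @export
print.null_lmm <- function(x, ...) {
  cat("Null linear mixed model (REML), N =", x$n, "\n")
  cat("  sigma_g^2 =", signif(x$sigma_g2, 4),
      " sigma^2 =", signif(x$sigma_e2, 4),
      " lambda =", signif(x$lambda, 4), "\n")
  h2 <- x$sigma_g2 / (x$sigma_g2 + x$sigma_e2)
  cat("  heritability (sigma_g^2 / total) =", round(h2, 3),
      "  REML logLik =", round(x$reml_loglik, 2), "\n")
  invisible(x)
}

#' @export
coef.null_lmm <- function(object, ...) object$fixed_effects

#' @export
residuals.null_lmm <- function(object, ...) object$residuals

#' @export
logLik.null_lmm <- function(object, ...) {
  structure(object$reml_loglik, df = object$p + 2, class = "logLik")
}

# Weighted residualization shared by single- and multi-SNP Wald tests:
# columns of Gs (rotated dosages) and ys are projected off the covariates
# under the plugged-in inverse-variance weights.
.wald_core <- function(fit, Gs) {
  v <- 1 / (fit$sigma_g2 * fit$d + fit$sigma_e2)
  sv <- sqrt(v)
  Xw <- fit$Xs * sv
  qrX <- qr(Xw)
  yt <- qr.resid(qrX, fit$ys * sv)
  Gt <- qr.resid(qrX, Gs * sv)
  gg <- colSums(Gt^2)
  gy <- colSums(Gt * yt)
  list(gg = gg, gy = gy)
}

#' Per-SNP Wald test with plugged-in variance components
#'
#' Generalized-least-squares estimate of the SNP effect using the covariance
#' `V = sigma_g^2 K + sigma^2 I` fixed at the null-model REML estimates
#' (the two-step plug-in scheme). Computed in the eigen-rotated basis, so each
#' SNP costs O(N) after the one-time decomposition. The squared ratio
#' `(beta/se)^2` is referred to a 1-df chi-square distribution.
#'
#' @param fit A `null_lmm` from [fit_null()].
#' @param g Dosage vector of the tested SNP (length N, same subject order).
#' @param snp_id Optional SNP identifier carried into the result.
#' @return A one-row data frame: `snp_id`, `beta`, `se`, `chi2`, `p`.
#' @export
snp_wald <- function(fit, g, snp_id = "snp") {
  stopifnot(inherits(fit, "null_lmm"))
  g <- as.numeric(g)
  if (length(g) != fit$n) stop("SNP vector length does not match the fit")
  if (anyNA(g)) stop("missing dosages in tested SNP")
  if (stats::var(g) <= 0) stop("degenerate SNP: monomorphic in sample")
  Gs <- crossprod(fit$eig$vectors, g)
  core <- .wald_core(fit, Gs)
  if (core$gg < 1e-12)
    stop("degenerate SNP: no variance left after covariate adjustment")
  beta <- core$gy / core$gg
  se <- sqrt(1 / core$gg)
  chi2 <- beta^2 / se^2
  data.frame(snp_id = snp_id, beta = beta, se = se, chi2 = chi2,
             p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Wald scan over a dosage matrix
#'
#' Vectorized form of [snp_wald()] for all SNPs of a cohort. Monomorphic or
#' covariate-confounded SNPs (no residual variance) get `NA` results rather
#' than an error so a genome scan can proceed.
#'
#' @param fit A `null_lmm`.
#' @param G N x S dosage matrix (or a `genotype_data`).
#' @param G_rot Optional precomputed rotation `U' G` (reuse across traits).
#' @param log_p If `TRUE`, add a `log_p` column with natural-log p-values
#'   (safe for extreme signals).
#' @return Data frame with one row per SNP: `snp_id`, `beta`, `se`, `chi2`,
#'   `p` (and `log_p`).
#' @export
snp_wald_scan <- function(fit, G, G_rot = NULL, log_p = FALSE) {
  stopifnot(inherits(fit, "null_lmm"))
  snp_ids <- NULL
  if (inherits(G, "genotype_data")) {
    snp_ids <- G$snp_ids
    G <- G$dosages
  }
  storage.mode(G) <- "double"
  if (is.null(snp_ids))
    snp_ids <- colnames(G) %||% paste0("snp", seq_len(ncol(G)))
  if (nrow(G) != fit$n) stop("dosage rows do not match the fit")
  if (is.null(G_rot)) G_rot <- crossprod(fit$eig$vectors, G)
  core <- .wald_core(fit, G_rot)
  ok <- core$gg > 1e-12
  beta <- se <- chi2 <- pv <- rep(NA_real_, ncol(G))
  beta[ok] <- core$gy[ok] / core$gg[ok]
  se[ok] <- sqrt(1 / core$gg[ok])
  chi2[ok] <- (beta[ok] / se[ok])^2
  pv[ok] <- stats::pchisq(chi2[ok], df = 1, lower.tail = FALSE)
  out <- data.frame(snp_id = snp_ids, beta = beta, se = se, chi2 = chi2,
                    p = pv, stringsAsFactors = FALSE)
  if (log_p) {
    lp <- rep(NA_real_, ncol(G))
    lp[ok] <- stats::pchisq(chi2[ok], df = 1, lower.tail = FALSE, log.p = TRUE)
    out$log_p <- lp
  }
  out
}

#' Residual correlation matrix across traits
#'
#' Pearson correlation of the conditional residuals (`y - X b - blup`) of the
#' per-trait null mixed models. With relatedness absorbed by the BLUP, this
#' estimates the between-phenotype correlation `rho_rr'` that calibrates the
#' gamma null of the Fisher statistic.
#'
#' @param fits List of `null_lmm` objects sharing the subject order.
#' @return R x R symmetric correlation matrix with unit diagonal.
#' @export
estimate_rho <- function(fits) {
  if (inherits(fits, "null_lmm")) fits <- list(fits)
  stopifnot(all(vapply(fits, inherits, logical(1), "null_lmm")))
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1L) stop("fits do not share the subject set")
  E <- vapply(fits, residuals, numeric(ns[1L]))
  sds <- apply(E, 2L, stats::sd)
  if (any(sds <= 0)) stop("zero-variance residual vector")
  C <- stats::cor(E)
  (C + t(C)) / 2
}

#' Raw phenotype correlation (no relatedness adjustment)
#'
#' Plain Pearson correlation of the trait values. This is the comparison
#' baseline that ignores genetic relatedness; with a shared causal genotype it
#' overestimates the residual correlation.
#'
#' @param phenotypes A `phenotype_data` or an N x R numeric matrix.
#' @return R x R correlation matrix.
#' @export
naive_rho <- function(phenotypes) {
  Y <- if (inherits(phenotypes, "phenotype_data")) phenotypes$values
       else as.matrix(phenotypes)
  sds <- apply(Y, 2L, stats::sd)
  if (any(sds <= 0)) stop("zero-variance trait")
  stats::cor(Y)
}
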