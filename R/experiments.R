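# Scripted simulation studies: correlation-estimator accuracy, type I error
# and power of the marginal vs multivariate tests, and the unequal-effect-size
# power grid. Every run is exactly reproducible from (grid, seed): a single
# RNG stream seeded once drives cohorts, phenotypes and everything else.

.scenarios <- c("non-admixed-independent", "non-admixed-related",
                "admixed-independent", "admixed-related")

#' Define a simulation experiment grid
#'
#' Collects the factors of one simulation study. The reduced-scale defaults (200
#' replicates, 2000 background SNPs) keep a full study in the minutes range;
#' the study-scale settings (1000 replicates, 10000 SNPs) are reached by
#' raising `replicates` and `S`. Genotype cohorts are redrawn every
#' `genotype_refresh` replicates; phenotypes are redrawn every replicate.
#'
#' @param scenarios Subset of the four population scenarios.
#' @param rho Phenotype correlation values (non-negative; negative
#'   correlations are excluded from shipped grids).
#' @param e Effect sizes: numeric vector, or a list of length-`n_traits`
#'   vectors for unequal effects.
#' @param n_traits Number of traits (2 for correlation accuracy, 4 for
#'   power/type-I studies).
#' @param replicates Replicates per cell (default 200).
#' @param S Number of SNPs per cohort (default 2000).
#' @param n_subjects Cohort size (default 1000).
#' @param seed Integer master seed.
#' @param alpha Nominal test level for rejection-rate summaries.
#' @param n_pcs Principal components used as covariates where a method calls
#'   for them (default 10).
#' @param genotype_refresh Redraw the genotype cohort every this many
#'   replicates (default 20).
#' @return An object of class `experiment_grid`.
#' @export
experiment_grid <- function(scenarios = .scenarios, rho = c(0, 0.4, 0.8),
                            e = c(0, 0.1, 0.2), n_traits = 4L,
                            replicates = 200L, S = 2000L, n_subjects = 1000L,
                            seed = 1L, alpha = 0.05, n_pcs = 10L,
                            genotype_refresh = 20L) {
  scenarios <- match.arg(scenarios, .scenarios, several.ok = TRUE)
  if (replicates < 1) stop("'replicates' must be >= 1")
  if (any(unlist(rho) < 0 | unlist(rho) >= 1))
    stop("'rho' values must lie in [0, 1)")
  if (is.list(e)) {
    if (any(vapply(e, length, integer(1)) != n_traits))
      stop("every effect-size vector must have length 'n_traits'")
    if (any(vapply(e, function(v) all(v == 0), logical(1))))
      stop("the all-zero effect vector is not part of power grids")
  }
  structure(list(scenarios = scenarios, rho = rho, e = e,
                 n_traits = as.integer(n_traits),
                 replicates = as.integer(replicates), S = as.integer(S),
                 n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 alpha = alpha, n_pcs = as.integer(n_pcs),
                 genotype_refresh = as.integer(genotype_refresh)),
            class = "experiment_grid")
}

#' @export
print.experiment_grid <- function(x, ...) {
  cat("experiment_grid:", length(x$scenarios), "scenario(s) x",
      length(x$rho), "rho x", length(x$e), "effect size(s),",
      x$replicates, "replicates, S =", x$S, ", N =", x$n_subjects, "\n")
  invisible(x)
}

# Cohort context: genotypes + GRM eigendecomposition + PCs, computed once and
# shared across the replicates that reuse the cohort.
.cohort_ctx <- function(scenario, S, n_subjects, n_pcs) {
  g <- simulate_cohort(scenario, S = S, n_subjects = n_subjects)
  grm <- compute_grm(g)
  eig <- grm_eigen(grm)
  pcs <- compute_pcs(grm, n_pcs = n_pcs, eig = eig)
  list(genotypes = g, grm = grm, eig = eig, pcs = pcs)
}

#' Accuracy of the three phenotype-correlation estimators
#'
#' For every (scenario, rho, e, replicate) cell with bivariate phenotypes,
#' estimates the between-trait correlation three ways: Method 1, correlation
#' of the mixed-model conditional residuals; Method 2, the same with the
#' first `n_pcs` principal components as fixed covariates; Method 3, the
#' raw phenotype correlation with no relatedness adjustment.
#'
#' @param grid An `experiment_grid` with `n_traits = 2` and scalar effect
#'   sizes.
#' @return Data frame of class `experiment_result`, one row per
#'   (scenario, rho, e, replicate, method) with `rho_hat` and `bias`.
#' @export
run_correlation_accuracy <- function(grid) {
  stopifnot(inherits(grid, "experiment_grid"))
  if (grid$n_traits != 2L || is.list(grid$e))
    stop("correlation-accuracy study is bivariate with scalar effect sizes")
  set.seed(grid$seed)
  rows <- vector("list", 0L)
  for (sc in grid$scenarios) {
    ctx <- NULL
    for (rep_i in seq_len(grid$replicates)) {
      if (is.null(ctx) || (rep_i - 1L) %% grid$genotype_refresh == 0L)
        ctx <- .cohort_ctx(sc, grid$S, grid$n_subjects, grid$n_pcs)
      for (rho in grid$rho) for (e in grid$e) {
        ph <- simulate_phenotypes(ctx$genotypes, R = 2L, e = e, rho = rho)
        f1 <- lapply(1:2, function(r)
          fit_null(ph$values[, r], grm = ctx$grm, eig = ctx$eig))
        f2 <- lapply(1:2, function(r)
          fit_null(ph$values[, r], covariates = ctx$pcs$scores,
                   grm = ctx$grm, eig = ctx$eig))
        est <- c(estimate_rho(f1)[1, 2], estimate_rho(f2)[1, 2],
                 naive_rho(ph)[1, 2])
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = sc, rho = rho, e = e, replicate = rep_i,
          method = c("lmm", "lmm_pcs", "naive"),
          rho_hat = est, bias = est - rho, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("experiment_result", class(out))
  out
}

# One power/type-I replicate on a prepared cohort: simulate R traits, fit the
# per-trait null models (with PCs), test the causal SNP per trait, combine.
.power_one <- function(ctx, R, e_vec, rho, causal = 1L) {
  ph <- simulate_phenotypes(ctx$genotypes, R = R, e = e_vec, rho = rho,
                            causal_snp = causal)
  fits <- lapply(seq_len(R), function(r)
    fit_null(ph$values[, r], covariates = ctx$pcs$scores,
             grm = ctx$grm, eig = ctx$eig))
  g <- ctx$genotypes$dosages[, causal]
  marg <- lapply(fits, snp_wald, g = g)
  log_p <- vapply(seq_len(R), function(r)
    stats::pchisq(marg[[r]]$chi2, 1, lower.tail = FALSE, log.p = TRUE),
    numeric(1))
  gnull <- gamma_moments(estimate_rho(fits), N = length(g))
  xi <- -2 * sum(log_p)
  c(p_marginal = marg[[1L]]$p, p_multivariate = multivariate_p(xi, gnull))
}

#' Type I error and power of the marginal vs multivariate tests
#'
#' For every (scenario, rho, e, replicate) cell with `n_traits` phenotypes,
#' simulates a cohort and phenotypes, tests the causal SNP with the trait-1
#' marginal Wald test and with the Fisher combination test (correlation from
#' mixed-model-with-PCs residuals), and records both p-values. Summarize
#' rejection rates with [summarize_power()].
#'
#' @param grid An `experiment_grid` (typically `n_traits = 4`,
#'   `e = c(0, 0.1, 0.2)`, `rho = c(0, 0.4, 0.8)`).
#' @return Data frame of class `experiment_result`, one row per cell and
#'   replicate with `p_marginal` and `p_multivariate`.
#' @export
run_power_type1 <- function(grid) {
  stopifnot(inherits(grid, "experiment_grid"))
  if (is.list(grid$e)) stop("use run_effectsize_grid() for effect vectors")
  set.seed(grid$seed)
  rows <- vector("list", 0L)
  for (sc in grid$scenarios) {
    ctx <- NULL
    for (rep_i in seq_len(grid$replicates)) {
      if (is.null(ctx) || (rep_i - 1L) %% grid$genotype_refresh == 0L)
        ctx <- .cohort_ctx(sc, grid$S, grid$n_subjects, grid$n_pcs)
      for (rho in grid$rho) for (e in grid$e) {
        pv <- .power_one(ctx, grid$n_traits, e, rho)
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = sc, rho = rho, e = e, replicate = rep_i,
          p_marginal = pv[["p_marginal"]],
          p_multivariate = pv[["p_multivariate"]],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- grid$alpha
  class(out) <- c("experiment_result", class(out))
  out
}

#' Power grid with unequal effect sizes
#'
#' Runs the Fisher combination test (and the trait-1 marginal test) on the
#' related admixed cohort under per-trait effect-size vectors, e.g. equal
#' small effects, increasing effects, equal medium effects, at weak and
#' moderate phenotype correlation. The residual correlation here uses the
#' plain mixed-model residuals (no PC covariates in the correlation step is
#' not distinguished at this design: PCs are included as in the power study).
#'
#' @param grid An `experiment_grid` whose `e` is a list of length-`n_traits`
#'   vectors and whose scenarios default to `"admixed-related"`.
#' @return Data frame of class `experiment_result` with one row per cell and
#'   replicate: `e_label`, `rho`, `p_marginal`, `p_multivariate`.
#' @export
run_effectsize_grid <- function(grid) {
  stopifnot(inherits(grid, "experiment_grid"))
  if (!is.list(grid$e)) stop("'grid$e' must be a list of effect-size vectors")
  set.seed(grid$seed)
  labels <- names(grid$e) %||% vapply(grid$e, function(v)
    paste(v, collapse = ","), character(1))
  rows <- vector("list", 0L)
  for (sc in grid$scenarios) {
    ctx <- NULL
    for (rep_i in seq_len(grid$replicates)) {
      if (is.null(ctx) || (rep_i - 1L) %% grid$genotype_refresh == 0L)
        ctx <- .cohort_ctx(sc, grid$S, grid$n_subjects, grid$n_pcs)
      for (rho in grid$rho) for (j in seq_along(grid$e)) {
        pv <- .power_one(ctx, grid$n_traits, grid$e[[j]], rho)
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = sc, rho = rho, e_label = labels[j], replicate = rep_i,
          p_marginal = pv[["p_marginal"]],
          p_multivariate = pv[["p_multivariate"]],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("experiment_result", class(out))
  out
}

#' Rejection-rate summary of a power/type-I experiment
#'
#' @param result Result of [run_power_type1()] or [run_effectsize_grid()].
#' @param alpha Test level (default: the grid's alpha, else 0.05).
#' @return Data frame with one row per cell: rejection rates of both tests
#'   and the replicate count.
#' @export
summarize_power <- function(result, alpha = NULL) {
  alpha <- alpha %||% attr(result, "alpha") %||% 0.05
  cell_vars <- intersect(c("scenario", "rho", "e", "e_label"), names(result))
  agg <- stats::aggregate(
    result[, c("p_marginal", "p_multivariate")],
    by = result[cell_vars],
    FUN = function(p) mean(p < alpha))
  names(agg)[names(agg) == "p_marginal"] <- "reject_marginal"
  names(agg)[names(agg) == "p_multivariate"] <- "reject_multivariate"
  cnt <- stats::aggregate(list(replicates = result$replicate),
                          by = result[cell_vars], FUN = length)
  merge(agg, cnt, by = cell_vars)
}

#' Write / read an experiment result table
#'
#' Tidy TSV, one row per (cell, replicate, measure); reading restores an
#' identical data frame.
#'
#' @param result An `experiment_result` data frame.
#' @param path File path.
#' @return `write_experiment_result()`: invisibly, the path;
#'   `read_experiment_result()`: the data frame.
#' @export
write_experiment_result <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_experiment_result
#' @export
read_experiment_result <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  class(out) <- c("experiment_result", class(out))
  out
}

#' Boxplot of correlation-estimator bias
#'
#' Mirrors the usual presentation of correlation-accuracy studies: one box
#' of `rho_hat - rho` per estimation method within each (rho, e) cell.
#'
#' @param result Result of [run_correlation_accuracy()].
#' @param scenario Scenario to display (default: first present).
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot_correlation_accuracy <- function(result, scenario = NULL, ...) {
  if (is.null(scenario)) scenario <- result$scenario[1L]
  d <- result[result$scenario == scenario, ]
  d$cell <- interaction(d$method, d$rho, d$e, sep = " ")
  graphics::boxplot(bias ~ cell, data = d, las = 2,
                    ylab = expression(hat(rho) - rho), main = scenario, ...)
  graphics::abline(h = 0, col = "grey50")
  invisible(result)
}

#' Null calibration scan across all SNPs
#'
#' Simulates one cohort per scenario and, for each phenotype correlation in
#' `rho`, draws phenotypes with no genetic effect and runs the full two-step
#' scan over all S (null) SNPs, returning the trait-1 marginal and
#' multivariate p-values. Under correct calibration both sets are uniform.
#'
#' @param scenario One of the four population scenarios.
#' @param rho Phenotype correlation values.
#' @param n_traits Number of traits (default 4).
#' @param S Number of SNPs (default 2000).
#' @param n_subjects Cohort size (default 1000).
#' @param n_pcs Principal-component covariates (default 10).
#' @param seed Optional integer seed.
#' @return Data frame with one row per (rho, SNP): `rho`, `snp_id`,
#'   `p_marginal`, `p_multivariate`.
#' @export
run_null_calibration <- function(scenario, rho = c(0, 0.4, 0.8),
                                 n_traits = 4L, S = 2000L,
                                 n_subjects = 1000L, n_pcs = 10L,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ctx <- .cohort_ctx(scenario, S, n_subjects, n_pcs)
  G <- ctx$genotypes$dosages
  storage.mode(G) <- "double"
  G_rot <- crossprod(ctx$eig$vectors, G)
  rows <- lapply(rho, function(r) {
    ph <- simulate_phenotypes(ctx$genotypes, R = n_traits, e = 0, rho = r)
    fits <- lapply(seq_len(n_traits), function(tr)
      fit_null(ph$values[, tr], covariates = ctx$pcs$scores,
               grm = ctx$grm, eig = ctx$eig))
    scans <- lapply(fits, snp_wald_scan, G = G, G_rot = G_rot, log_p = TRUE)
    gnull <- gamma_moments(estimate_rho(fits), N = nrow(G))
    log_pmat <- vapply(scans, function(s) s$log_p, numeric(ncol(G)))
    comb <- combine_pvalues(log_pmat, gnull, snp_ids = ctx$genotypes$snp_ids)
    data.frame(rho = r, snp_id = comb$snp_id,
               p_marginal = scans[[1L]]$p, p_multivariate = comb$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "scenario") <- scenario
  out
}
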