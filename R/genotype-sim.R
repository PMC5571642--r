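# Genotype simulation: two ancestral populations, one parent-child generation,
# Mendelian gene dropping. SNPs are unlinked biallelic markers; dosages count
# copies of the reference (B) allele.

#' Draw reference-allele frequencies for two ancestral populations
#'
#' Generates two independent sets of `S` reference-allele frequencies, one per
#' ancestral population, each drawn iid Uniform(0.1, 0.9). These define the
#' marker panel used by [simulate_parents()] and [simulate_cohort()].
#'
#' @param S Number of SNPs (positive integer).
#' @param seed Optional integer seed; identical seeds give identical draws.
#' @return An object of class `population_freqs`: a list with elements
#'   `freqs_pop1`, `freqs_pop2` (numeric vectors of length `S`) and `S`.
#' @examples
#' fr <- draw_allele_freqs(100, seed = 1)
#' range(fr$freqs_pop1)
#' @export
draw_allele_freqs <- function(S, seed = NULL) {
  if (!is.numeric(S) || length(S) != 1L || !is.finite(S) || S < 1)
    stop("'S' must be a positive integer")
  S <- as.integer(S)
  if (!is.null(seed)) set.seed(seed)
  structure(
    list(freqs_pop1 = stats::runif(S, 0.1, 0.9),
         freqs_pop2 = stats::runif(S, 0.1, 0.9),
         S = S),
    class = "population_freqs"
  )
}

#' @export
print.population_freqs <- function(x, ...) {
  cat("Allele frequencies for 2 ancestral populations,", x$S, "SNPs\n")
  cat("  pop1: mean", round(mean(x$freqs_pop1), 3),
      " pop2: mean", round(mean(x$freqs_pop2), 3), "\n")
  invisible(x)
}

# Parent-origin labels. In the admixed scenarios families are split in equal
# thirds between the three types; remainders go, deterministically, to
# pop1xpop1 first, then pop2xpop2, then mixed.
.parent_origins <- function(n_families, admixed) {
  if (!admixed) return(rep("pop1xpop1", n_families))
  base <- n_families %/% 3L
  rem <- n_families %% 3L
  counts <- rep(base, 3L) + c(rem >= 1L, rem >= 2L, FALSE)
  rep(c("pop1xpop1", "pop2xpop2", "mixed"), counts)
}

#' Construct genotype data
#'
#' Container for an N x S dosage matrix (0/1/2 copies of the reference allele,
#' `NA` allowed for externally read data) with subject and SNP identifiers and
#' an optional pedigree.
#'
#' @param dosages Integer/numeric N x S matrix with entries in {0, 1, 2, NA}.
#' @param subject_ids Character vector of length N.
#' @param snp_ids Character vector of length S.
#' @param pedigree Optional data frame with one row per subject (columns
#'   `fid`, `iid`, `pat`, `mat`, `role`, `origin`).
#' @return An object of class `genotype_data`.
#' @export
genotype_data <- function(dosages, subject_ids = NULL, snp_ids = NULL,
                          pedigree = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(subject_ids)) subject_ids <- paste0("id", seq_len(nrow(dosages)))
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(dosages)))
  if (length(subject_ids) != nrow(dosages))
    stop("length of 'subject_ids' does not match row count of 'dosages'")
  if (length(snp_ids) != ncol(dosages))
    stop("length of 'snp_ids' does not match column count of 'dosages'")
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad))
    stop("dosages must be 0, 1, 2 or NA; first offending entry at index ",
         which(bad)[1L])
  dimnames(dosages) <- list(subject_ids, snp_ids)
  structure(
    list(dosages = dosages,
         subject_ids = as.character(subject_ids),
         snp_ids = as.character(snp_ids),
         pedigree = pedigree),
    class = "genotype_data"
  )
}

#' @export
print.genotype_data <- function(x, ...) {
  cat("genotype_data:", nrow(x$dosages), "subjects x", ncol(x$dosages), "SNPs\n")
  if (!is.null(x$pedigree))
    cat("  pedigree:", length(unique(x$pedigree$fid)), "families\n")
  nmiss <- sum(is.na(x$dosages))
  if (nmiss > 0) cat("  missing entries:", nmiss, "\n")
  invisible(x)
}

#' @export
dim.genotype_data <- function(x) dim(x$dosages)

# Draw genotypes for one set of subjects under HWE at the given frequencies:
# rows subjects, cols SNPs; freq vector of length S applies column-wise.
.hwe_draw <- function(n, freqs) {
  S <- length(freqs)
  matrix(stats::rbinom(n * S, 2L, rep(freqs, each = n)), nrow = n, ncol = S)
}

#' Simulate parental genotypes
#'
#' Draws two parents per family under Hardy-Weinberg equilibrium within the
#' origin population of each parent. In the admixed scenario the families are
#' split in equal thirds between (pop1 x pop1), (pop2 x pop2) and mixed
#' (one parent from each population); remainders are assigned in that fixed
#' order. In the non-admixed scenario all parents come from population 1.
#'
#' @param n_families Number of families (positive integer).
#' @param freqs A `population_freqs` object.
#' @param admixed Logical; draw the three parent-origin types?
#' @param seed Optional integer seed.
#' @return A `genotype_data` of the 2*`n_families` parents, with a pedigree
#'   whose `origin` column records the family parent-origin type.
#' @export
simulate_parents <- function(n_families, freqs, admixed = FALSE, seed = NULL) {
  if (!is.numeric(n_families) || length(n_families) != 1L || n_families < 1)
    stop("'n_families' must be a positive integer")
  stopifnot(inherits(freqs, "population_freqs"))
  n_families <- as.integer(n_families)
  if (!is.null(seed)) set.seed(seed)

  origin <- .parent_origins(n_families, admixed)
  # population of each parent: parent 1 then parent 2, family-major
  pop1_of <- ifelse(origin == "pop2xpop2", 2L, 1L)
  pop2_of <- ifelse(origin == "pop1xpop1", 1L, 2L)
  pop <- as.vector(rbind(pop1_of, pop2_of))   # length 2*n_families

  n_par <- 2L * n_families
  S <- freqs$S
  dos <- matrix(0L, n_par, S)
  for (p in 1:2) {
    idx <- which(pop == p)
    if (length(idx))
      dos[idx, ] <- .hwe_draw(length(idx),
                              if (p == 1L) freqs$freqs_pop1 else freqs$freqs_pop2)
  }
  fid <- rep(paste0("fam", seq_len(n_families)), each = 2L)
  iid <- paste0(fid, "_p", rep(1:2, n_families))
  ped <- data.frame(fid = fid, iid = iid, pat = "0", mat = "0",
                    role = rep(c("parent1", "parent2"), n_families),
                    origin = rep(origin, each = 2L),
                    stringsAsFactors = FALSE)
  genotype_data(dos, subject_ids = iid, snp_ids = paste0("snp", seq_len(S)),
                pedigree = ped)
}

#' Drop alleles from parents to children
#'
#' Simulates children by Mendelian transmission at unlinked SNPs: each child
#' receives, independently per SNP, one allele sampled uniformly from each
#' parent's two alleles (a parent with dosage d transmits the reference allele
#' with probability d/2). Siblings are conditionally independent given the
#' parents.
#'
#' @param parents A `genotype_data` of parents carrying a pedigree with roles
#'   `parent1`/`parent2` (as produced by [simulate_parents()]).
#' @param children_per_family Number of children to generate in every family.
#' @param seed Optional integer seed.
#' @return A `genotype_data` of the children, with pedigree rows pointing at
#'   the parental IDs and carrying the family `origin`.
#' @export
gene_drop <- function(parents, children_per_family = 1L, seed = NULL) {
  stopifnot(inherits(parents, "genotype_data"))
  ped <- parents$pedigree
  if (is.null(ped) || !all(c("role", "fid") %in% names(ped)))
    stop("malformed pedigree: parents must carry a pedigree with roles")
  if (children_per_family < 1) stop("'children_per_family' must be >= 1")
  children_per_family <- as.integer(children_per_family)
  if (!is.null(seed)) set.seed(seed)

  p1 <- which(ped$role == "parent1")
  p2 <- which(ped$role == "parent2")
  if (length(p1) != length(p2) || !identical(ped$fid[p1], ped$fid[p2]))
    stop("malformed pedigree: each family needs exactly one parent1 and one parent2")
  n_fam <- length(p1)
  S <- ncol(parents$dosages)
  n_child <- n_fam * children_per_family

  fam_of_child <- rep(seq_len(n_fam), each = children_per_family)
  D1 <- parents$dosages[p1[fam_of_child], , drop = FALSE]
  D2 <- parents$dosages[p2[fam_of_child], , drop = FALSE]
  if (anyNA(D1) || anyNA(D2)) stop("missing parental dosage")
  dos <- (matrix(stats::runif(n_child * S), n_child, S) < D1 / 2) +
         (matrix(stats::runif(n_child * S), n_child, S) < D2 / 2)
  storage.mode(dos) <- "integer"

  fid <- ped$fid[p1[fam_of_child]]
  cnum <- rep(seq_len(children_per_family), n_fam)
  iid <- paste0(fid, "_c", cnum)
  cped <- data.frame(fid = fid, iid = iid,
                     pat = ped$iid[p1[fam_of_child]],
                     mat = ped$iid[p2[fam_of_child]],
                     role = "child",
                     origin = ped$origin[p1[fam_of_child]],
                     stringsAsFactors = FALSE)
  genotype_data(dos, subject_ids = iid, snp_ids = parents$snp_ids,
                pedigree = cped)
}

#' Simulate a study cohort under one of four population scenarios
#'
#' Generates a children-only analysis sample of `n_subjects` under the crossed
#' design admixed/non-admixed x related/independent: independent scenarios use
#' `n_subjects` families with one child each, related scenarios use
#' `n_subjects`/4 families with four full sibs each. Parental genomes are
#' drawn from Uniform(0.1, 0.9) population allele frequencies and alleles are
#' dropped down the one-generation pedigree.
#'
#' @param scenario One of `"non-admixed-independent"`, `"non-admixed-related"`,
#'   `"admixed-independent"`, `"admixed-related"`.
#' @param S Number of SNPs.
#' @param seed Optional integer seed.
#' @param n_subjects Number of children in the analysis sample (default 1000;
#'   must be divisible by 4 for related scenarios).
#' @param freqs Optional `population_freqs` to reuse; drawn fresh otherwise.
#' @param include_parents If `TRUE`, parents are appended after the children
#'   (children remain the first `n_subjects` rows).
#' @return A `genotype_data` of the cohort.
#' @examples
#' g <- simulate_cohort("non-admixed-independent", S = 50, seed = 1,
#'                      n_subjects = 40)
#' dim(g)
#' @export
simulate_cohort <- function(scenario = c("non-admixed-independent",
                                         "non-admixed-related",
                                         "admixed-independent",
                                         "admixed-related"),
                            S = 10000L, seed = NULL, n_subjects = 1000L,
                            freqs = NULL, include_parents = FALSE) {
  scenario <- match.arg(scenario)
  if (!is.null(seed)) set.seed(seed)
  admixed <- grepl("^admixed", scenario)
  related <- grepl("related$", scenario)
  cpf <- if (related) 4L else 1L
  if (n_subjects %% cpf != 0L)
    stop("'n_subjects' must be divisible by ", cpf, " for scenario ", scenario)
  n_fam <- n_subjects %/% cpf
  if (is.null(freqs)) freqs <- draw_allele_freqs(S)
  parents <- simulate_parents(n_fam, freqs, admixed = admixed)
  children <- gene_drop(parents, children_per_family = cpf)
  attr(children, "freqs") <- freqs
  attr(children, "scenario") <- scenario
  if (include_parents) {
    dos <- rbind(children$dosages, parents$dosages)
    ped <- rbind(children$pedigree, parents$pedigree)
    out <- genotype_data(dos,
                         subject_ids = c(children$subject_ids, parents$subject_ids),
                         snp_ids = children$snp_ids, pedigree = ped)
    attr(out, "freqs") <- freqs
    attr(out, "scenario") <- scenario
    return(out)
  }
  children
}
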