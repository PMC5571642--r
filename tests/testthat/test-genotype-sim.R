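test_that("allele frequencies are uniform on (0.1, 0.9) and seeded", {
  fr <- draw_allele_freqs(10000, seed = 1)
  expect_true(all(fr$freqs_pop1 > 0.1 & fr$freqs_pop1 < 0.9))
  expect_true(all(fr$freqs_pop2 > 0.1 & fr$freqs_pop2 < 0.9))
  expect_lt(abs(mean(fr$freqs_pop1) - 0.5), 0.02)
  expect_lt(abs(mean(fr$freqs_pop2) - 0.5), 0.02)
  fr2 <- draw_allele_freqs(10000, seed = 1)
  expect_identical(fr, fr2)
  one <- draw_allele_freqs(1, seed = 3)
  expect_length(one$freqs_pop1, 1)
  expect_error(draw_allele_freqs(0), "positive")
})

test_that("admixed parent-origin types split in thirds with a fixed remainder rule", {
  fr <- draw_allele_freqs(5, seed = 2)
  counts_of <- function(nf) {
    p <- simulate_parents(nf, fr, admixed = TRUE, seed = 4)
    table(p$pedigree$origin[p$pedigree$role == "parent1"])
  }
  c300 <- counts_of(300)
  expect_equal(unname(c300[c("pop1xpop1", "pop2xpop2", "mixed")]),
               c(100L, 100L, 100L), ignore_attr = TRUE)
  c301 <- counts_of(301)
  expect_equal(unname(c301[c("pop1xpop1", "pop2xpop2", "mixed")]),
               c(101L, 100L, 100L), ignore_attr = TRUE)
  c302 <- counts_of(302)
  expect_equal(unname(c302[c("pop1xpop1", "pop2xpop2", "mixed")]),
               c(101L, 101L, 100L), ignore_attr = TRUE)
})

test_that("parental genotypes follow the assigned population frequencies", {
  fr <- draw_allele_freqs(500, seed = 5)
  p <- simulate_parents(300, fr, admixed = FALSE, seed = 6)
  expect_true(all(p$pedigree$origin == "pop1xpop1"))
  # sample allele frequency inside a 4-sigma binomial band around p_s
  phat <- colMeans(p$dosages) / 2
  band <- 4 * sqrt(fr$freqs_pop1 * (1 - fr$freqs_pop1) / (2 * 600))
  expect_gt(mean(abs(phat - fr$freqs_pop1) < band), 0.99)
})

test_that("mean dosage is twice the allele frequency", {
  fr <- structure(list(freqs_pop1 = rep(0.1, 2000),
                       freqs_pop2 = rep(0.1, 2000), S = 2000L),
                  class = "population_freqs")
  p <- simulate_parents(5, fr, seed = 7)
  expect_equal(mean(p$dosages), 0.2, tolerance = 0.02)
})

test_that("gene dropping obeys Mendelian transmission", {
  S <- 6000L
  ped <- data.frame(fid = "f1", iid = c("m", "d"), pat = "0", mat = "0",
                    role = c("parent1", "parent2"), origin = "pop1xpop1",
                    stringsAsFactors = FALSE)
  # one parent homozygous reference, the other homozygous alternate:
  # every child is heterozygous with probability 1
  par_fixed <- genotype_data(rbind(rep(2L, S), rep(0L, S)),
                             subject_ids = c("m", "d"), pedigree = ped)
  kid <- gene_drop(par_fixed, children_per_family = 2, seed = 8)
  expect_true(all(kid$dosages == 1L))
  # two heterozygous parents: offspring dosages 0/1/2 with probs 1/4, 1/2, 1/4
  par_het <- genotype_data(rbind(rep(1L, S), rep(1L, S)),
                           subject_ids = c("m", "d"), pedigree = ped)
  kid2 <- gene_drop(par_het, children_per_family = 4, seed = 9)
  props <- as.numeric(table(factor(kid2$dosages, levels = 0:2))) / (4 * S)
  expect_lt(max(abs(props - c(0.25, 0.5, 0.25))), 0.015)
  # pedigree-free input is rejected
  bare <- genotype_data(rbind(rep(1L, 5), rep(1L, 5)))
  expect_error(gene_drop(bare), "pedigree")
})

test_that("cohort simulation honors the four scenario designs", {
  g_ind <- simulate_cohort("non-admixed-independent", S = 40, seed = 10,
                           n_subjects = 48)
  expect_equal(dim(g_ind), c(48L, 40L))
  expect_equal(length(unique(g_ind$pedigree$fid)), 48L)
  g_rel <- simulate_cohort("admixed-related", S = 40, seed = 11,
                           n_subjects = 48)
  expect_equal(dim(g_rel), c(48L, 40L))
  tab <- table(g_rel$pedigree$fid)
  expect_true(all(tab == 4L))
  expect_equal(length(tab), 12L)
  # seeded determinism
  g_rel2 <- simulate_cohort("admixed-related", S = 40, seed = 11,
                            n_subjects = 48)
  expect_identical(g_rel$dosages, g_rel2$dosages)
  expect_error(simulate_cohort("admixed-related", S = 10, n_subjects = 30),
               "divisible")
  expect_error(simulate_cohort("banana", S = 10), "arg")
  withp <- simulate_cohort("non-admixed-related", S = 20, seed = 12,
                           n_subjects = 40, include_parents = TRUE)
  expect_equal(nrow(withp$dosages), 40L + 2L * 10L)
})

test_that("non-admixed cohorts satisfy Hardy-Weinberg proportions", {
  g <- simulate_cohort("non-admixed-independent", S = 4000, seed = 13,
                       n_subjects = 800)
  p <- attr(g, "freqs")$freqs_pop1
  n <- nrow(g$dosages)
  counts <- apply(g$dosages, 2, function(col) tabulate(col + 1L, nbins = 3L))
  expected <- rbind((1 - p)^2, 2 * p * (1 - p), p^2) * n
  chi2 <- colSums((counts - expected)^2 / expected)
  not_rejected <- mean(pchisq(chi2, df = 2, lower.tail = FALSE) > 0.001)
  expect_gte(not_rejected, 0.985)
})
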