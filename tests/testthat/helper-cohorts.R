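# Small cohorts shared across test files. Built once per test run.

tiny_cohort <- local({
  cache <- new.env()
  function(scenario = "non-admixed-independent", S = 300L, n = 120L,
           seed = 101L) {
    key <- paste(scenario, S, n, seed, sep = "|")
    if (is.null(cache[[key]]))
      cache[[key]] <- simulate_cohort(scenario, S = S, seed = seed,
                                      n_subjects = n)
    cache[[key]]
  }
})

# exchangeable correlation matrix helper
exch <- function(R, rho) {
  M <- matrix(rho, R, R)
  diag(M) <- 1
  M
}
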