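# random nested annulus specs for geometry oracles
random_annulus_specs <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    R_out <- runif(1, 60, 110)
    R_in <- runif(1, 0.5, 0.9) * R_out
    d <- runif(1, 0, min(R_out - R_in, R_in))
    frame_spec(R_out, R_in, d)
  })
}

# small generated cohort reused across tests (fixed seed)
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- sample_cohorts(cohort_config(n_cycles = 150, seed = 99))
    cache
  }
})
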