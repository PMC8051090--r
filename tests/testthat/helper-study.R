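# A scaled-down generator configuration for fast unit tests. The full-size
# defaults are exercised by the acceptance suite.
small_config <- function(...) {
  generator_config(
    n_kp = 400, n_kn = 20000, n_b_germline = 200, n_spike = 60,
    depth = 400,
    ...
  )
}

# Cached small bundle shared across test files (generation is seeded, so
# caching does not leak state between tests).
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_study(small_config(), seed = 42)
    cache
  }
})

# Full-size default bundle (the study conditions) for the end-to-end
# recovery checks; cached for the same reason.
default_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_study(generator_config(),
                                                 seed = 101)
    cache
  }
})
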