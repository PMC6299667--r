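# The full-scale study cohort (8 subjects x 20 min, the synthetic_spec()
# defaults) is expensive to build; it is constructed lazily and shared by
# the acceptance tests that need it.

easy_cohort_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- cohort_dataset(generate_cohort(synthetic_spec()))
    }
    cache
  }
})
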