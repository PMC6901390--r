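# Monte-Carlo studies shared between the fitting property tests and the
# acceptance suite; computed once per test run and memoized.
.study_cache <- new.env(parent = emptyenv())

get_recovery_study <- function() {
  if (is.null(.study_cache$recovery))
    .study_cache$recovery <- recovery_study(n_rep = 20, noise_sd = 0.02,
                                            seed = 1)
  .study_cache$recovery
}

get_mechanism_study <- function() {
  if (is.null(.study_cache$mechanism))
    .study_cache$mechanism <- mechanism_study(n_trials = 20, noise_sd = 0.02,
                                              seed = 1)
  .study_cache$mechanism
}
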