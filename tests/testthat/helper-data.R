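# Shared synthetic study bundle (built once per test session). Five planted
# microRNAs with large effects against low noise, plus confounded covariates,
# so the screening pipeline has a known right answer.
.sitmir_test_cache <- new.env(parent = emptyenv())

planted_mirs <- function() mir_panel()[c(5, 19, 33, 47, 61)]

planted_config <- function(seed = 301) {
  cohort_config(n_participants = 600, n_days = 5, seed = seed,
                true_effect_mirs = stats::setNames(rep(3, 5), planted_mirs()),
                expr_noise_sd = 0.4)
}

get_planted_bundle <- function() {
  if (is.null(.sitmir_test_cache$bundle)) {
    .sitmir_test_cache$bundle <- generate_study(planted_config())
  }
  .sitmir_test_cache$bundle
}
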