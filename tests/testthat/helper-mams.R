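# Shared fixtures: small replicate stores and the reference designs for the
# three-comparator, two-stage worked example.

small_store <- function(R = 2000, K = 3, J = 2, n_max = 20, seed = 11) {
  mams_store(R = R, K = K, J = J, n_max = n_max, seed = seed)
}

# effect sizes of the two worked-example scenarios
scenario_deltas <- function(scenario) {
  if (scenario == 1) list(delta1 = 0.545, delta0 = 0.178)
  else list(delta1 = 1, delta0 = 0)
}

# A design whose stage-1 boundaries force every arm into stage 2.
forced_continuation_design <- function(K = 3, n = 5, terminal = 1.96,
                                       rule = "simultaneous",
                                       statistic = "z") {
  mams_design(K = K, J = 2, n = n, e = c(10, terminal), f = c(-10, terminal),
              rule = rule, statistic = statistic)
}
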