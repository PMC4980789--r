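# shared fixtures built in code

# a fully specified genotype record
toy_record <- function(states = c("WILD_HOM", "HET", "VAR_HOM",
                                  "WILD_HOM", "HET"),
                       group = "trial", dose = 1) {
  genotype_record("T01", group, dose,
                  stats::setNames(states, cyp_loci()))
}

# small planted-effect dataset for model tests
planted_dataset <- function(n = 400, strength = 3, noise_sd = 0.3,
                            seed = 5) {
  make_cohort(cohort_spec(n, effect_matrix = example_effect_matrix(strength),
                          noise_sd = noise_sd, seed = seed))
}

# sweep-profile GSN spec: frugal fit used for the protocol tests
sweep_gsn <- function() {
  model_gsn(epochs = 40, calibration_rounds = 1,
            calibration_chains = 32, calibration_keep = 40)
}

# toy dataset with unique feature rows (continuous jitter on dose) so
# nearest-neighbour self-retrieval is unambiguous
unique_feature_dataset <- function(n = 40, seed = 9) {
  ds <- planted_dataset(n = n, seed = seed)
  set.seed(seed)
  ds$X[, "dose"] <- ds$X[, "dose"] + stats::runif(n)
  ds
}
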