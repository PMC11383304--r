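# Shared fixture builders for the test suite. Everything is generated in
# code at test time; sizes are kept small so the suite runs on one CPU.

# a 12-phoneme inventory spanning all five manner classes
test_inventory <- function() {
  ft <- phoneme_features()
  ft[ft$phoneme %in% c("AA", "IY", "UW", "EH", "L", "R", "M", "N",
                       "S", "Z", "T", "K"), ]
}

# a 6-phoneme inventory for the cheapest decode runs
mini_inventory <- function() {
  ft <- phoneme_features()
  ft[ft$phoneme %in% c("AA", "IY", "L", "M", "S", "T"), ]
}

# small synthetic cohort of PRP sets (full pipeline)
make_cohort <- function(alpha = 1, n_participants = 4, dur_s = 40,
                        noise_sd = 1.5, seed = 1, inventory = mini_inventory(),
                        kappa = 0, latency_shift = 0, n_electrodes = 61,
                        store_epochs = FALSE, group = "test",
                        informative_electrodes = NULL) {
  truth <- gen_phoneme_templates(inventory, n_electrodes = n_electrodes,
                                 alpha = alpha, kappa = kappa,
                                 latency_shift = latency_shift,
                                 seed = seed,
                                 informative_electrodes = informative_electrodes)
  simulate_cohort(truth, n_participants = n_participants, dur_s = dur_s,
                  noise_sd = noise_sd, min_count = 5, cap = 30,
                  seed = seed + 100, group = group,
                  store_epochs = store_epochs)
}

# direct one-way fixed-effects ANOVA F on a list of per-group vectors
# (independent oracle for the separability F statistic)
anova_f_oracle <- function(groups) {
  k <- length(groups)
  ns <- lengths(groups)
  N <- sum(ns)
  gm <- mean(unlist(groups))
  msb <- sum(ns * (vapply(groups, mean, 0) - gm)^2) / (k - 1)
  msw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0)) / (N - k)
  msb / msw
}

# brute-force Spearman: average ranks then Pearson (oracle for rdm_corr)
spearman_oracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
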