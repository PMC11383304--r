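test_that("preprocess resamples higher-rate recordings to the target grid", {
  mont <- standard_montage(include_references = TRUE)
  raw_rate <- 256
  tt <- seq(1 / raw_rate, 30, by = 1 / raw_rate)
  x <- sin(2 * pi * 8 * tt)                       # passband tone
  X <- matrix(rep(x, nrow(mont)), nrow(mont), byrow = TRUE)
  X[match(c("TP9", "TP10"), mont$name), ] <- 0    # quiet references
  rec <- new_recording(X, raw_rate, mont)
  out <- preprocess(rec, target_rate = 128)
  expect_equal(out$rate, 128)
  expect_equal(ncol(out$data), length(tt) / 2)
  mid <- 1500:2500
  expect_lt(abs(sd(out$data[1, mid]) / sd(x)), 1.1)
  expect_gt(abs(sd(out$data[1, mid]) / sd(x)), 0.9)
})

test_that("band-pass preprocessing has the specified frequency response", {
  rate <- 128
  tt <- seq(1 / rate, 40, by = 1 / rate)
  h <- phondecode:::design_bandpass(1, 15, rate)
  gain_db <- function(f) {
    x <- sin(2 * pi * f * tt)
    y <- as.numeric(signal::filter(h, 1, x))
    mid <- seq(1500, length(tt) - 500)
    20 * log10(sd(y[mid]) / sd(x[mid]))
  }
  expect_lt(gain_db(0.5), -20)            # stopband below the band
  expect_lt(abs(gain_db(8)), 1)           # passband within +-1 dB
  expect_lt(gain_db(25), -20)             # stopband above the band
})

test_that("preprocess re-references, drops reference channels, and kills DC", {
  mont <- standard_montage(include_references = TRUE)
  rate <- 128
  nt <- 20 * rate
  # identical constant offset on every channel
  X <- matrix(5, nrow(mont), nt)
  rec <- new_recording(X, rate, mont)
  out <- preprocess(rec, reference_channels = c("TP9", "TP10"))
  expect_equal(nrow(out$data), 61)
  expect_false(any(c("TP9", "TP10") %in% out$channels$name))
  expect_lt(max(abs(out$data[, 1000:2000])), 1e-6)
  expect_error(preprocess(rec, reference_channels = "M1"), "reference")
  expect_error(preprocess(rec, hi_hz = 70), "Nyquist")
})

test_that("phoneme selection applies the strict count rule and capping", {
  ev <- data.frame(
    label = c(rep("A", 500), rep("B", 319), rep("C", 320)),
    onset = seq(0, by = 0.1, length.out = 1139),
    duration = 0.08)
  track <- new_annotation_track(ev)
  plan <- select_phonemes(track, min_count = 319, cap = 319,
                          exclude = character(0))
  expect_setequal(plan$plan$label, c("A", "C"))   # B fails the strict > test
  expect_equal(plan$plan$n_use[plan$plan$label == "A"], 319)
  expect_equal(plan$plan$n_use[plan$plan$label == "C"], 319)   # capped
  expect_lte(max(plan$plan$n_use), 319)
  # exclusion removes a label regardless of count
  plan2 <- select_phonemes(track, min_count = 319, cap = 319, exclude = "A")
  expect_setequal(plan2$plan$label, "C")
  # empty result errors
  expect_error(select_phonemes(track, min_count = 600, cap = 600), "no phoneme")
})

test_that("PRPs average epochs exactly and capping is seed-deterministic", {
  inv <- mini_inventory()
  truth <- gen_phoneme_templates(inv, n_electrodes = 8, alpha = 1, seed = 5)
  # noiseless single-phoneme recording: PRP equals the template
  track <- new_annotation_track(
    data.frame(label = rep("AA", 4), onset = c(1, 2, 3, 4), duration = 0.08),
    inventory = truth$labels)
  rec <- gen_continuous_eeg(truth, track, noise_sd = 0, seed = 1)
  plan <- select_phonemes(track, min_count = 2, cap = 10,
                          exclude = character(0))
  ps <- compute_prp(rec, track, plan, seed = 1, participant_id = "p1")
  expect_equal(unname(ps$prp[["AA"]]), unname(truth$templates[["AA"]]),
               tolerance = 1e-9)
  expect_equal(ps$times[1], 0)
  expect_equal(length(ps$times), 64)
  # +-v alternating noise on identical epochs cancels in the average
  rec2 <- rec
  v <- matrix(stats::rnorm(8 * 64), 8, 64)
  for (i in seq_len(4)) {
    s0 <- round(track$events$onset[i] * rec$rate)
    sign <- if (i %% 2 == 1) 1 else -1
    rec2$data[, (s0 + 1):(s0 + 64)] <- rec2$data[, (s0 + 1):(s0 + 64)] +
      sign * v
  }
  ps2 <- compute_prp(rec2, track, plan, seed = 1)
  expect_equal(ps2$prp[["AA"]], ps$prp[["AA"]], tolerance = 1e-9)
  # capping: different seeds select different subsets, same seed identical
  track3 <- gen_phoneme_sequence(30, truth$labels, zipf_s = 0, seed = 3)
  rec3 <- gen_continuous_eeg(truth, track3, noise_sd = 1, seed = 4)
  plan3 <- select_phonemes(track3, min_count = 5, cap = 10,
                           exclude = character(0))
  a <- compute_prp(rec3, track3, plan3, seed = 1)
  b <- compute_prp(rec3, track3, plan3, seed = 2)
  c <- compute_prp(rec3, track3, plan3, seed = 1)
  expect_identical(a$prp, c$prp)
  expect_false(identical(a$prp, b$prp))
  # with all counts at or below the cap the seed is irrelevant
  plan4 <- select_phonemes(track3, min_count = 5, cap = 10000,
                           exclude = character(0))
  d1 <- compute_prp(rec3, track3, plan4, seed = 1)
  d2 <- compute_prp(rec3, track3, plan4, seed = 99)
  expect_identical(d1$prp, d2$prp)
})

test_that("PRP linearity: concatenated recordings give count-weighted means", {
  inv <- mini_inventory()
  truth <- gen_phoneme_templates(inv, n_electrodes = 6, alpha = 1, seed = 8)
  mk <- function(n_ev, seed) {
    track <- new_annotation_track(
      data.frame(label = rep("S", n_ev),
                 onset = seq(1, by = 1, length.out = n_ev),
                 duration = 0.08),
      inventory = truth$labels)
    rec <- gen_continuous_eeg(truth, track, noise_sd = 1, seed = seed)
    list(rec = rec, track = track)
  }
  a <- mk(3, 1); b <- mk(5, 2)
  plan <- function(tr) select_phonemes(tr, min_count = 2, cap = 100,
                                       exclude = character(0))
  pa <- compute_prp(a$rec, a$track, plan(a$track), seed = 1)
  pb <- compute_prp(b$rec, b$track, plan(b$track), seed = 1)
  # concatenate the recordings and shift b's events
  nta <- ncol(a$rec$data)
  cat_rec <- new_recording(cbind(a$rec$data, b$rec$data), a$rec$rate,
                           a$rec$channels, a$rec$adjacency)
  evb <- b$track$events
  evb$onset <- evb$onset + nta / a$rec$rate
  cat_track <- new_annotation_track(rbind(a$track$events, evb),
                                    inventory = truth$labels)
  pc <- compute_prp(cat_rec, cat_track, plan(cat_track), seed = 1)
  weighted <- (3 * pa$prp[["S"]] + 5 * pb$prp[["S"]]) / 8
  expect_equal(pc$prp[["S"]], weighted, tolerance = 1e-9)
})

test_that("separability F matches a direct ANOVA oracle per cell", {
  inv <- mini_inventory()
  truth <- gen_phoneme_templates(inv, n_electrodes = 4, alpha = 1, seed = 2)
  track <- gen_phoneme_sequence(30, truth$labels, zipf_s = 0, seed = 3)
  rec <- gen_continuous_eeg(truth, track, noise_sd = 1, seed = 4)
  plan <- select_phonemes(track, min_count = 4, cap = 20,
                          exclude = character(0))
  ps <- compute_prp(rec, track, plan, seed = 1)
  fc <- separability_f(ps)
  expect_true(all(fc$f >= 0))
  # oracle: direct one-way ANOVA on a handful of (electrode, time) cells
  for (cell in list(c(1, 5), c(2, 20), c(4, 40), c(3, 64))) {
    groups <- lapply(ps$phonemes, function(l) ps$epochs[[l]][, cell[1], cell[2]])
    expect_equal(fc$f_cells[cell[1], cell[2]], anova_f_oracle(groups),
                 tolerance = 1e-8)
  }
  # curve is the electrode average
  expect_equal(fc$f, colMeans(fc$f_cells), tolerance = 1e-12)
})

test_that("F statistic is calibrated under the null and detects structure", {
  # null: identical templates (alpha = 0), only noise differs
  inv <- mini_inventory()
  truth0 <- gen_phoneme_templates(inv, n_electrodes = 3, alpha = 0, seed = 6)
  track <- gen_phoneme_sequence(420, truth0$labels, zipf_s = 0, seed = 7,
                                mean_dur_ms = 80)
  rec <- gen_continuous_eeg(truth0, track, noise_sd = 1, seed = 8)
  plan <- select_phonemes(track, min_count = 100, cap = 500,
                          exclude = character(0))
  ps <- compute_prp(rec, track, plan, seed = 1)
  expect_gte(sum(ps$n_used), 3000)
  f0 <- separability_f(ps)
  expect_gt(mean(f0$f), 0.8)
  expect_lt(mean(f0$f), 1.2)
  # planted structure: F well above 1 at the component peak
  truth1 <- gen_phoneme_templates(inv, n_electrodes = 3, alpha = 1, seed = 6)
  rec1 <- gen_continuous_eeg(truth1, track, noise_sd = 0.5, seed = 8)
  ps1 <- compute_prp(rec1, track, plan, seed = 1)
  f1 <- separability_f(ps1)
  peak_idx <- which.min(abs(f1$times - truth1$component_peak_time))
  expect_gt(f1$f[peak_idx], 3)
  # a cohort with larger alpha dominates one with smaller alpha
  expect_gt(mean(f1$f), mean(f0$f))
})

test_that("F curves of higher-alpha cohorts dominate across replicates", {
  inv <- mini_inventory()
  wins <- 0
  for (r in 1:5) {
    seed <- 200 + 13 * r
    track <- gen_phoneme_sequence(180, inv$phoneme, zipf_s = 0, seed = seed)
    plan <- select_phonemes(track, min_count = 50, cap = 150,
                            exclude = character(0))
    mean_f <- vapply(c(0.5, 1), function(alpha) {
      truth <- gen_phoneme_templates(inv, n_electrodes = 3, alpha = alpha,
                                     seed = seed)
      rec <- gen_continuous_eeg(truth, track, noise_sd = 1,
                                seed = seed + 1)
      mean(separability_f(compute_prp(rec, track, plan, seed = 1))$f)
    }, 0)
    if (mean_f[2] > mean_f[1]) wins <- wins + 1
  }
  expect_gte(wins, 5)
})
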