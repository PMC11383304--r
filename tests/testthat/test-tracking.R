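test_that("gammatone spectrogram localizes tones and respects the rate", {
  rate <- 16000
  tt <- seq(0, 0.8, by = 1 / rate)
  tone <- sin(2 * pi * 1000 * tt)
  spec <- gammatone_spectrogram(tone, rate, n_channels = 48, f_lo = 100,
                                f_hi = 4000)
  expect_equal(spec$rate, 1000)
  expect_equal(ncol(spec$env), floor(length(tone) * 1000 / rate))
  # energy peaks in the channel whose center frequency is nearest 1 kHz
  en <- rowMeans(spec$env[, 100:700])
  expect_equal(which.max(en), which.min(abs(spec$cf - 1000)), tolerance = 1)
  # silence maps to (numerically) zero envelopes
  sil <- gammatone_spectrogram(numeric(8000), rate, n_channels = 16,
                               f_lo = 100, f_hi = 4000)
  expect_lt(max(sil$env), 1e-10)
  expect_error(gammatone_spectrogram(c(1, NA, 0), rate), "non-finite")
  expect_error(gammatone_spectrogram(tone, 8000, f_hi = 5000), "rate")
})

test_that("compression and banding partition the filterbank", {
  set.seed(1)
  env <- matrix(stats::runif(256 * 100), 256, 100)
  cf <- exp(seq(log(20), log(5000), length.out = 256))
  spec <- structure(list(env = env, cf = cf, rate = 1000),
                    class = "spectrogram")
  cb <- compress_and_band(spec, exponent = 0.6, n_bands = 8)
  expect_equal(nrow(cb$bands), 8)
  # every channel in exactly one band
  expect_equal(sort(unique(cb$assignment)), 1:8)
  expect_equal(length(cb$assignment), 256)
  expect_equal(colSums(cb$bands), colSums(env^0.6), tolerance = 1e-9)
  # exponent 1 with one band reduces to the channel sum
  cb1 <- compress_and_band(spec, exponent = 1, n_bands = 1)
  expect_equal(as.numeric(cb1$bands), colSums(env), tolerance = 1e-12)
  # homogeneity of degree 0.6
  spec2 <- spec; spec2$env <- 3 * env
  cb2 <- compress_and_band(spec2, exponent = 0.6, n_bands = 8)
  expect_equal(cb2$bands, 3^0.6 * cb$bands, tolerance = 1e-9)
  expect_error(compress_and_band(spec, exponent = 0), "positive")
})

test_that("edge detector rectifies and scales linearly below rectification", {
  # monotone decreasing envelope: zero onsets
  dec <- matrix(seq(1, 0, length.out = 200), 1, 200, byrow = TRUE)
  expect_equal(max(edge_detect(dec, rate = 128)), 0)
  # a step yields a prompt single peak; doubling the step doubles it
  stepm <- matrix(c(rep(0, 100), rep(1, 100)), 1)
  on1 <- edge_detect(stepm, rate = 128)
  on2 <- edge_detect(2 * stepm, rate = 128)
  pk <- which.max(on1[1, ])
  expect_gte(pk, 101)
  expect_lte(pk, 101 + round(0.010 * 128))
  expect_equal(2 * on1, on2, tolerance = 1e-12)
})

test_that("boosting recovers a planted kernel from noiseless tracking data", {
  pred <- gen_acoustic_predictors(30, 128, seed = 5)
  K <- gen_true_trf(8, 2, peak_ms = 80, seed = 6)
  eeg <- phondecode:::trf_convolve(K, pred$envelope, 128)
  fit <- boosting_trf(pred$envelope, eeg, rate = 128, step_frac = 0.02,
                      max_iter = 3000, patience = 200)
  expect_true(all(fit$r > 0.95))
  expect_gt(stats::cor(as.vector(fit$kernel), as.vector(K)), 0.9)
  expect_equal(dim(fit$kernel), c(8, 78, 2))
  expect_equal(range(fit$lags_ms), c(-101.5625, 500), tolerance = 0.1)
  # training L1 error descends monotonically by construction: the
  # recovered kernel must beat the null prediction on the training span
  expect_gt(mean(fit$r, na.rm = TRUE), 0)
  expect_error(boosting_trf(pred$envelope, eeg[, 1:100], rate = 128),
               "mismatch")
  expect_error(boosting_trf(pred$envelope, eeg, rate = 128, max_iter = 0),
               "at least one")
})

test_that("boosting finds no tracking in predictor-independent noise", {
  set.seed(7)
  pred <- gen_acoustic_predictors(20, 128, seed = 8)
  eeg <- matrix(stats::rnorm(3 * ncol(pred$envelope)), 3)
  fit <- boosting_trf(pred$envelope, eeg, rate = 128, step_frac = 0.02,
                      max_iter = 300, patience = 20)
  r <- fit$r[!is.na(fit$r)]
  expect_lt(abs(mean(r)), 2 * max(sd(r), 0.05) / sqrt(max(length(r), 1)) + 0.1)
})

test_that("unique contributions subtract correlations per electrode", {
  mk_model <- function(r, ch = c("A", "B", "C")) {
    structure(list(kernel = array(0, c(2, 5, 3)), lags_ms = 1:5, r = r,
                   fold_r = NULL, folds = 5, channels = ch),
              class = "trf_model")
  }
  full <- mk_model(c(0.5, 0.4, 0.1))
  red <- mk_model(c(0.3, 0.4, 0.2))
  dm <- unique_contribution(full, red)
  expect_equal(dm$delta_r, c(0.2, 0, -0.1), tolerance = 1e-12)
  # identical models: exactly zero
  expect_equal(unique_contribution(full, full)$delta_r, rep(0, 3))
  # antisymmetry under swapping full/reduced
  expect_equal(unique_contribution(red, full)$delta_r, -dm$delta_r)
  expect_error(unique_contribution(full, mk_model(c(0.1, 0.2, 0.3),
                                                  ch = c("A", "B", "D"))),
               "mismatch")
})

test_that("ROI definition detects planted tracking topographies", {
  mont <- standard_montage()
  adj <- montage_adjacency(mont)
  ne <- nrow(mont)
  driven <- which(adj[match("Cz", mont$name), ] | mont$name == "Cz")
  set.seed(10)
  maps <- matrix(stats::rnorm(16 * ne, 0, 0.02), 16, ne)
  maps[, driven] <- maps[, driven] + 0.06
  colnames(maps) <- mont$name
  roi <- define_roi(maps, adj, n_perm = 500, seed = 2)
  expect_gte(length(intersect(roi$roi, driven)),
             ceiling(0.8 * length(driven)))
  # reruns with the same seed give the identical ROI
  roi2 <- define_roi(maps, adj, n_perm = 500, seed = 2)
  expect_identical(roi$roi, roi2$roi)
  # pure-noise maps: empty ROI most of the time (checked via one draw)
  noise <- matrix(stats::rnorm(16 * ne, 0, 0.02), 16, ne)
  expect_warning(r0 <- define_roi(noise, adj, n_perm = 300, seed = 3),
                 "empty ROI")
  expect_equal(length(r0$roi), 0)
  expect_equal(roi_score(unique_contribution(
    structure(list(kernel = array(0, c(1, 1, ne)), lags_ms = 0,
                   r = rep(0.2, ne), folds = 5, channels = mont$name),
              class = "trf_model"),
    structure(list(kernel = array(0, c(1, 1, ne)), lags_ms = 0,
                   r = rep(0.1, ne), folds = 5, channels = mont$name),
              class = "trf_model")), roi$roi), 0.1, tolerance = 1e-12)
})

test_that("joint envelope+onset models attribute unique contributions", {
  # EEG driven by both predictor families: full model beats each reduced
  # model and both delta-r values are positive on the driven electrodes
  pred <- gen_acoustic_predictors(25, 128, seed = 11)
  Kenv <- gen_true_trf(8, 2, peak_ms = 100, seed = 12)
  Kons <- gen_true_trf(8, 2, peak_ms = 60, seed = 13)
  eeg <- phondecode:::trf_convolve(Kenv, pred$envelope, 128) +
         phondecode:::trf_convolve(Kons, pred$onset, 128)
  both <- rbind(pred$envelope, pred$onset)
  fit_full <- boosting_trf(both, eeg, rate = 128, step_frac = 0.02,
                           max_iter = 2500, patience = 150)
  fit_env <- boosting_trf(pred$envelope, eeg, rate = 128, step_frac = 0.02,
                          max_iter = 2500, patience = 150)
  fit_ons <- boosting_trf(pred$onset, eeg, rate = 128, step_frac = 0.02,
                          max_iter = 2500, patience = 150)
  expect_true(all(fit_full$r > fit_env$r))
  expect_true(all(fit_full$r > fit_ons$r))
  d_ons <- unique_contribution(fit_full, fit_env)   # onset's unique share
  d_env <- unique_contribution(fit_full, fit_ons)
  expect_true(all(d_ons$delta_r > 0))
  expect_true(all(d_env$delta_r > 0))
  # the onset-kernel estimate peaks near the planted latency
  onset_part <- fit_full$kernel[9:16, , , drop = FALSE]
  prof <- apply(abs(onset_part), 2, sum)
  peak_lag <- fit_full$lags_ms[which.max(prof)]
  expect_lt(abs(peak_lag - 60), 25)
})
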