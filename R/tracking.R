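#' Gammatone spectrogram of a speech waveform
#'
#' Filters mono audio with a bank of 4th-order gammatone filters at
#' ERB-spaced center frequencies between `f_lo` and `f_hi`, takes the
#' Hilbert envelope of each band, and resamples the envelopes to
#' `out_rate` (1 kHz by default, regardless of the input rate).
#'
#' @param wave numeric vector, mono audio.
#' @param rate input sampling rate in Hz, must be >= `2 * f_hi`.
#' @param n_channels number of filterbank channels (default 256).
#' @param f_lo,f_hi cut-off frequencies in Hz (default 20-5000).
#' @param out_rate output envelope rate in Hz (default 1000).
#' @return object of class `spectrogram`: `env` (channels x time, >= 0),
#'   `cf` center frequencies, `rate` = `out_rate`.
#' @export
gammatone_spectrogram <- function(wave, rate, n_channels = 256, f_lo = 20,
                                  f_hi = 5000, out_rate = 1000) {
  if (any(!is.finite(wave))) stop("audio contains non-finite samples")
  if (rate < 2 * f_hi) stop("audio rate must be >= 2 * f_hi")
  # ERB-rate spaced center frequencies (Glasberg & Moore)
  erb <- function(f) 21.4 * log10(1 + 0.00437 * f)
  erb_inv <- function(e) (10^(e / 21.4) - 1) / 0.00437
  cf <- erb_inv(seq(erb(f_lo), erb(f_hi), length.out = n_channels))
  fr <- .rational(out_rate / rate)
  nt_out <- floor(length(wave) * out_rate / rate)
  rows <- lapply(cf, function(f) {
    b <- 1.019 * 24.7 * (4.37 * f / 1000 + 1)        # ERB bandwidth
    dur <- min(max(12 / b, 0.01), 0.2)
    tk <- seq(0, dur, by = 1 / rate)
    k <- tk^3 * exp(-2 * pi * b * tk) * cos(2 * pi * f * tk)
    k <- k / sqrt(sum(k^2))
    y <- fft_conv(wave, k)
    e <- Mod(analytic_signal(y))
    e <- as.numeric(signal::resample(e, fr$p, fr$q))
    length(e) <- nt_out                              # trim/pad to the grid
    e[is.na(e)] <- 0
    e
  })
  env <- do.call(rbind, rows)
  env[env < 0] <- 0
  structure(list(env = env, cf = cf, rate = out_rate), class = "spectrogram")
}

#' Compress and band a spectrogram into envelope predictors
#'
#' Raises the spectrogram to `exponent` (amplitude compression emulating
#' cochlear nonlinearity) and sums the channels into `n_bands`
#' logarithmically spaced frequency bands; every channel is assigned to
#' exactly one band.
#'
#' @param spec a `spectrogram` (or a non-negative channels x time matrix
#'   with center frequencies in attribute/`cf`).
#' @param exponent compression exponent, > 0 (default 0.6).
#' @param n_bands number of output bands (default 8).
#' @return list with `bands` (n_bands x time matrix), `edges` (band
#'   boundary frequencies), `assignment` (channel -> band), `rate`.
#' @export
compress_and_band <- function(spec, exponent = 0.6, n_bands = 8) {
  if (exponent <= 0) stop("exponent must be positive")
  env <- spec$env
  cf <- spec$cf
  if (any(env < 0)) stop("spectrogram must be non-negative")
  comp <- env^exponent
  edges <- exp(seq(log(min(cf)), log(max(cf)), length.out = n_bands + 1))
  assignment <- pmin(pmax(findInterval(cf, edges, rightmost.closed = TRUE), 1),
                     n_bands)
  bands <- rowsum(comp, assignment)
  rownames(bands) <- paste0("band", seq_len(nrow(bands)))
  list(bands = bands, edges = edges, assignment = assignment,
       rate = spec$rate)
}

#' Auditory edge detection (acoustic onsets)
#'
#' Per channel, the onset signal is the half-wave-rectified difference
#' between the current value and a short leaky integration of the recent
#' past: `onset[t] = max(0, x[t] - z[t])` with
#' `z[t] = lambda * z[t-1] + (1 - lambda) * x[t-1]` and
#' `lambda = exp(-1 / (rate * tau))`. A sustained level yields zero after
#' the transient; an upward step yields a single decaying peak right after
#' the step, scaling linearly with step height.
#'
#' @param spec channels x time matrix (compressed spectrogram), or a
#'   `spectrogram` object.
#' @param rate sampling rate in Hz (taken from the object if available).
#' @param tau leaky-integrator time constant in seconds (default 0.02).
#' @return matrix of the same size, all values >= 0.
#' @export
edge_detect <- function(spec, rate = NULL, tau = 0.02) {
  if (inherits(spec, "spectrogram")) {
    rate <- rate %||% spec$rate
    spec <- spec$env
  }
  if (is.null(rate)) stop("`rate` required for a plain matrix")
  spec <- as.matrix(spec)
  lambda <- exp(-1 / (rate * tau))
  nt <- ncol(spec)
  z <- matrix(0, nrow(spec), nt)
  if (nt > 1) {
    z[, 1] <- spec[, 1]
    for (t in 2:nt)
      z[, t] <- lambda * z[, t - 1] + (1 - lambda) * spec[, t - 1]
  }
  pmax(spec - z, 0)
}

#' Estimate a multivariate TRF by cross-validated boosting
#'
#' Sparse coordinate-descent boosting of the kernel mapping stimulus
#' predictor bands to each EEG electrode over the lag window: starting from
#' a zero kernel, the (band, lag) cell and sign whose `step`-sized update
#' most reduces the training L1 error is applied repeatedly, and training
#' stops when the validation L1 error stops improving (the kernel at the
#' validation minimum is kept). Time is partitioned into `segments`
#' contiguous segments grouped into `folds` test folds; within each fold
#' one training segment (rotated across folds) serves as the validation
#' set. Fold kernels are averaged into the reported kernel; per-electrode
#' prediction accuracy `r` is the Pearson correlation between predicted
#' and observed EEG concatenated over each fold's held-out segments.
#'
#' @param predictors band x time matrix at the EEG rate (stack envelope
#'   and onset bands for a joint model), or a `predictor_set` (stacked
#'   automatically).
#' @param eeg electrodes x time matrix (or a `recording`).
#' @param rate sampling rate in Hz (required for plain matrices).
#' @param lags_ms lag window in ms, default `c(-100, 500)`.
#' @param folds number of cross-validation folds (default 5).
#' @param segments number of contiguous segments (default 15).
#' @param step_frac boosting step size as a fraction of the response SD
#'   (default 0.005).
#' @param max_iter maximum boosting iterations per electrode and fold.
#' @param patience validation-error patience (iterations).
#' @param basis_ms width in ms of the Hamming basis window the sparse
#'   coefficients are convolved with (kernels are sums of basis-shaped
#'   bumps rather than isolated spikes, as in the boosting TRF
#'   literature); 0 disables the basis. Default 50.
#' @param seed integer seed (controls nothing stochastic at present but is
#'   recorded for provenance).
#' @return object of class `trf_model`: `kernel` (band x lag x electrode),
#'   `lags_ms`, `r` (per-electrode held-out correlation), `fold_r`
#'   (electrode x fold), `folds`.
#' @export
boosting_trf <- function(predictors, eeg, rate = NULL,
                         lags_ms = c(-100, 500), folds = 5, segments = 15,
                         step_frac = 0.005, max_iter = 3000, patience = 100,
                         basis_ms = 50, seed = 1) {
  if (inherits(predictors, "predictor_set")) {
    rate <- rate %||% predictors$rate
    predictors <- rbind(predictors$envelope, predictors$onset)
  }
  if (inherits(eeg, "recording")) {
    rate <- rate %||% eeg$rate
    eeg <- eeg$data
  }
  if (is.null(rate)) stop("`rate` required")
  predictors <- as.matrix(predictors)
  eeg <- as.matrix(eeg)
  if (ncol(predictors) != ncol(eeg))
    stop("predictor/EEG length mismatch")
  if (max_iter < 1) stop("at least one boosting iteration is required")
  nt <- ncol(eeg)
  lag_samp <- seq(round(lags_ms[1] * rate / 1000),
                  round(lags_ms[2] * rate / 1000))
  seg_id <- as.integer(cut(seq_len(nt), breaks = segments, labels = FALSE))
  fold_of_seg <- rep(seq_len(folds), length.out = segments)

  # basis trick: boosting a kernel constrained to sums of basis-shaped
  # bumps is equivalent to boosting spikes on basis-smoothed predictors
  # and convolving the coefficient kernel with the basis afterwards
  nbas <- if (basis_ms > 0) max(1, round(basis_ms / 1000 * rate)) else 1
  if (nbas > 1) {
    basis <- signal::hamming(nbas)
    basis <- basis / sum(basis)
    center <- floor((nbas - 1) / 2)
    smooth1 <- function(x) {
      y <- fft_conv(c(x, rep(0, nbas)), basis)
      y[(1 + center):(length(x) + center)]
    }
    fit_predictors <- t(apply(predictors, 1, smooth1))
  } else fit_predictors <- predictors

  nb <- nrow(predictors); nl <- length(lag_samp); ne <- nrow(eeg)
  kernel <- array(0, dim = c(nb, nl, ne))
  fold_r <- matrix(NA_real_, ne, folds)
  pred_all <- matrix(NA_real_, ne, nt)

  for (f in seq_len(folds)) {
    test_seg <- which(fold_of_seg == f)
    train_seg <- setdiff(seq_len(segments), test_seg)
    val_seg <- train_seg[1 + (f - 1) %% length(train_seg)]
    fit_seg <- setdiff(train_seg, val_seg)
    idx_fit <- which(seg_id %in% fit_seg)
    idx_val <- which(seg_id %in% val_seg)
    idx_test <- which(seg_id %in% test_seg)
    for (e in seq_len(ne)) {
      y <- eeg[e, ]
      step <- step_frac * stats::sd(y[idx_fit])
      if (step == 0) step <- step_frac
      C <- boost_trf_cpp(fit_predictors, y, lag_samp,
                         idx_fit - 1L, idx_val - 1L,
                         step, as.integer(max_iter), as.integer(patience))
      K <- if (nbas > 1) t(apply(C, 1, smooth1)) else C
      kernel[, , e] <- kernel[, , e] + K / folds
      pred <- trf_predict_cpp(fit_predictors, C, lag_samp)
      pred_all[e, idx_test] <- pred[idx_test]
      if (stats::sd(pred[idx_test]) > 0)
        fold_r[e, f] <- stats::cor(pred[idx_test], y[idx_test])
    }
  }
  r <- vapply(seq_len(ne), function(e) {
    ok <- !is.na(pred_all[e, ])
    if (sum(ok) < 3 || stats::sd(pred_all[e, ok]) == 0) return(NA_real_)
    stats::cor(pred_all[e, ok], eeg[e, ok])
  }, 0)
  attr(kernel, "lags_ms") <- lag_samp / rate * 1000
  structure(list(kernel = kernel, lags_ms = lag_samp / rate * 1000,
                 r = r, fold_r = fold_r, folds = folds, segments = segments,
                 rate = rate, step_frac = step_frac, seed = seed,
                 channels = rownames(eeg)),
            class = "trf_model")
}

#' @export
print.trf_model <- function(x, ...) {
  cat(sprintf("Boosting TRF: %d bands x %d lags x %d electrodes; mean r = %.3f\n",
              dim(x$kernel)[1], dim(x$kernel)[2], dim(x$kernel)[3],
              mean(x$r, na.rm = TRUE)))
  invisible(x)
}

#' Unique predictor contribution to neural tracking
#'
#' Per-electrode difference in held-out prediction correlation between the
#' full encoding model and a reduced model omitting the predictor family of
#' interest: `delta_r = r_full - r_reduced`.
#'
#' @param full,reduced `trf_model` objects fitted on the same electrodes
#'   and fold structure.
#' @return object of class `delta_r_map`: `delta_r` per electrode plus the
#'   two r vectors.
#' @export
unique_contribution <- function(full, reduced) {
  stopifnot(inherits(full, "trf_model"), inherits(reduced, "trf_model"))
  if (length(full$r) != length(reduced$r) ||
      !identical(full$channels, reduced$channels))
    stop("electrode mismatch between models")
  if (full$folds != reduced$folds) stop("fold structure mismatch")
  structure(list(delta_r = full$r - reduced$r, r_full = full$r,
                 r_reduced = reduced$r, channels = full$channels),
            class = "delta_r_map")
}

#' Define the neural-tracking region of interest
#'
#' Pools the per-participant delta-r topographies of all participants and
#' identifies electrodes whose delta-r is significantly greater than zero
#' with a one-tailed one-sample cluster-mass permutation test (sign-flip
#' null). The ROI is the union of electrodes in clusters with corrected
#' p < `alpha`.
#'
#' @param delta_maps matrix, participants x electrodes (e.g., stacked
#'   `delta_r` vectors).
#' @param adjacency electrode adjacency matrix.
#' @param n_perm permutations (default 10000).
#' @param seed integer seed.
#' @param alpha cluster-level significance threshold.
#' @return list with `roi` (electrode indices), `channels` if dimnames are
#'   available, and the underlying `cluster_result`.
#' @export
define_roi <- function(delta_maps, adjacency, n_perm = 10000, seed = 1,
                       alpha = 0.05) {
  res <- cluster_test(delta_maps, design = "one-sample", tail = "greater",
                      n_perm = n_perm, seed = seed, adjacency = adjacency)
  sig <- Filter(function(cl) cl$p < alpha, res$clusters)
  roi <- sort(unique(unlist(lapply(sig, `[[`, "electrodes"))))
  if (!length(roi)) warning("no significant electrodes: empty ROI")
  list(roi = roi,
       channels = if (!is.null(colnames(delta_maps))) colnames(delta_maps)[roi],
       result = res)
}

#' Per-participant tracking score
#'
#' Mean delta-r over the ROI electrodes.
#'
#' @param delta_map a `delta_r_map`.
#' @param roi integer electrode indices.
#' @return scalar score.
#' @export
roi_score <- function(delta_map, roi) {
  if (!length(roi)) stop("empty ROI")
  mean(delta_map$delta_r[roi])
}
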