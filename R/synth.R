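#' Generate feature-structured phoneme response templates
#'
#' Builds the planted ground truth for recovery tests: each phoneme's
#' noiseless evoked template is a shared base response plus
#' `alpha * sum_f featval(p, f) * component_f + alpha * idiosyncratic(p)`,
#' where `featval` is the +-1 coding of the phoneme's \[syllabic\],
#' \[sonorant\], \[continuant\] values and each feature component has a
#' distinct spatial pattern and temporal kernel. The three temporal kernels
#' overlap around a common component peak time so that, at that latency,
#' Euclidean distances between noiseless templates mirror the 3-feature
#' dissimilarity structure. `kappa` spatially smooths all patterns across
#' the electrode layout (larger values blur the topography, making
#' information more distributed).
#'
#' @param feature_table data.frame as from [phoneme_features()] restricted
#'   to the inventory to simulate.
#' @param n_electrodes number of electrodes (uses the first `n` channels of
#'   [standard_montage()]).
#' @param n_times samples per template (default 64, i.e. 0.5 s at 128 Hz).
#' @param alpha distinctiveness scale, >= 0; 0 collapses all templates onto
#'   the shared base.
#' @param kappa spatial blur, >= 0 (dimensionless; kernel width
#'   `0.15 * kappa` in layout units where the head radius is 0.5).
#' @param seed integer seed; fully determines all draws.
#' @param rate sampling rate the templates are defined on (Hz).
#' @param latency_shift group latency shift delta in ms applied when the
#'   templates are inserted into continuous EEG.
#' @param amplitude peak scale of the feature components, in microvolts.
#' @param informative_electrodes optional integer count: confine the
#'   feature components to the `n` electrodes closest to the vertex plus
#'   temporal sites (used by electrode-selection recovery tests); `NULL`
#'   uses all electrodes.
#' @return object of class `ground_truth` with `templates` (named list of
#'   electrode x time matrices), the component descriptions, and the
#'   parameters.
#' @export
gen_phoneme_templates <- function(feature_table, n_electrodes = 61,
                                  n_times = 64, alpha = 1, kappa = 0,
                                  seed = 1, rate = 128, latency_shift = 0,
                                  amplitude = 1.5,
                                  informative_electrodes = NULL) {
  if (alpha < 0) stop("alpha must be >= 0")
  if (kappa < 0) stop("kappa must be >= 0")
  feats <- c("syllabic", "sonorant", "continuant")
  if (!all(feats %in% names(feature_table))) stop("unknown feature label")
  mont <- standard_montage()
  mont <- mont[seq_len(n_electrodes), , drop = FALSE]
  pts <- as.matrix(mont[, c("x", "y")])
  labels <- feature_table$phoneme
  tt <- (seq_len(n_times) - 1) / rate

  smooth_spatial <- function(w, width) {
    if (width <= 0) return(w)
    d2 <- as.matrix(stats::dist(pts))^2
    K <- exp(-d2 / (2 * width^2))
    K <- K / rowSums(K)
    as.numeric(K %*% w)
  }

  with_seed(seed, {
    # shared base response: smooth bump common to all phonemes
    base_spat <- smooth_spatial(stats::rnorm(n_electrodes), 0.12)
    base_temp <- exp(-(tt - 0.15)^2 / (2 * 0.08^2))
    base <- amplitude * 0.5 * outer(base_spat / max(abs(base_spat)), base_temp)

    centers <- c(0.18, 0.20, 0.22)
    widths <- c(0.06, 0.07, 0.08)
    mask <- rep(1, n_electrodes)
    if (!is.null(informative_electrodes)) {
      mask <- rep(0, n_electrodes)
      mask[seq_len(min(informative_electrodes, n_electrodes))] <- 1
    }
    components <- lapply(1:3, function(f) {
      s <- stats::rnorm(n_electrodes) * mask
      s <- smooth_spatial(s, 0.08 + 0.15 * kappa)  # blur spreads beyond mask
      s <- s / sqrt(sum(s^2))
      k <- exp(-(tt - centers[f])^2 / (2 * widths[f]^2))
      amplitude * outer(s, k)
    })
    comp_norm <- mean(vapply(components, function(m) sqrt(sum(m^2)), 0))
    idio <- lapply(labels, function(p) {
      m <- outer(smooth_spatial(stats::rnorm(n_electrodes) * mask,
                                0.08 + 0.15 * kappa),
                 exp(-(tt - stats::runif(1, 0.12, 0.3))^2 / (2 * 0.07^2)))
      m / sqrt(sum(m^2)) * 0.25 * comp_norm
    })
    names(idio) <- labels

    fv <- 2 * as.matrix(feature_table[, feats]) - 1   # {0,1} -> {-1,+1}
    templates <- lapply(seq_along(labels), function(i) {
      m <- base
      for (f in 1:3) m <- m + alpha * fv[i, f] * components[[f]]
      m <- m + alpha * idio[[labels[i]]]
      rownames(m) <- mont$name
      m
    })
    names(templates) <- labels

    structure(list(templates = templates, labels = labels,
                   channels = mont$name, montage = mont, times = tt,
                   rate = rate, alpha = alpha, kappa = kappa,
                   latency_shift = latency_shift, noise_sd = NULL,
                   true_trf = NULL, components = components,
                   component_peak_time = 0.2, feature_table = feature_table,
                   seed = seed),
              class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(paste0("Ground truth: %d phoneme templates, %d electrodes x ",
                     "%d samples (alpha=%g, kappa=%g, delta=%g ms)\n"),
              length(x$templates), length(x$channels), length(x$times),
              x$alpha, x$kappa, x$latency_shift))
  invisible(x)
}

#' Generate a Zipf-like phoneme sequence
#'
#' Draws consecutive phoneme events whose labels follow a Zipf-type
#' frequency distribution (`p_k` proportional to `k^-zipf_s` over the
#' inventory in order). The default exponent 0.6 puts the most frequent
#' label's share near 10% for a 32-label inventory, mirroring the skew of
#' natural speech where the schwa dominates. Event durations are gamma
#' distributed with mean `mean_dur_ms`; events tile the total duration
#' without gaps.
#'
#' @param total_dur_s total duration in seconds.
#' @param inventory character vector of labels (frequency rank order).
#' @param zipf_s Zipf exponent, >= 0 (0 gives near-uniform counts).
#' @param mean_dur_ms mean phone duration in ms.
#' @param seed integer seed.
#' @return an `annotation_track`.
#' @export
gen_phoneme_sequence <- function(total_dur_s, inventory, zipf_s = 0.6,
                                 mean_dur_ms = 80, seed = 1) {
  if (total_dur_s <= 0) stop("total duration must be positive")
  if (!length(inventory)) stop("empty inventory")
  n_events <- ceiling(total_dur_s / (mean_dur_ms / 1000) * 1.3)
  with_seed(seed, {
    shape <- 8
    durs <- stats::rgamma(n_events, shape = shape,
                          rate = shape / (mean_dur_ms / 1000))
    onsets <- cumsum(c(0, durs[-n_events]))
    keep <- onsets + durs <= total_dur_s
    durs <- durs[keep]; onsets <- onsets[keep]
    p <- seq_along(inventory)^(-zipf_s)
    p <- p / sum(p)
    labels <- sample(inventory, length(onsets), replace = TRUE, prob = p)
    new_annotation_track(
      data.frame(label = labels, onset = onsets, duration = durs,
                 stringsAsFactors = FALSE),
      inventory = inventory)
  })
}

#' Generate synthetic acoustic predictors
#'
#' Eight band envelopes of low-pass-filtered rectified noise plus the
#' corresponding onset bands obtained by the shared auditory edge detector
#' ([edge_detect()]); a stand-in for audiobook-derived gammatone band
#' predictors with the same non-negativity and smoothness properties.
#'
#' @param total_dur_s duration in seconds, > 0.
#' @param rate_hz sampling rate, >= 64 Hz.
#' @param seed integer seed.
#' @param n_bands number of bands (default 8).
#' @return object of class `predictor_set`: `envelope` and `onset`
#'   (band x time matrices, both >= 0), `rate`, `bands`.
#' @export
gen_acoustic_predictors <- function(total_dur_s, rate_hz = 128, seed = 1,
                                    n_bands = 8) {
  if (total_dur_s <= 0) stop("duration must be positive")
  if (rate_hz < 64) stop("rate must be >= 64 Hz")
  nt <- round(total_dur_s * rate_hz)
  with_seed(seed, {
    bf <- signal::butter(2, min(20 / (rate_hz / 2), 0.9), type = "low")
    env <- t(vapply(seq_len(n_bands), function(b) {
      x <- abs(stats::rnorm(nt))
      y <- as.numeric(signal::filter(bf, x))
      pmax(y, 0)
    }, numeric(nt)))
    onset <- edge_detect(env, rate = rate_hz)
    new_predictor_set(env, onset, rate_hz,
                      bands = paste0("band", seq_len(n_bands)))
  })
}

#' Predictor set constructor
#'
#' @param envelope,onset band x time matrices (non-negative, equal size).
#' @param rate sampling rate in Hz.
#' @param bands band names.
#' @return object of class `predictor_set`.
#' @export
new_predictor_set <- function(envelope, onset, rate, bands = NULL) {
  stopifnot(all(dim(envelope) == dim(onset)))
  if (any(envelope < 0) || any(onset < 0))
    stop("predictor values must be >= 0")
  bands <- bands %||% paste0("band", seq_len(nrow(envelope)))
  rownames(envelope) <- rownames(onset) <- bands
  structure(list(envelope = envelope, onset = onset, rate = rate,
                 bands = bands), class = "predictor_set")
}

#' Generate a ground-truth temporal response function kernel
#'
#' Smooth kernels (Gaussian bumps over lag) per predictor band and
#' electrode, with per-(band, electrode) amplitudes; mass is confined to
#' `driven_electrodes` so that tracking recovery tests know which
#' electrodes carry signal.
#'
#' @param n_bands number of predictor bands the kernel applies to.
#' @param n_electrodes number of electrodes.
#' @param lags_ms lag window, default `c(-100, 500)`.
#' @param rate sampling rate (Hz).
#' @param peak_ms center of the kernel bump in ms.
#' @param driven_electrodes indices of electrodes receiving the kernel
#'   (others get zero rows); default all.
#' @param seed integer seed.
#' @return array `n_bands x n_lags x n_electrodes` with attributes
#'   `lags_ms` (lag axis) and `peak_ms`.
#' @export
gen_true_trf <- function(n_bands, n_electrodes, lags_ms = c(-100, 500),
                         rate = 128, peak_ms = 80,
                         driven_electrodes = seq_len(n_electrodes),
                         seed = 1) {
  lag_samp <- seq(round(lags_ms[1] * rate / 1000),
                  round(lags_ms[2] * rate / 1000))
  lags <- lag_samp / rate * 1000
  with_seed(seed, {
    K <- array(0, dim = c(n_bands, length(lags), n_electrodes))
    for (e in driven_electrodes) {
      for (b in seq_len(n_bands)) {
        amp <- stats::rnorm(1, 1, 0.3)
        width <- stats::runif(1, 25, 45)
        K[b, , e] <- amp * exp(-(lags - peak_ms)^2 / (2 * width^2))
      }
    }
    attr(K, "lags_ms") <- lags
    attr(K, "peak_ms") <- peak_ms
    K
  })
}

# Convolve stacked predictors (bands x time) with a TRF kernel
# (bands x lags x electrodes); returns electrodes x time.
trf_convolve <- function(kernel, predictors, rate) {
  lags <- attr(kernel, "lags_ms")
  lag_samp <- round(lags * rate / 1000)
  nb <- dim(kernel)[1]; ne <- dim(kernel)[3]
  nt <- ncol(predictors)
  stopifnot(nrow(predictors) == nb)
  y <- matrix(0, ne, nt)
  for (i in seq_along(lag_samp)) {
    l <- lag_samp[i]
    src <- seq_len(nt) - l
    ok <- src >= 1 & src <= nt
    Pl <- matrix(0, nb, nt)
    Pl[, ok] <- predictors[, src[ok], drop = FALSE]
    y <- y + t(kernel[, i, , drop = FALSE][, 1, ]) %*% Pl
  }
  y
}

#' Generate continuous EEG with planted structure
#'
#' Sums (i) each phoneme event's template inserted at
#' `onset + latency_shift`, (ii) the TRF-predicted response to the acoustic
#' predictors when a ground-truth kernel is attached, and (iii) 1/f (pink)
#' background noise of standard deviation `noise_sd` per channel. Events
#' superpose linearly.
#'
#' @param truth a `ground_truth` from [gen_phoneme_templates()]; its
#'   optional `true_trf` field (see [gen_true_trf()]) drives the tracking
#'   component.
#' @param annotations an `annotation_track`; labels must have templates.
#' @param predictors optional `predictor_set` at the EEG rate (required if
#'   `truth$true_trf` is set; stacked as envelope rows then onset rows, or
#'   envelope only if the kernel has 8 rows).
#' @param noise_sd pink-noise standard deviation in microvolts.
#' @param seed integer seed.
#' @param include_references append mastoid channels `TP9`/`TP10`
#'   containing noise only (for preprocessing round-trips).
#' @return a `recording` at the truth's sampling rate.
#' @export
gen_continuous_eeg <- function(truth, annotations, predictors = NULL,
                               noise_sd = 1, seed = 1,
                               include_references = FALSE) {
  stopifnot(inherits(truth, "ground_truth"))
  rate <- truth$rate
  bad <- setdiff(unique(annotations$events$label), truth$labels)
  if (length(bad)) stop("no template for label(s): ", paste(bad, collapse = ", "))
  dur <- max(annotations$events$onset + annotations$events$duration)
  if (!is.null(predictors)) dur <- max(dur, ncol(predictors$envelope) / rate)
  nt <- ceiling((dur + 0.6) * rate)
  ne <- length(truth$channels)
  X <- matrix(0, ne, nt)
  n_times <- length(truth$times)
  shift <- truth$latency_shift / 1000
  for (i in seq_len(nrow(annotations$events))) {
    ev <- annotations$events[i, ]
    s0 <- round((ev$onset + shift) * rate)
    if (s0 < 0 || s0 + n_times > nt) next
    idx <- (s0 + 1):(s0 + n_times)
    X[, idx] <- X[, idx] + truth$templates[[ev$label]]
  }
  if (!is.null(truth$true_trf)) {
    if (is.null(predictors)) stop("true_trf set but no predictors supplied")
    if (abs(predictors$rate - rate) > 1e-9)
      stop("predictors must be at the EEG rate")
    nb <- dim(truth$true_trf)[1]
    P <- if (nb == nrow(predictors$envelope)) predictors$envelope
         else rbind(predictors$envelope, predictors$onset)
    if (nrow(P) != nb) stop("kernel/predictor band mismatch")
    ptime <- min(ncol(P), nt)
    X[, seq_len(ptime)] <- X[, seq_len(ptime)] +
      trf_convolve(truth$true_trf, P[, seq_len(ptime), drop = FALSE], rate)
  }
  mont <- truth$montage
  if (include_references) {
    extra <- standard_montage(include_references = TRUE)
    mont <- rbind(mont, extra[extra$name %in% c("TP9", "TP10"), ])
    X <- rbind(X, matrix(0, 2, nt))
    ne <- ne + 2
  }
  if (noise_sd > 0) {
    X <- X + with_seed(seed, {
      t(vapply(seq_len(ne), function(e) noise_sd * pink_noise(nt), numeric(nt)))
    })
  }
  new_recording(X, rate, mont)
}

# printed group parameters for the participant covariates
.covariate_params <- list(
  younger = list(wave_i = c(0.404, 0.184), wave_v = c(0.284, 0.164),
                 pta_124 = c(5.625, 3.918), win_snr_loss = c(3.426, 1.187),
                 ospan = c(48.375, 13.318), moca = c(27.708, 1.706),
                 ehf_12_5 = c(-2.5, 5)),
  middle = list(wave_i = c(0.266, 0.152), wave_v = c(0.279, 0.130),
                pta_124 = c(10.708, 3.976), win_snr_loss = c(4.505, 1.339),
                ospan = c(43.750, 17.586), moca = c(27.350, 1.954),
                ehf_12_5 = c(15, 5))
)

# location of a zero-truncated normal whose truncated mean equals `target`
.trunc_loc <- function(target, s) {
  f <- function(mu) {
    a <- -mu / s
    mu + s * stats::dnorm(a) / (1 - stats::pnorm(a)) - target
  }
  stats::uniroot(f, c(target - 3 * s, target))$root
}

#' Generate participant covariates
#'
#' Draws audiological and cognitive covariates from Gaussian distributions
#' with the group means and standard deviations reported for younger and
#' middle-aged normal-hearing adults (ABR wave I and wave V amplitudes,
#' pure-tone average over 1/2/4 kHz, WIN SNR loss, OSPAN, MoCA, EHF
#' threshold at 12.5 kHz). ABR amplitudes are physically positive: they are
#' drawn from zero-truncated normals whose location is adjusted so the
#' post-truncation mean equals the printed group mean.
#'
#' @param group `"younger"` or `"middle"`.
#' @param n number of participants, > 0.
#' @param seed integer seed.
#' @return data.frame with `participant_id`, `group` and one column per
#'   covariate.
#' @export
gen_participant_covariates <- function(group = c("younger", "middle"), n,
                                       seed = 1) {
  group <- match.arg(group)
  if (n <= 0) stop("n must be positive")
  par <- .covariate_params[[group]]
  with_seed(seed, {
    draw <- function(nm) {
      m <- par[[nm]][1]; s <- par[[nm]][2]
      if (nm %in% c("wave_i", "wave_v")) {
        mu <- .trunc_loc(m, s)
        x <- stats::rnorm(n, mu, s)
        while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), mu, s)
        x
      } else stats::rnorm(n, m, s)
    }
    out <- data.frame(
      participant_id = sprintf("%s_%03d", group, seq_len(n)),
      group = group, stringsAsFactors = FALSE)
    for (nm in names(par)) out[[nm]] <- draw(nm)
    out
  })
}

#' Simulate a cohort of PRP sets through the full pipeline
#'
#' Convenience generator used throughout the recovery tests: for each
#' synthetic participant, generates a phoneme sequence, synthesizes
#' continuous EEG from the shared ground-truth templates (participant-
#' specific noise), and derives capped PRPs. All participants of a cohort
#' share the planted templates (a common "language"), while noise and
#' instance subsets differ.
#'
#' @param truth a `ground_truth`.
#' @param n_participants cohort size.
#' @param dur_s recording duration per participant, seconds.
#' @param noise_sd pink-noise SD in microvolts.
#' @param min_count,cap phoneme selection rule passed to [select_phonemes()]
#'   (scaled-down defaults for simulation-length recordings).
#' @param seed integer seed.
#' @param group label stored on each PRP set's participant id.
#' @param store_epochs keep epoch pools in the PRP sets.
#' @return list of `prp_set`, one per participant.
#' @export
simulate_cohort <- function(truth, n_participants = 8, dur_s = 90,
                            noise_sd = 1, min_count = 20, cap = 40,
                            seed = 1, group = "cohort",
                            store_epochs = FALSE) {
  lapply(seq_len(n_participants), function(i) {
    s <- sub_seed(seed, i)
    track <- gen_phoneme_sequence(dur_s, truth$labels, zipf_s = 0.3,
                                  mean_dur_ms = 80, seed = s)
    rec <- gen_continuous_eeg(truth, track, noise_sd = noise_sd,
                              seed = sub_seed(s, 1))
    plan <- select_phonemes(track, min_count = min_count, cap = cap,
                            exclude = character(0))
    suppressMessages(
      compute_prp(rec, track, plan, seed = sub_seed(s, 2),
                  participant_id = sprintf("%s_%02d", group, i),
                  store_epochs = store_epochs))
  })
}
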