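#' Construct a continuous EEG recording object
#'
#' @param data numeric matrix, electrodes x time, in microvolts.
#' @param rate sampling rate in Hz.
#' @param channels data.frame with at least `name`, `x`, `y` (2-D positions),
#'   one row per row of `data`.
#' @param adjacency optional logical electrode adjacency matrix; computed
#'   from the channel positions by [montage_adjacency()] when `NULL`.
#' @return object of class `recording`.
#' @export
new_recording <- function(data, rate, channels, adjacency = NULL) {
  data <- as.matrix(data)
  stopifnot(rate > 0, nrow(channels) == nrow(data))
  if (!all(is.finite(data))) stop("recording contains non-finite values")
  if (is.null(adjacency)) adjacency <- montage_adjacency(channels)
  stopifnot(isTRUE(all(adjacency == t(adjacency))), !any(diag(adjacency)))
  rownames(data) <- channels$name
  structure(list(data = data, rate = rate, channels = channels,
                 adjacency = adjacency),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples at %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate))
  invisible(x)
}

#' Construct a phoneme annotation track
#'
#' @param events data.frame with columns `label`, `onset` (s), `duration` (s),
#'   onsets strictly increasing and durations positive.
#' @param inventory label set; defaults to the labels present.
#' @return object of class `annotation_track`.
#' @export
new_annotation_track <- function(events, inventory = NULL) {
  stopifnot(all(c("label", "onset", "duration") %in% names(events)))
  if (is.unsorted(events$onset, strictly = TRUE))
    stop("onsets must be strictly increasing")
  if (any(events$duration <= 0)) stop("durations must be positive")
  inventory <- inventory %||% sort(unique(events$label))
  if (!all(events$label %in% inventory))
    stop("event label outside the inventory")
  structure(list(events = events, inventory = inventory),
            class = "annotation_track")
}

# Minimum-phase FIR from a linear-phase prototype via the real cepstrum
# (homomorphic method); magnitude response is preserved to numerical
# accuracy, group delay collapses toward zero.
minimum_phase_fir <- function(h) {
  n <- length(h)
  nfft <- stats::nextn(8 * n, 2)
  H <- abs(stats::fft(c(h, rep(0, nfft - n))))
  H <- pmax(H, max(H) * 1e-8)
  cep <- Re(stats::fft(log(H), inverse = TRUE)) / nfft
  fold <- numeric(nfft)
  fold[1] <- cep[1]
  fold[2:(nfft / 2)] <- 2 * cep[2:(nfft / 2)]
  fold[nfft / 2 + 1] <- cep[nfft / 2 + 1]
  hm <- Re(stats::fft(exp(stats::fft(fold)), inverse = TRUE)) / nfft
  hm[seq_len(n)]
}

# causal FIR band-pass design: windowed sinc (Hamming) converted to
# minimum phase. Cutoffs at the -6 dB points.
design_bandpass <- function(lo_hz, hi_hz, rate, transition_hz = 1) {
  ntaps <- ceiling(3.3 * rate / transition_hz)
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  h <- signal::fir1(ntaps - 1, c(lo_hz, hi_hz) / (rate / 2), type = "pass")
  minimum_phase_fir(h)
}

#' Preprocess a continuous EEG recording
#'
#' Resamples to `target_rate` (polyphase), band-pass filters with a causal
#' minimum-phase windowed-sinc FIR, then re-references to the mean of the
#' named reference channels and drops them. Mirrors the standard continuous
#' speech EEG pipeline: downsample to 128 Hz, band-pass 1-15 Hz, mastoid
#' reference.
#'
#' @param raw a `recording`.
#' @param lo_hz,hi_hz band edges in Hz.
#' @param target_rate output sampling rate in Hz.
#' @param reference_channels channel names averaged as the reference and
#'   removed from the output; `NULL` skips re-referencing.
#' @param transition_hz filter transition bandwidth in Hz (width of the
#'   roll-off around each edge).
#' @return preprocessed `recording` at `target_rate`.
#' @export
preprocess <- function(raw, lo_hz = 1, hi_hz = 15, target_rate = 128,
                       reference_channels = c("TP9", "TP10"),
                       transition_hz = 1) {
  stopifnot(inherits(raw, "recording"))
  if (hi_hz >= target_rate / 2) stop("hi_hz must be below the Nyquist rate")
  if (raw$rate < 2 * hi_hz) stop("raw rate too low for the requested band")
  x <- raw$data
  if (raw$rate != target_rate) {
    fr <- .rational(target_rate / raw$rate)
    x <- t(apply(x, 1, function(ch) signal::resample(ch, fr$p, fr$q)))
  }
  h <- design_bandpass(lo_hz, hi_hz, target_rate, transition_hz)
  x <- t(apply(x, 1, function(ch) signal::filter(h, 1, ch)))
  channels <- raw$channels
  if (!is.null(reference_channels)) {
    ri <- match(reference_channels, channels$name)
    if (anyNA(ri)) stop("missing reference channel: ",
                        paste(reference_channels[is.na(ri)], collapse = ", "))
    ref <- colMeans(x[ri, , drop = FALSE])
    x <- sweep(x, 2, ref)
    x <- x[-ri, , drop = FALSE]
    channels <- channels[-ri, , drop = FALSE]
  }
  new_recording(x, target_rate, channels,
                adjacency = montage_adjacency(channels))
}

.rational <- function(x, tol = 1e-9) {
  for (q in 1:10000) {
    p <- round(x * q)
    if (abs(p / q - x) < tol) return(list(p = p, q = q))
  }
  stop("cannot approximate resampling ratio")
}

#' Select phonemes for PRP derivation
#'
#' Applies the inventory filtering rule: keep labels whose instance count
#' strictly exceeds `min_count` and that are not in `exclude`; labels kept
#' with more than `cap` instances are flagged for capping, i.e. only a
#' seeded random subset of exactly `cap` instances enters the average
#' (the subset is drawn by [compute_prp()] using its seed). The defaults
#' reproduce the published rule: `min_count = cap = 319`, excluding the
#' highly frequent schwa AH.
#'
#' @param track an `annotation_track`.
#' @param min_count keep labels with count strictly greater than this.
#' @param cap maximum number of instances averaged per label.
#' @param exclude labels removed regardless of count.
#' @return object of class `prp_plan`: data.frame of kept labels with
#'   `count` and `n_use`, plus the `cap`.
#' @export
select_phonemes <- function(track, min_count = 319, cap = 319,
                            exclude = "AH") {
  stopifnot(min_count >= 1, cap >= min_count)
  counts <- table(track$events$label)
  keep <- names(counts)[counts > min_count & !(names(counts) %in% exclude)]
  if (!length(keep)) stop("no phoneme satisfies the selection rule")
  plan <- data.frame(label = keep,
                     count = as.integer(counts[keep]),
                     stringsAsFactors = FALSE)
  plan$n_use <- pmin(plan$count, cap)
  plan <- plan[order(plan$label), ]
  rownames(plan) <- NULL
  structure(list(plan = plan, cap = cap, min_count = min_count,
                 exclude = exclude), class = "prp_plan")
}

#' Compute phoneme-related potentials
#'
#' Epochs the recording from each selected phoneme onset over
#' `[onset, onset + window)` (half-open, 0-based sample indexing) and
#' averages the epochs per phoneme. Labels above the instance cap are
#' down-sampled to exactly `cap` instances with the given seed. Epochs
#' extending beyond the end of the recording are dropped (and counted).
#'
#' @param rec preprocessed `recording` (128 Hz for the standard 61 x 64 grid).
#' @param track an `annotation_track`.
#' @param plan a `prp_plan` from [select_phonemes()].
#' @param window epoch window in seconds, default `c(0, 0.5)`.
#' @param seed integer seed controlling the capping subsets.
#' @param participant_id optional identifier carried in the result.
#' @param store_epochs keep the per-instance epoch pools (needed by
#'   [separability_f()]).
#' @return object of class `prp_set`: `phonemes` (ordered labels), `prp`
#'   (label -> electrode x time matrix), `epochs` (label -> instance x
#'   electrode x time array, if stored), `n_used`, `times`, `channels`,
#'   `adjacency`.
#' @export
compute_prp <- function(rec, track, plan, window = c(0, 0.5), seed = 1,
                        participant_id = NA_character_, store_epochs = TRUE) {
  stopifnot(inherits(rec, "recording"), inherits(plan, "prp_plan"))
  nsamp <- round((window[2] - window[1]) * rec$rate)
  n_time <- ncol(rec$data)
  labels <- plan$plan$label
  prp <- list(); epochs <- list(); n_used <- integer(0)
  dropped <- 0L
  for (i in seq_along(labels)) {
    lab <- labels[i]
    onsets <- track$events$onset[track$events$label == lab] + window[1]
    starts <- round(onsets * rec$rate)            # 0-based start sample
    ok <- starts >= 0 & (starts + nsamp) <= n_time
    dropped <- dropped + sum(!ok)
    starts <- starts[ok]
    if (!length(starts)) stop("no valid epochs for phoneme ", lab)
    if (length(starts) > plan$cap) {
      starts <- with_seed(sub_seed(seed, i),
                          sort(sample(starts, plan$cap)))
    }
    pool <- array(0, dim = c(length(starts), nrow(rec$data), nsamp))
    for (j in seq_along(starts))
      pool[j, , ] <- rec$data[, (starts[j] + 1):(starts[j] + nsamp)]
    prp[[lab]] <- apply(pool, c(2, 3), mean)
    dimnames(prp[[lab]]) <- list(rec$channels$name, NULL)
    if (store_epochs) epochs[[lab]] <- pool
    n_used[lab] <- length(starts)
  }
  if (dropped > 0)
    message(dropped, " epoch(s) beyond the recording end were dropped")
  structure(list(participant_id = participant_id, phonemes = labels,
                 prp = prp, epochs = if (store_epochs) epochs else NULL,
                 n_used = n_used,
                 times = window[1] + (seq_len(nsamp) - 1) / rec$rate,
                 channels = rec$channels$name, adjacency = rec$adjacency,
                 seed = seed),
            class = "prp_set")
}

#' @export
print.prp_set <- function(x, ...) {
  cat(sprintf("PRP set (%s): %d phonemes, %d electrodes x %d time points\n",
              x$participant_id, length(x$phonemes),
              length(x$channels), length(x$times)))
  invisible(x)
}

#' Time-resolved phoneme-separability F statistic
#'
#' At each (electrode, time) cell, computes the one-way fixed-effects F
#' statistic across single epochs grouped by phoneme (between-phoneme mean
#' square over within-phoneme mean square), then averages across
#' electrodes to yield the F-vs-time curve. Large values indicate that
#' phoneme identity separates the single-epoch responses well at that
#' latency.
#'
#' @param prpset a `prp_set` computed with `store_epochs = TRUE`.
#' @return object of class `f_curve`: `f` (curve over time), `times`,
#'   and `f_cells` (electrode x time F matrix).
#' @export
separability_f <- function(prpset) {
  if (is.null(prpset$epochs)) stop("epoch pools required (store_epochs = TRUE)")
  labs <- prpset$phonemes
  if (length(labs) < 2) stop("need at least 2 phonemes")
  ns <- vapply(prpset$epochs, function(a) dim(a)[1], 0L)
  if (any(ns < 2)) stop("need at least 2 epochs per phoneme")
  k <- length(labs)
  N <- sum(ns)
  dims <- dim(prpset$epochs[[1]])[2:3]
  gm <- matrix(0, dims[1], dims[2])          # grand sum
  ssb <- matrix(0, dims[1], dims[2])
  ssw <- matrix(0, dims[1], dims[2])
  means <- lapply(labs, function(l) {
    a <- prpset$epochs[[l]]
    apply(a, c(2, 3), mean)
  })
  names(means) <- labs
  for (l in labs) gm <- gm + means[[l]] * ns[[l]]
  gm <- gm / N
  for (l in labs) {
    a <- prpset$epochs[[l]]
    m <- means[[l]]
    ssb <- ssb + ns[[l]] * (m - gm)^2
    dev <- sweep(a, c(2, 3), m)
    ssw <- ssw + apply(dev^2, c(2, 3), sum)
  }
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  if (any(msw == 0)) {
    warning("zero within-phoneme variance at some cells; F set to +Inf")
  }
  f_cells <- msb / msw
  structure(list(f = colMeans(f_cells), times = prpset$times,
                 f_cells = f_cells, df1 = k - 1, df2 = N - k),
            class = "f_curve")
}
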