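#' DeepLIFT attribution with the Rescale rule
#'
#' Backpropagates contribution scores from the pre-softmax score of the
#' target class to the input grid, relative to a baseline input (default
#' all-zero, the natural resting reference after high-pass filtering).
#' Linear layers pass multipliers through their weights; ELU
#' nonlinearities use the Rescale rule (slope between the activation at
#' input and at baseline). Contributions are signed and satisfy
#' completeness: they sum to the difference between the target's
#' pre-softmax score at the input and at the baseline.
#'
#' @param model trained `eegnet_model` (or a raw parameter list).
#' @param prp_input electrode x time matrix on the model's input grid.
#' @param target_class class label (matched against `model$labels`) or
#'   1-based class index.
#' @param baseline electrode x time matrix; default all zeros.
#' @return electrode x time contribution matrix.
#' @export
deeplift_rescale <- function(model, prp_input, target_class,
                             baseline = NULL) {
  params <- if (inherits(model, "eegnet_model")) model$params else model
  scale <- if (inherits(model, "eegnet_model")) model$input_scale else 1
  if (is.null(baseline))
    baseline <- matrix(0, nrow(prp_input), ncol(prp_input))
  if (is.character(target_class)) {
    target_class <- match(target_class, model$labels)
    if (is.na(target_class)) stop("unknown target class")
  }
  eegnet_deeplift_cpp(params, prp_input * scale, baseline * scale,
                      as.integer(target_class) - 1L)
}

#' Summarize relevance per participant
#'
#' Takes the absolute contribution scores of every attributable test PRP,
#' z-transforms each matrix (within-matrix mean 0, variance 1), averages
#' across phonemes within each repetition and then across repetitions, and
#' returns one relevance matrix per participant.
#'
#' @param contributions list of electrode x time contribution matrices
#'   (e.g., `preds$contributions` from [train_cv()] with
#'   `attribute = TRUE`).
#' @param info data.frame aligned with `contributions` containing
#'   `participant` and `repetition` columns (e.g., `preds$info`).
#' @return named list of `relevance_matrix` objects (electrode x time),
#'   one per participant.
#' @export
summarize_relevance <- function(contributions, info) {
  stopifnot(length(contributions) == nrow(info))
  present <- !vapply(contributions, is.null, TRUE)   # e.g. correct-only runs
  contributions <- contributions[present]
  info <- info[present, , drop = FALSE]
  zmat <- lapply(contributions, function(m) {
    a <- abs(m)
    s <- stats::sd(a)
    if (s == 0) {
      warning("zero-variance contribution matrix skipped")
      return(NULL)
    }
    (a - mean(a)) / s
  })
  keep <- !vapply(zmat, is.null, TRUE)
  zmat <- zmat[keep]
  info <- info[keep, , drop = FALSE]
  out <- list()
  for (p in unique(info$participant)) {
    rows_p <- info$participant == p
    reps <- unique(info$repetition[rows_p])
    rep_means <- lapply(reps, function(r) {
      sel <- which(rows_p & info$repetition == r)
      Reduce(`+`, zmat[sel]) / length(sel)
    })
    m <- Reduce(`+`, rep_means) / length(rep_means)
    out[[p]] <- structure(list(scores = m, participant_id = p),
                          class = "relevance_matrix")
  }
  out
}

#' Relevance dispersion
#'
#' Variance across electrodes of the time-averaged relevance scores.
#' Smaller values indicate more spatially distributed relevance.
#'
#' @param rel a `relevance_matrix` (or a plain electrode x time matrix).
#' @return scalar variance.
#' @export
dispersion <- function(rel) {
  scores <- if (inherits(rel, "relevance_matrix")) rel$scores else rel
  if (nrow(scores) < 2) stop("need at least 2 electrodes")
  stats::var(rowMeans(scores))
}

#' Relevance peak latency
#'
#' Time of the maximum of the electrode-averaged relevance curve, in ms
#' relative to PRP onset on the sampling grid (multiples of 1000/rate ms).
#' Ties are broken toward the earliest sample (with a warning).
#'
#' @param rel a `relevance_matrix` or electrode x time matrix.
#' @param rate sampling rate in Hz (default 128).
#' @return latency in ms.
#' @export
peak_latency <- function(rel, rate = 128) {
  scores <- if (inherits(rel, "relevance_matrix")) rel$scores else rel
  curve <- colMeans(scores)
  mx <- max(curve)
  at <- which(curve >= mx - 1e-12)
  if (length(at) > 1) warning("tied relevance peak; earliest sample reported")
  (min(at) - 1) / rate * 1000
}

#' Rank electrodes by relevance
#'
#' Orders channels by their time-averaged relevance (descending), averaged
#' over a cohort's relevance matrices; the ranking feeds the forward
#' electrode selection of the representational similarity analysis.
#'
#' @param rels list of `relevance_matrix` objects with equal row order.
#' @param channels channel names corresponding to the rows.
#' @return character vector of channel names, most relevant first.
#' @export
relevance_ranking <- function(rels, channels) {
  avg <- Reduce(`+`, lapply(rels, function(r) rowMeans(r$scores))) /
    length(rels)
  channels[order(avg, decreasing = TRUE)]
}
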