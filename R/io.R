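#' Write phoneme events as a BIDS-style TSV
#'
#' Columns `onset`, `duration`, `trial_type` (seconds, seconds, label).
#'
#' @param track an `annotation_track`.
#' @param file output path.
#' @export
write_events_tsv <- function(track, file) {
  df <- data.frame(onset = track$events$onset,
                   duration = track$events$duration,
                   trial_type = track$events$label)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read phoneme events from a TSV
#'
#' Accepts BIDS-style columns (`onset`, `duration`, `trial_type`) or
#' `label`/`onset`/`duration`.
#'
#' @param file path to the TSV.
#' @param inventory optional label set.
#' @return an `annotation_track`.
#' @export
read_events_tsv <- function(file, inventory = NULL) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  if ("trial_type" %in% names(df)) df$label <- df$trial_type
  new_annotation_track(df[, c("label", "onset", "duration")], inventory)
}

#' Write a PRP set as per-phoneme CSV matrices plus a JSON manifest
#'
#' @param prpset a `prp_set`.
#' @param dir output directory (created if missing).
#' @export
write_prp_set <- function(prpset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (lab in prpset$phonemes) {
    m <- prpset$prp[[lab]]
    utils::write.csv(as.data.frame(m), file.path(dir, paste0(lab, ".csv")),
                     row.names = TRUE)
  }
  manifest <- list(participant_id = prpset$participant_id,
                   phonemes = prpset$phonemes,
                   n_used = as.list(prpset$n_used),
                   times = prpset$times,
                   channels = prpset$channels,
                   seed = prpset$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a PRP set written by [write_prp_set()]
#'
#' Epoch pools are not serialized, so the result cannot feed
#' [separability_f()]; all averaged-PRP consumers (decoding, RSA) work.
#'
#' @param dir directory containing the CSVs and `manifest.json`.
#' @return a `prp_set` without epoch pools.
#' @export
read_prp_set <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  prp <- lapply(man$phonemes, function(lab) {
    m <- utils::read.csv(file.path(dir, paste0(lab, ".csv")), row.names = 1)
    as.matrix(m)
  })
  names(prp) <- man$phonemes
  structure(list(participant_id = man$participant_id,
                 phonemes = man$phonemes, prp = prp, epochs = NULL,
                 n_used = unlist(man$n_used), times = man$times,
                 channels = man$channels, adjacency = NULL,
                 seed = man$seed),
            class = "prp_set")
}

#' Write ground-truth parameters as a sidecar JSON
#'
#' Records the generator parameters (and, optionally, the full template
#' arrays) alongside exported synthetic datasets so recovery analyses can
#' be scored later.
#'
#' @param truth a `ground_truth`.
#' @param file output JSON path.
#' @param include_templates also serialize the template matrices.
#' @export
write_ground_truth <- function(truth, file, include_templates = FALSE) {
  payload <- list(labels = truth$labels, channels = truth$channels,
                  rate = truth$rate, alpha = truth$alpha,
                  kappa = truth$kappa, latency_shift = truth$latency_shift,
                  component_peak_time = truth$component_peak_time,
                  seed = truth$seed)
  if (include_templates)
    payload$templates <- lapply(truth$templates, function(m)
      unname(as.data.frame(m)))
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Write/read a participant table
#'
#' @param table data.frame with one row per participant.
#' @param file CSV path.
#' @export
write_participant_table <- function(table, file) {
  utils::write.csv(table, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_participant_table
#' @export
read_participant_table <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE)
}
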