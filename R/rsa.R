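#' Phonological distinctive-feature table
#'
#' Binary feature values (\[syllabic\], \[sonorant\], \[continuant\]) for
#' the 2-letter ARPAbet phoneme inventory, coding feature presence as 1 and
#' absence as 0. The three features jointly separate the five manner
#' classes: vowels (1,1,1), approximants (0,1,1), nasals (0,1,0),
#' fricatives (0,0,1), and stops (0,0,0). Affricates (CH, JH) are coded
#' \[-continuant\] with the stops; an alternative coding can be supplied by
#' editing the CSV this table is read from.
#'
#' @param file optional path to a feature CSV with columns
#'   `phoneme, syllabic, sonorant, continuant`; defaults to the table
#'   shipped with the package.
#' @return data.frame keyed by `phoneme` with 0/1 feature columns.
#' @export
phoneme_features <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "phoneme_features.csv",
                        package = "phondecode", mustWork = TRUE)
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  needed <- c("phoneme", "syllabic", "sonorant", "continuant")
  if (!all(needed %in% names(tab))) stop("feature table missing columns")
  tab
}

#' Construct a representational dissimilarity matrix object
#'
#' @param d symmetric numeric matrix of pairwise dissimilarities with a
#'   zero diagonal.
#' @param labels condition labels, in the order of the rows of `d`.
#' @return object of class `rdm`.
#' @export
new_rdm <- function(d, labels) {
  d <- as.matrix(d)
  stopifnot(nrow(d) == ncol(d), length(labels) == nrow(d))
  if (any(d < -1e-12)) stop("dissimilarities must be >= 0")
  if (max(abs(d - t(d))) > 1e-8) stop("RDM must be symmetric")
  if (max(abs(diag(d))) > 1e-8) stop("RDM diagonal must be zero")
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(labels, labels)
  structure(list(labels = as.character(labels), d = d), class = "rdm")
}

#' @export
print.rdm <- function(x, ...) {
  cat("RDM over", length(x$labels), "conditions;",
      "mean off-diagonal dissimilarity",
      format(mean(x$d[upper.tri(x$d)]), digits = 4), "\n")
  invisible(x)
}

#' Feature-model RDM
#'
#' Pairwise Euclidean distances between binary distinctive-feature vectors,
#' restricted to a feature subset. With all three features the distances
#' over the five manner classes take exactly the values {0, 1, sqrt 2,
#' sqrt 3} (vertices of the binary 3-cube).
#'
#' @param table feature table as from [phoneme_features()], possibly
#'   subset to the phoneme inventory of interest.
#' @param features non-empty subset of
#'   `c("syllabic", "sonorant", "continuant")`.
#' @return an [new_rdm()] object over `table$phoneme`.
#' @export
feature_rdm <- function(table, features = c("syllabic", "sonorant", "continuant")) {
  if (!length(features)) stop("feature subset must be non-empty")
  if (!all(features %in% c("syllabic", "sonorant", "continuant")))
    stop("unknown feature name")
  m <- as.matrix(table[, features, drop = FALSE])
  if (anyNA(m)) stop("phoneme missing a feature value")
  d <- as.matrix(stats::dist(m, method = "euclidean"))
  new_rdm(d, table$phoneme)
}

#' Time-resolved neural RDMs from phoneme-related potentials
#'
#' At each time point, the dissimilarity between two phonemes is the
#' Euclidean distance between their PRP electrode vectors at that time.
#'
#' @param prpset a `prp_set` (see [compute_prp()]).
#' @param electrodes character subset of channel names, or indices;
#'   `NULL` uses all electrodes.
#' @param times indices of time points to use; `NULL` uses all.
#' @return list with `times` (seconds) and `rdms`, a list of `rdm` objects,
#'   one per selected time point.
#' @export
neural_rdms <- function(prpset, electrodes = NULL, times = NULL) {
  labels <- prpset$phonemes
  chans <- prpset$channels
  if (is.null(electrodes)) {
    ei <- seq_along(chans)
  } else if (is.character(electrodes)) {
    ei <- match(electrodes, chans)
    if (anyNA(ei)) stop("unknown electrode label: ",
                        paste(electrodes[is.na(ei)], collapse = ", "))
  } else ei <- as.integer(electrodes)
  if (!length(ei)) stop("electrode subset must be non-empty")
  nt <- ncol(prpset$prp[[1]])
  ti <- if (is.null(times)) seq_len(nt) else as.integer(times)
  rdms <- lapply(ti, function(t) {
    m <- vapply(labels, function(p) prpset$prp[[p]][ei, t], numeric(length(ei)))
    m <- matrix(m, nrow = length(ei))
    d <- as.matrix(stats::dist(t(m)))
    new_rdm(d, labels)
  })
  list(times = prpset$times[ti], rdms = rdms)
}

#' Spearman correlation between two RDMs
#'
#' Rank correlation over the upper-triangle (off-diagonal) dissimilarities,
#' ties handled by average ranks. The second RDM is aligned to the first
#' one's condition order when the label sets match.
#'
#' @param a,b `rdm` objects over the same label set.
#' @return Spearman's rho.
#' @export
rdm_corr <- function(a, b) {
  stopifnot(inherits(a, "rdm"), inherits(b, "rdm"))
  if (!identical(a$labels, b$labels)) {
    if (!setequal(a$labels, b$labels))
      stop("RDMs must share the same label set")
    # align b to a's condition order
    i <- match(a$labels, b$labels)
    b <- new_rdm(b$d[i, i], a$labels)
  }
  ut <- upper.tri(a$d)
  x <- a$d[ut]; y <- b$d[ut]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant RDM: Spearman correlation undefined")
  stats::cor(x, y, method = "spearman")
}

#' Forward electrode selection for featural-neural alignment
#'
#' Electrodes are ranked by relevance; the top two seed the set, and the
#' next-ranked electrode is added while the objective (Spearman rho between
#' the neural RDMs built on the current set and the target RDM, averaged
#' over time points and participants) keeps improving. Stops at the first
#' non-improvement.
#'
#' @param prpsets list of `prp_set` objects (one per participant of a cohort).
#' @param relevance_ranking character vector of channel names, most relevant
#'   first; must cover all channels of the PRP sets.
#' @param target_rdm feature RDM over the same phoneme labels.
#' @param times optional time-point indices for the objective (default all).
#' @return list with `electrodes` (selected channel names), `objective`
#'   (final mean rho), `trace` (objective after each addition), and
#'   `rho_curve`, the group-mean rho-vs-time curve of the final set with its
#'   `times`.
#' @export
forward_select <- function(prpsets, relevance_ranking, target_rdm, times = NULL) {
  chans <- prpsets[[1]]$channels
  if (!setequal(relevance_ranking, chans))
    stop("ranking must cover all electrodes")
  if (length(chans) < 2) stop("need at least 2 electrodes")

  rho_curve <- function(set) {
    curves <- lapply(prpsets, function(ps) {
      nr <- neural_rdms(ps, electrodes = set, times = times)
      vapply(nr$rdms, function(r) {
        tryCatch(rdm_corr(r, target_rdm), error = function(e) NA_real_)
      }, 0)
    })
    rowMeans(do.call(cbind, curves), na.rm = TRUE)
  }
  objective <- function(set) mean(rho_curve(set), na.rm = TRUE)

  set <- relevance_ranking[1:2]
  best <- objective(set)
  trace <- best
  k <- 3
  while (k <= length(relevance_ranking)) {
    cand <- c(set, relevance_ranking[k])
    val <- objective(cand)
    if (!is.finite(val) || val <= best) break
    set <- cand
    best <- val
    trace <- c(trace, val)
    k <- k + 1
  }
  curve <- rho_curve(set)
  nt <- ncol(prpsets[[1]]$prp[[1]])
  ti <- if (is.null(times)) seq_len(nt) else as.integer(times)
  list(electrodes = set, objective = best, trace = trace,
       rho_curve = curve, times = prpsets[[1]]$times[ti])
}

#' RDM from a classifier confusion matrix
#'
#' Rows of the confusion matrix are normalized to per-class prediction
#' probability profiles; the dissimilarity between two phonemes is the
#' Euclidean distance between their profiles. Invariant to the total test
#' count per class.
#'
#' @param cm confusion matrix (true x predicted counts) with dimnames.
#' @return an `rdm` over the row labels.
#' @export
confusion_rdm <- function(cm) {
  cm <- as.matrix(cm)
  rs <- rowSums(cm)
  if (any(rs == 0)) stop("confusion matrix has an all-zero row")
  prof <- cm / rs
  d <- as.matrix(stats::dist(prof))
  new_rdm(d, rownames(cm) %||% as.character(seq_len(nrow(cm))))
}

#' Permutation test for a group difference in confusion-RDM alignment
#'
#' The observed statistic is the difference in Spearman rho between each
#' group's confusion-derived RDM and the target feature RDM. The null is
#' built by randomly shuffling the rows of both confusion matrices and
#' recomputing the difference `n_perm` times. By default the p value is the
#' proportion of permuted differences at least as extreme (two-sided on
#' absolute value); `mode = "literal"` instead reports the proportion of
#' permuted differences smaller than the observed one.
#'
#' @param cm_a,cm_b confusion matrices with identical label sets.
#' @param target_rdm feature RDM over the same labels.
#' @param n_perm number of row shuffles.
#' @param seed integer seed.
#' @param mode `"two-sided"` or `"literal"`.
#' @return list with `delta_rho` observed, `p`, and the null sample.
#' @export
confusion_permutation_test <- function(cm_a, cm_b, target_rdm, n_perm = 5000,
                                       seed = 1, mode = c("two-sided", "literal")) {
  mode <- match.arg(mode)
  cm_a <- as.matrix(cm_a); cm_b <- as.matrix(cm_b)
  stopifnot(identical(rownames(cm_a), rownames(cm_b)))
  obs <- rdm_corr(confusion_rdm(cm_a), target_rdm) -
         rdm_corr(confusion_rdm(cm_b), target_rdm)
  k <- nrow(cm_a)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      repeat {
        pa <- sample(k); pb <- sample(k)
        ca <- cm_a[pa, , drop = FALSE]; rownames(ca) <- rownames(cm_a)
        cb <- cm_b[pb, , drop = FALSE]; rownames(cb) <- rownames(cm_b)
        v <- tryCatch(
          rdm_corr(confusion_rdm(ca), target_rdm) -
          rdm_corr(confusion_rdm(cb), target_rdm),
          error = function(e) NULL)   # degenerate RDM: redraw
        if (!is.null(v)) return(v)
      }
    }, 0)
  })
  p <- switch(mode,
    "two-sided" = mean(abs(null) >= abs(obs) - 1e-15),
    "literal" = mean(null < obs))
  list(delta_rho = obs, p = p, null = null, mode = mode, seed = seed)
}
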