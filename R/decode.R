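#' Classifier configuration
#'
#' Hyperparameters of the compact convolutional phoneme classifier and its
#' cross-validation protocol. The published protocol is the default
#' (8 temporal filters, 2 spatial filters per temporal filter, dropout 0.5,
#' initial learning rate 0.01 decayed by 0.7 every 100 epochs, batch 16,
#' up to 300 epochs with the model kept at the validation-loss minimum,
#' 20 folds holding out 5% with a random 15% validation split, 20
#' repetitions); [test_scale_config()] gives the reduced settings used in
#' the simulation suites.
#'
#' @param F1 temporal filters.
#' @param D spatial filters per temporal filter.
#' @param dropout dropout rate.
#' @param max_epochs maximum training epochs.
#' @param lr0 initial learning rate.
#' @param lr_decay multiplicative decay factor.
#' @param decay_every epochs between decays.
#' @param batch minibatch size.
#' @param folds cross-validation folds.
#' @param val_fraction fraction of non-test data used for validation.
#' @param test_fraction nominal held-out fraction per fold
#'   (`folds * test_fraction` should be about 1).
#' @param repetitions protocol repetitions with fresh seeds.
#' @param k1 temporal kernel length (samples).
#' @param k2 separable-stage kernel length.
#' @param p1,p2 average-pooling factors.
#' @param patience early-stopping patience (epochs without validation
#'   improvement) within the `max_epochs` budget.
#' @param stratify `"phoneme"` (default) or `"participant"` fold
#'   stratification.
#' @param attribute also compute DeepLIFT contributions for every test PRP.
#' @param attribute_correct_only restrict attributions to correctly
#'   classified test PRPs (default `FALSE`: attribute all test PRPs toward
#'   their true class).
#' @param seed master seed.
#' @return list of class `classifier_config`.
#' @export
classifier_config <- function(F1 = 8, D = 2, dropout = 0.5,
                              max_epochs = 300, lr0 = 0.01, lr_decay = 0.7,
                              decay_every = 100, batch = 16, folds = 20,
                              val_fraction = 0.15, test_fraction = 0.05,
                              repetitions = 20, k1 = 32, k2 = 16,
                              p1 = 4, p2 = 8, patience = 12,
                              stratify = c("phoneme", "participant"),
                              attribute = FALSE,
                              attribute_correct_only = FALSE, seed = 1) {
  stopifnot(val_fraction > 0, val_fraction < 1,
            test_fraction > 0, test_fraction < 1)
  if (abs(folds * test_fraction - 1) > 0.25)
    warning("folds * test_fraction is far from 1; folds will not tile the data evenly")
  structure(list(F1 = F1, D = D, dropout = dropout, max_epochs = max_epochs,
                 lr0 = lr0, lr_decay = lr_decay, decay_every = decay_every,
                 batch = batch, folds = folds, val_fraction = val_fraction,
                 test_fraction = test_fraction, repetitions = repetitions,
                 k1 = k1, k2 = k2, p1 = p1, p2 = p2, patience = patience,
                 stratify = match.arg(stratify), attribute = attribute,
                 attribute_correct_only = attribute_correct_only,
                 seed = seed),
            class = "classifier_config")
}

#' Reduced protocol for simulation suites
#'
#' Same architecture, scaled-down protocol (3 repetitions, 60 max epochs)
#' intended for 12-phoneme synthetic cohorts on one CPU.
#'
#' @param ... overrides passed to [classifier_config()].
#' @export
test_scale_config <- function(...) {
  defaults <- list(repetitions = 3, max_epochs = 60, patience = 8)
  args <- utils::modifyList(defaults, list(...))
  do.call(classifier_config, args)
}

#' Build an untrained classifier
#'
#' Instantiates the network for a given input grid: temporal convolution
#' (`F1` kernels, same padding), depthwise spatial convolution across all
#' electrodes (`D` filters per temporal filter), ELU, average pooling by
#' `p1`, dropout, separable temporal convolution (depthwise kernel `k2`
#' plus pointwise mixing), ELU, average pooling by `p2`, dropout, and a
#' dense softmax readout over `n_classes`.
#'
#' @param cfg a `classifier_config`.
#' @param n_electrodes,n_times input grid.
#' @param n_classes number of phoneme classes, >= 2.
#' @param seed initialization seed (defaults to `cfg$seed`).
#' @return object of class `eegnet_model` with `params` and `n_parameters`.
#' @export
build_classifier <- function(cfg, n_electrodes = 61, n_times = 64,
                             n_classes, seed = cfg$seed) {
  stopifnot(n_classes >= 2)
  params <- eegnet_init_cpp(n_electrodes, n_times, n_classes,
                            cfg$F1, cfg$D, cfg$k1, cfg$k2, cfg$p1, cfg$p2,
                            as.integer(seed))
  npar <- sum(vapply(params[setdiff(names(params), "meta")], length, 0L))
  structure(list(params = params, cfg = cfg, n_parameters = npar,
                 labels = NULL, input_scale = 1),
            class = "eegnet_model")
}

#' @export
print.eegnet_model <- function(x, ...) {
  m <- x$params$meta
  cat(sprintf("Compact CNN classifier: %d x %d input, %d classes, %d parameters\n",
              m$n_e, m$n_t, m$n_classes, x$n_parameters))
  invisible(x)
}

#' Class probabilities for PRP inputs
#'
#' @param model a (trained) `eegnet_model`.
#' @param X electrode x time x sample array (or a single matrix).
#' @return samples x classes probability matrix (rows sum to 1).
#' @export
predict_proba <- function(model, X) {
  if (is.matrix(X)) X <- array(X, dim = c(dim(X), 1))
  p <- eegnet_predict_cpp(model$params, X * model$input_scale)
  colnames(p) <- model$labels
  p
}

# stack a cohort's PRPs into (array, labels, participants)
.stack_prps <- function(prpsets) {
  labels <- prpsets[[1]]$phonemes
  ne <- length(prpsets[[1]]$channels)
  nt <- length(prpsets[[1]]$times)
  n <- length(prpsets) * length(labels)
  X <- array(0, dim = c(ne, nt, n))
  y <- character(n); pid <- character(n)
  i <- 0
  for (ps in prpsets) {
    stopifnot(identical(ps$phonemes, labels))
    for (lab in labels) {
      i <- i + 1
      X[, , i] <- ps$prp[[lab]]
      y[i] <- lab
      pid[i] <- ps$participant_id
    }
  }
  list(X = X, y = y, pid = pid, labels = labels)
}

# stratified fold assignment: shuffle within stratum, deal round-robin
# from a random starting fold so small strata still spread over all folds
.fold_assignment <- function(strata, folds) {
  fold <- integer(length(strata))
  for (s in unique(strata)) {
    idx <- sample(which(strata == s))
    start <- sample.int(folds, 1)
    fold[idx] <- ((seq_along(idx) - 1 + start - 1) %% folds) + 1
  }
  fold
}

#' Train phoneme classifiers under the cross-validation protocol
#'
#' For each repetition, cohorts are balanced by randomly dropping the
#' surplus participants of the larger cohort(s); each cohort is then
#' trained separately with `folds`-fold cross-validation (stratified by
#' phoneme label by default) in which each fold's samples are held out as
#' the test set exactly once, a random `val_fraction` of the non-test data
#' serves as validation, and the model at the epoch with the lowest
#' validation cross-entropy predicts the test set. Inputs are scaled by
#' the training set's global standard deviation (multiplicative only, so
#' the all-zero baseline is preserved).
#'
#' @param cohorts named list of cohorts, each a list of `prp_set` objects
#'   (one per participant). A single cohort may be passed as
#'   `list(all = prpsets)`.
#' @param cfg a `classifier_config`.
#' @return object of class `prediction_set`: `info` data.frame
#'   (`participant`, `cohort`, `true`, `predicted`, `fold`, `repetition`),
#'   `probs` matrix aligned with `info` rows, `labels`, and
#'   `contributions` (list of DeepLIFT matrices) when `cfg$attribute`.
#' @export
train_cv <- function(cohorts, cfg = classifier_config()) {
  stopifnot(is.list(cohorts), length(cohorts) >= 1)
  if (is.null(names(cohorts))) names(cohorts) <- paste0("cohort", seq_along(cohorts))
  sizes <- vapply(cohorts, length, 0L)
  n_target <- min(sizes)

  info <- list(); probs <- list(); contribs <- list()
  for (rep_i in seq_len(cfg$repetitions)) {
    rep_seed <- sub_seed(cfg$seed, rep_i)
    balanced <- with_seed(rep_seed, {
      lapply(cohorts, function(ps) {
        if (length(ps) > n_target) ps[sort(sample(length(ps), n_target))]
        else ps
      })
    })
    for (ci in seq_along(balanced)) {
      cohort_name <- names(balanced)[ci]
      res <- .train_cohort_rep(balanced[[ci]], cfg,
                               sub_seed(rep_seed, ci), rep_i, cohort_name)
      info[[length(info) + 1]] <- res$info
      probs[[length(probs) + 1]] <- res$probs
      if (cfg$attribute) contribs <- c(contribs, res$contribs)
    }
  }
  info <- do.call(rbind, info)
  probs <- do.call(rbind, probs)
  structure(list(info = info, probs = probs,
                 labels = colnames(probs),
                 contributions = if (cfg$attribute) contribs),
            class = "prediction_set")
}

.train_cohort_rep <- function(prpsets, cfg, seed, rep_i, cohort_name) {
  st <- .stack_prps(prpsets)
  labels <- sort(unique(st$y))
  y_int <- match(st$y, labels) - 1L
  n <- length(st$y)
  if (n < cfg$folds) stop("cohort too small to form ", cfg$folds, " folds")

  with_seed(seed, {
    strata <- switch(cfg$stratify, phoneme = st$y, participant = st$pid)
    fold <- .fold_assignment(strata, cfg$folds)
    info <- list(); probs <- list(); contribs <- list()
    for (f in seq_len(cfg$folds)) {
      test_idx <- which(fold == f)
      if (!length(test_idx)) next
      rest <- which(fold != f)
      n_val <- max(1, round(cfg$val_fraction * length(rest)))
      val_idx <- sample(rest, n_val)
      train_idx <- setdiff(rest, val_idx)

      sdev <- stats::sd(st$X[, , train_idx])
      scale <- if (sdev > 0) 1 / sdev else 1
      model <- build_classifier(cfg, dim(st$X)[1], dim(st$X)[2],
                                length(labels),
                                seed = sub_seed(seed, 1000 + f))
      fit <- eegnet_train_cpp(model$params,
                              st$X[, , train_idx, drop = FALSE] * scale,
                              y_int[train_idx],
                              st$X[, , val_idx, drop = FALSE] * scale,
                              y_int[val_idx],
                              cfg$lr0, cfg$lr_decay, cfg$decay_every,
                              cfg$batch, cfg$max_epochs, cfg$dropout,
                              cfg$patience, sub_seed(seed, 2000 + f))
      p <- eegnet_predict_cpp(fit$params,
                              st$X[, , test_idx, drop = FALSE] * scale)
      colnames(p) <- labels
      info[[f]] <- data.frame(
        participant = st$pid[test_idx], cohort = cohort_name,
        true = st$y[test_idx],
        predicted = labels[max.col(p, ties.method = "first")],
        fold = f, repetition = rep_i, stringsAsFactors = FALSE)
      probs[[f]] <- p
      if (cfg$attribute) {
        base <- matrix(0, dim(st$X)[1], dim(st$X)[2])
        correct <- labels[max.col(p, ties.method = "first")] == st$y[test_idx]
        contribs <- c(contribs, lapply(seq_along(test_idx), function(k) {
          if (isTRUE(cfg$attribute_correct_only) && !correct[k]) return(NULL)
          i <- test_idx[k]
          eegnet_deeplift_cpp(fit$params, st$X[, , i] * scale, base,
                              y_int[i])
        }))
      }
    }
    list(info = do.call(rbind, info), probs = do.call(rbind, probs),
         contribs = contribs)
  })
}

#' Shannon entropy of prediction probability vectors
#'
#' `-sum(p * ln p)` per row, with `0 * ln 0 := 0`; bounded by `ln K`.
#'
#' @param probs matrix of class probabilities (rows sum to 1).
#' @return numeric vector of entropies in nats.
#' @export
prediction_entropy <- function(probs) {
  probs <- as.matrix(probs)
  lp <- ifelse(probs > 0, log(probs), 0)
  -rowSums(probs * lp)
}

#' Per-participant accuracy and prediction uncertainty
#'
#' Accuracy is the fraction of test PRPs whose highest-probability phoneme
#' matches the true label; uncertainty is the Shannon entropy of the
#' probability vector. Both are averaged over phonemes within each
#' repetition and then over repetitions for each participant.
#'
#' @param preds a `prediction_set`.
#' @return data.frame with `participant`, `cohort`, `accuracy`, `entropy`.
#' @export
prediction_metrics <- function(preds) {
  info <- preds$info
  if (!nrow(info)) stop("empty prediction set")
  info$correct <- as.numeric(info$true == info$predicted)
  info$ent <- prediction_entropy(preds$probs)
  by_rep <- stats::aggregate(cbind(correct, ent) ~ participant + cohort +
                               repetition + true,
                             data = info, FUN = mean)
  by_rep2 <- stats::aggregate(cbind(correct, ent) ~ participant + cohort +
                                repetition,
                              data = by_rep, FUN = mean)
  out <- stats::aggregate(cbind(correct, ent) ~ participant + cohort,
                          data = by_rep2, FUN = mean)
  names(out)[names(out) == "correct"] <- "accuracy"
  names(out)[names(out) == "ent"] <- "entropy"
  out
}

#' Confusion matrix of pooled predictions
#'
#' Counts of true x predicted labels pooled over folds and repetitions.
#'
#' @param preds a `prediction_set`.
#' @param cohort optional cohort name to restrict to.
#' @return integer matrix with dimnames over the label set.
#' @export
confusion <- function(preds, cohort = NULL) {
  info <- preds$info
  if (!is.null(cohort)) info <- info[info$cohort == cohort, ]
  labs <- preds$labels
  cm <- table(factor(info$true, levels = labs),
              factor(info$predicted, levels = labs))
  m <- matrix(as.integer(cm), nrow = length(labs),
              dimnames = list(labs, labs))
  m
}

#' Chance-level accuracy for a K-class problem
#'
#' @param n_classes number of classes.
#' @return chance accuracy in percent (`100 / n_classes`).
#' @export
chance_level <- function(n_classes) 100 / n_classes
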