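#' Cluster-mass permutation test on electrode topographies
#'
#' Mass-univariate test over electrodes with cluster-based correction for
#' multiple comparisons. A t statistic is computed per electrode (one-sample
#' against `mu`, or two-sample Welch between groups), electrodes exceeding
#' the t value equivalent to uncorrected p <= `cluster_alpha` are clustered
#' by spatial adjacency (same sign of effect), and each cluster's mass (sum
#' of member t values) is compared with the null distribution of the maximum
#' cluster mass obtained by permutation: sign flips of participant maps for
#' the one-sample design, group-label exchanges for the two-sample design.
#' If the number of distinct permutations does not exceed `n_perm` the null
#' is enumerated exactly.
#'
#' @param maps numeric matrix, participants x electrodes.
#' @param design `"one-sample"` or `"two-sample"`.
#' @param groups factor/vector of length `nrow(maps)` for the two-sample design.
#' @param tail `"two"`, `"greater"` or `"less"`.
#' @param n_perm number of permutations for the null distribution.
#' @param seed integer seed for the permutation draws.
#' @param adjacency logical adjacency matrix over electrodes.
#' @param mu null value for the one-sample design.
#' @param cluster_alpha uncorrected alpha defining the cluster-forming t.
#' @return An object of class `cluster_result`: list with per-electrode `t`,
#'   the cluster-forming `threshold`, and `clusters`, a list of clusters
#'   (member electrodes, mass, `t_max`, corrected `p`).
#' @export
cluster_test <- function(maps, design = c("one-sample", "two-sample"),
                         groups = NULL, tail = c("two", "greater", "less"),
                         n_perm = 10000, seed = 1, adjacency, mu = 0,
                         cluster_alpha = 0.05) {
  design <- match.arg(design)
  tail <- match.arg(tail)
  maps <- as.matrix(maps)
  n <- nrow(maps)
  ne <- ncol(maps)
  stopifnot(is.matrix(adjacency), nrow(adjacency) == ne)

  if (design == "one-sample") {
    if (n < 2) stop("need at least 2 participants")
    stat_fun <- function(x) {
      m <- colMeans(x) - mu
      s <- sqrt((colSums(x^2) - n * colMeans(x)^2) / (n - 1))
      m / (s / sqrt(n))
    }
    df <- n - 1
  } else {
    if (is.null(groups)) stop("two-sample design needs `groups`")
    groups <- as.factor(groups)
    if (nlevels(groups) != 2) stop("`groups` must have exactly 2 levels")
    ia <- which(groups == levels(groups)[1])
    ib <- which(groups == levels(groups)[2])
    if (length(ia) < 2 || length(ib) < 2)
      stop("need at least 2 participants per group")
    welch <- function(xa, xb) {
      na <- nrow(xa); nb <- nrow(xb)
      ma <- colMeans(xa); mb <- colMeans(xb)
      va <- (colSums(xa^2) - na * ma^2) / (na - 1)
      vb <- (colSums(xb^2) - nb * mb^2) / (nb - 1)
      se2 <- va / na + vb / nb
      t <- (ma - mb) / sqrt(se2)
      df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
      list(t = t, df = df)
    }
    w0 <- welch(maps[ia, , drop = FALSE], maps[ib, , drop = FALSE])
    df <- w0$df
  }

  crit <- if (tail == "two") stats::qt(1 - cluster_alpha / 2, df)
          else stats::qt(1 - cluster_alpha, df)

  observed_t <- if (design == "one-sample") stat_fun(maps) else w0$t

  cluster_masses <- function(tvals) {
    out <- list()
    if (tail %in% c("two", "greater")) {
      sup <- which(tvals > crit)
      for (cl in connected_components(sup, adjacency))
        out[[length(out) + 1]] <- list(electrodes = cl, mass = sum(tvals[cl]),
                                       t_max = max(tvals[cl]))
    }
    if (tail %in% c("two", "less")) {
      sup <- which(tvals < -crit)
      for (cl in connected_components(sup, adjacency))
        out[[length(out) + 1]] <- list(electrodes = cl, mass = sum(tvals[cl]),
                                       t_max = min(tvals[cl]))
    }
    out
  }

  max_mass <- function(tvals) {
    cls <- cluster_masses(tvals)
    if (!length(cls)) 0 else max(vapply(cls, function(c) abs(c$mass), 0))
  }

  # permutation schemes, enumerated exactly when feasible
  null_mass <- with_seed(seed, {
    if (design == "one-sample") {
      n_exact <- 2^n
      if (n_exact <= n_perm) {
        vapply(0:(n_exact - 1), function(k) {
          signs <- 1 - 2 * as.integer(intToBits(k)[1:n])
          max_mass(stat_fun(maps * signs))
        }, 0)
      } else {
        vapply(seq_len(n_perm), function(i) {
          signs <- sample(c(-1, 1), n, replace = TRUE)
          max_mass(stat_fun(maps * signs))
        }, 0)
      }
    } else {
      n_exact <- choose(n, length(ia))
      if (n_exact <= n_perm) {
        idx <- utils::combn(n, length(ia))
        vapply(seq_len(ncol(idx)), function(i) {
          pa <- idx[, i]
          w <- welch(maps[pa, , drop = FALSE], maps[-pa, , drop = FALSE])
          max_mass(w$t)
        }, 0)
      } else {
        vapply(seq_len(n_perm), function(i) {
          pa <- sample(n, length(ia))
          w <- welch(maps[pa, , drop = FALSE], maps[-pa, , drop = FALSE])
          max_mass(w$t)
        }, 0)
      }
    }
  })

  clusters <- cluster_masses(observed_t)
  for (i in seq_along(clusters)) {
    m <- abs(clusters[[i]]$mass)
    clusters[[i]]$p <- (1 + sum(null_mass >= m)) / (1 + length(null_mass))
    if (!is.null(colnames(maps)))
      clusters[[i]]$channels <- colnames(maps)[clusters[[i]]$electrodes]
  }
  structure(list(t = observed_t, threshold = crit, clusters = clusters,
                 design = design, tail = tail, n_perm = length(null_mass),
                 seed = seed),
            class = "cluster_result")
}

# connected components of the node subset `nodes` under `adjacency`
connected_components <- function(nodes, adjacency) {
  if (!length(nodes)) return(list())
  remaining <- nodes
  comps <- list()
  while (length(remaining)) {
    queue <- remaining[1]
    comp <- integer(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      nb <- intersect(which(adjacency[v, ]), remaining)
      queue <- c(queue, setdiff(nb, comp))
    }
    comps[[length(comps) + 1]] <- sort(comp)
    remaining <- setdiff(remaining, comp)
  }
  comps
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("Cluster-mass permutation test (", x$design, ", ", x$tail, "-tailed, ",
      x$n_perm, " permutations)\n", sep = "")
  if (!length(x$clusters)) {
    cat("  no suprathreshold clusters\n")
  } else {
    for (cl in x$clusters)
      cat(sprintf("  cluster of %d electrodes: mass=%.2f t_max=%.2f p=%.4f\n",
                  length(cl$electrodes), cl$mass, cl$t_max, cl$p))
  }
  invisible(x)
}

#' Two-group comparison (Welch t or Mann-Whitney U)
#'
#' @param values numeric vector of the measure.
#' @param group two-level factor of the same length.
#' @param test `"welch"` for Welch's two-sample t test (normal-assumed
#'   variables) or `"mannwhitney"` for the rank-based Mann-Whitney U test.
#' @return list with `statistic`, `p`, and either the 95% CI (Welch) or the
#'   rank-biserial effect estimate (Mann-Whitney); always two-sided.
#' @export
group_compare <- function(values, group, test = c("welch", "mannwhitney")) {
  test <- match.arg(test)
  group <- as.factor(group)
  stopifnot(nlevels(group) == 2)
  a <- values[group == levels(group)[1]]
  b <- values[group == levels(group)[2]]
  if (test == "welch") {
    if (stats::var(a) == 0 && stats::var(b) == 0)
      stop("zero variance in both groups")
    ht <- stats::t.test(a, b, var.equal = FALSE)
    list(test = "welch", statistic = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value, ci = unname(ht$conf.int), estimate = unname(diff(rev(ht$estimate))))
  } else {
    ht <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    u <- unname(ht$statistic)
    rb <- 2 * u / (length(a) * length(b)) - 1   # rank-biserial correlation
    list(test = "mannwhitney", statistic = u, p = ht$p.value, effect = rb)
  }
}

#' Rationalized arcsine transform of a proportion-correct score
#'
#' Variance-stabilizing transform for proportion-correct data that
#' mitigates floor and ceiling effects. With `k = round(x * n)` correct out
#' of `n`, theta = asin(sqrt(k/(n+1))) + asin(sqrt((k+1)/(n+1))) and
#' `RAU = (146/pi) * theta - 23`, mapping \[0, 1\] to roughly \[-23, 123\]
#' with 0.5 near 50.
#'
#' @param x proportion correct in \[0, 1\] (vectorized).
#' @param n number of trials underlying `x`.
#' @return RAU score(s).
#' @export
rau <- function(x, n) {
  if (any(x < 0 | x > 1)) stop("`x` must be within [0, 1]")
  if (any(n < 1)) stop("`n` must be >= 1")
  k <- round(x * n)
  theta <- asin(sqrt(k / (n + 1))) + asin(sqrt((k + 1) / (n + 1)))
  (146 / pi) * theta - 23
}

#' Log transform for extended high-frequency thresholds
#'
#' Thresholds in dB HL can be negative; adding 25 dB before the natural
#' log keeps the argument positive for any audiometrically plausible value.
#'
#' @param threshold threshold(s) in dB HL, must exceed -25.
#' @return `ln(threshold + 25)`.
#' @export
ehf_log_transform <- function(threshold) {
  if (any(threshold <= -25)) stop("threshold must be > -25 dB HL")
  log(threshold + 25)
}

#' Words-in-Noise SNR loss
#'
#' Converts the number of correctly repeated WIN words (out of 70: 10 words
#' at each of 7 SNR levels over two lists) to the SNR loss in dB via
#' `26 - 0.4 * n_correct`.
#'
#' @param n_correct number of correctly identified words, 0..70.
#' @return SNR loss in dB.
#' @export
win_snr_loss <- function(n_correct) {
  if (any(n_correct < 0 | n_correct > 70)) stop("`n_correct` must be in 0..70")
  26 - 0.4 * n_correct
}

#' Backward stepwise regression by AIC
#'
#' Ordinary least squares with backward elimination: at each step the
#' predictor whose removal lowers the AIC the most is dropped, stopping when
#' no removal lowers it. Delegates to [stats::step()], whose
#' `extractAIC` uses the n*ln(RSS/n) + 2k convention. Predictors are
#' z-scored by default so coefficients are comparable across measures.
#'
#' @param table data.frame with the response and predictors.
#' @param response name of the response column.
#' @param predictors character vector of predictor column names.
#' @param standardize z-score the predictors before fitting.
#' @return list with the selected `model` (an `lm`), `retained` predictor
#'   names, `coefficients`, and the AIC `trace` (anova component of step).
#' @export
stepwise_aic <- function(table, response, predictors, standardize = TRUE) {
  dat <- table[, c(response, predictors), drop = FALSE]
  if (anyNA(dat)) stop("complete cases required")
  if (standardize)
    for (p in predictors) dat[[p]] <- as.numeric(scale(dat[[p]]))
  fml <- stats::as.formula(paste(response, "~", paste(predictors, collapse = " + ")))
  full <- stats::lm(fml, data = dat)
  if (qr(full)$rank < length(predictors) + 1) stop("rank-deficient design")
  sel <- stats::step(full, direction = "backward", trace = 0)
  retained <- setdiff(attr(stats::terms(sel), "term.labels"), character(0))
  list(model = sel, retained = retained, coefficients = stats::coef(sel),
       aic = stats::extractAIC(sel)[2], aic_full = stats::extractAIC(full)[2],
       trace = sel$anova, data = dat)
}

#' Residual group analysis after covariate adjustment
#'
#' Fits OLS of the response on the retained (non-group) predictors, extracts
#' the residuals, and regresses them on the group indicator, reporting the
#' group coefficient. This asks whether a group difference persists after
#' accounting for the selected covariates.
#'
#' @param table data.frame; must contain a `group` column plus the variables.
#' @param retained_predictors character vector, must not include `"group"`.
#' @param response response column name.
#' @return list with `beta`, `se`, `t`, `p` for the group indicator and the
#'   residual vector.
#' @export
residual_group_test <- function(table, retained_predictors, response) {
  if ("group" %in% retained_predictors)
    stop("retained predictors must exclude group")
  if (length(retained_predictors)) {
    fml <- stats::as.formula(paste(response, "~",
                                   paste(retained_predictors, collapse = " + ")))
  } else {
    fml <- stats::as.formula(paste(response, "~ 1"))
  }
  fit <- stats::lm(fml, data = table)
  res <- stats::residuals(fit)
  if (stats::sd(res) == 0) stop("constant residuals")
  g <- as.factor(table$group)
  fit2 <- stats::lm(res ~ g)
  sm <- summary(fit2)$coefficients
  list(beta = sm[2, 1], se = sm[2, 2], t = sm[2, 3], p = sm[2, 4],
       residuals = res)
}

#' Permutation cluster test for group differences between time curves
#'
#' One-dimensional analogue of [cluster_test()]: a Welch t statistic is
#' computed at each time point, contiguous suprathreshold runs form temporal
#' clusters, and cluster masses are compared with the permutation null of
#' the maximum cluster mass under group-label exchange. Used to localize
#' where two groups' time series (e.g., RSA alignment curves) differ.
#'
#' @param curves matrix, participants x time points.
#' @param group two-level factor over participants.
#' @param times numeric vector of time stamps in seconds (one per column).
#' @param n_perm permutations.
#' @param seed integer seed.
#' @param cluster_alpha uncorrected alpha for the cluster-forming threshold.
#' @return list with `t` per time point, and `intervals`: a data.frame of
#'   significant contiguous intervals (`start_ms`, `end_ms`, `mass`, `p`).
#' @export
curve_difference_test <- function(curves, group, times, n_perm = 1000,
                                  seed = 1, cluster_alpha = 0.05) {
  curves <- as.matrix(curves)
  group <- as.factor(group)
  stopifnot(nlevels(group) == 2, length(times) == ncol(curves))
  ia <- which(group == levels(group)[1])
  ib <- which(group == levels(group)[2])
  if (length(ia) < 2 || length(ib) < 2)
    stop("need at least 2 participants per group")
  nt <- ncol(curves)
  # chain adjacency over time points
  adj <- matrix(FALSE, nt, nt)
  if (nt > 1) {
    adj[cbind(1:(nt - 1), 2:nt)] <- TRUE
    adj[cbind(2:nt, 1:(nt - 1))] <- TRUE
  }
  res <- cluster_test(curves, design = "two-sample", groups = group,
                      tail = "two", n_perm = n_perm, seed = seed,
                      adjacency = adj, cluster_alpha = cluster_alpha)
  sig <- Filter(function(cl) cl$p < 0.05, res$clusters)
  intervals <- do.call(rbind, lapply(sig, function(cl) {
    data.frame(start_ms = 1000 * times[min(cl$electrodes)],
               end_ms = 1000 * times[max(cl$electrodes)],
               mass = cl$mass, p = cl$p)
  }))
  if (is.null(intervals))
    intervals <- data.frame(start_ms = numeric(0), end_ms = numeric(0),
                            mass = numeric(0), p = numeric(0))
  list(t = res$t, threshold = res$threshold, intervals = intervals,
       clusters = res$clusters)
}
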