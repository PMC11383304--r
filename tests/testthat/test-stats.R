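test_that("cluster test controls type-I error and finds planted patches", {
  mont <- standard_montage()
  adj <- montage_adjacency(mont)
  ne <- nrow(mont)
  # type-I calibration under the two-sample null (reduced sizes)
  set.seed(1)
  n_sim <- 60
  fp <- 0
  for (i in seq_len(n_sim)) {
    maps <- matrix(stats::rnorm(12 * ne), 12, ne)
    res <- cluster_test(maps, design = "two-sample",
                        groups = rep(c("a", "b"), each = 6),
                        n_perm = 200, seed = i, adjacency = adj)
    if (any(vapply(res$clusters, function(cl) cl$p, 0) < 0.05)) fp <- fp + 1
  }
  expect_lt(fp / n_sim, 0.15)
  # power: +2 SD shift on a connected 6-electrode patch, 12 per group
  patch <- which(adj[match("Cz", mont$name), ])[1:5]
  patch <- c(match("Cz", mont$name), patch)
  set.seed(2)
  maps <- matrix(stats::rnorm(24 * ne), 24, ne)
  maps[1:12, patch] <- maps[1:12, patch] + 2
  res <- cluster_test(maps, design = "two-sample",
                      groups = rep(c("a", "b"), each = 12),
                      n_perm = 500, seed = 3, adjacency = adj)
  sig <- Filter(function(cl) cl$p < 0.05, res$clusters)
  hit <- unique(unlist(lapply(sig, `[[`, "electrodes")))
  expect_gte(length(intersect(hit, patch)), 5)
  # single participant per group is refused
  expect_error(cluster_test(maps[1:2, ], design = "two-sample",
                            groups = c("a", "b"), adjacency = adj),
               "at least 2")
  # exact enumeration for tiny one-sample designs
  small <- matrix(stats::rnorm(5 * ne, 1), 5, ne)
  r1 <- cluster_test(small, design = "one-sample", n_perm = 10000, seed = 4,
                     adjacency = adj)
  expect_equal(r1$n_perm, 32)   # 2^5 sign flips enumerated exactly
})

test_that("group comparison matches the textbook Welch formula", {
  a <- c(2.1, 3.4, 1.9, 4.2, 3.3)
  b <- c(5.0, 4.1, 6.2, 5.5, 4.9)
  res <- group_compare(c(a, b), rep(c("x", "y"), each = 5), test = "welch")
  se <- sqrt(var(a) / 5 + var(b) / 5)
  t_direct <- (mean(a) - mean(b)) / se
  df_direct <- se^4 / ((var(a) / 5)^2 / 4 + (var(b) / 5)^2 / 4)
  expect_equal(res$statistic, t_direct, tolerance = 1e-10)
  expect_equal(res$df, df_direct, tolerance = 1e-10)
  # identical samples: t = 0, p = 1
  same <- group_compare(c(a, a), rep(c("x", "y"), each = 5), test = "welch")
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(group_compare(rep(1, 10), rep(c("x", "y"), each = 5),
                             test = "welch"), "zero variance")
  # Mann-Whitney is invariant under monotone transforms of pooled values
  g <- rep(c("x", "y"), each = 5)
  v <- c(a, b)
  r1 <- group_compare(v, g, test = "mannwhitney")
  r2 <- group_compare(exp(v), g, test = "mannwhitney")
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p, r2$p)
})

test_that("RAU transform is exact, monotone, and spans [-23, 123]", {
  # direct evaluation of the two-arcsine formula as an oracle
  set.seed(3)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    x <- stats::runif(1)
    k <- round(x * n)
    theta <- asin(sqrt(k / (n + 1))) + asin(sqrt((k + 1) / (n + 1)))
    expect_equal(rau(x, n), (146 / pi) * theta - 23, tolerance = 1e-10)
  }
  expect_equal(rau(0.5, 1e6), 50, tolerance = 0.01)
  xs <- seq(0, 1, by = 0.01)
  expect_true(all(diff(rau(xs, 100)) > 0))
  expect_gte(min(rau(xs, 1000)), -23 - 1e-9)
  expect_lte(max(rau(xs, 1000)), 123 + 1e-9)
  expect_error(rau(1.2, 10), "within")
})

test_that("threshold transforms and WIN scoring evaluate exactly", {
  expect_equal(ehf_log_transform(-2.5), log(22.5), tolerance = 1e-12)
  expect_equal(ehf_log_transform(15), log(40), tolerance = 1e-12)
  expect_error(ehf_log_transform(-25), "-25")
  expect_equal(win_snr_loss(0), 26)
  expect_equal(win_snr_loss(65), 0)
  expect_equal(win_snr_loss(56), 3.6)
  expect_error(win_snr_loss(75), "0..70")
})

test_that("backward stepwise AIC keeps true predictors, drops noise", {
  hits <- 0
  for (run in 1:20) {
    set.seed(run)
    n <- 200
    dat <- data.frame(x1 = stats::rnorm(n))
    for (j in 2:6) dat[[paste0("x", j)]] <- stats::rnorm(n)
    dat$y <- 2 * dat$x1 + stats::rnorm(n)
    fit <- stepwise_aic(dat, "y", paste0("x", 1:6))
    if ("x1" %in% fit$retained &&
        sum(paste0("x", 2:6) %in% fit$retained) <= 1) hits <- hits + 1
    # the true predictor itself must never be dropped
    expect_true("x1" %in% fit$retained)
    # the selected model never has higher AIC than the full model
    expect_lte(fit$aic, fit$aic_full + 1e-9)
  }
  # AIC's k=2 penalty retains a pure-noise predictor with probability
  # P(t^2 > 2) ~ 0.16, so "at most one of five retained" holds in ~82%
  # of runs; demand the binomial-plausible majority
  expect_gte(hits, 15)
  # single predictor whose removal raises AIC: model returned unchanged
  set.seed(99)
  d1 <- data.frame(x1 = stats::rnorm(100))
  d1$y <- 3 * d1$x1 + stats::rnorm(100)
  f1 <- stepwise_aic(d1, "y", "x1")
  expect_equal(f1$retained, "x1")
  # standardized coefficients invariant to affine rescaling of predictors
  d2 <- d1; d2$x1 <- 100 * d2$x1 + 7
  f2 <- stepwise_aic(d2, "y", "x1")
  expect_equal(unname(coef(f1$model)["x1"]), unname(coef(f2$model)["x1"]),
               tolerance = 1e-8)
})

test_that("residual group analysis separates mediated from direct effects", {
  # fully mediated: group only acts through the retained covariate
  tally <- 0
  for (run in 1:20) {
    set.seed(run + 40)
    n <- 120
    group <- rep(c("younger", "middle"), each = n / 2)
    w <- stats::rnorm(n) + (group == "middle") * 1.5
    y <- 2 * w + stats::rnorm(n)
    tab <- data.frame(group = group, w = w, y = y)
    res <- residual_group_test(tab, "w", "y")
    if (abs(res$t) < 2) tally <- tally + 1
    expect_lt(abs(sum(res$residuals)), 1e-9)
  }
  expect_gte(tally, 18)
  # direct group effect orthogonal to the covariates is recovered
  set.seed(77)
  n <- 200
  group <- rep(c("younger", "middle"), each = n / 2)
  w <- stats::rnorm(n)
  y <- 2 * w + 1.0 * (group == "younger") + stats::rnorm(n, sd = 0.5)
  tab <- data.frame(group = group, w = w, y = y)
  res <- residual_group_test(tab, "w", "y")
  expect_lt(abs(abs(res$beta) - 1.0) / 1.0, 0.2)
  expect_lt(res$p, 0.01)
  expect_error(residual_group_test(tab, c("group", "w"), "y"), "exclude")
})

test_that("curve difference test localizes planted temporal effects", {
  rate <- 128
  times <- (0:63) / rate
  n <- 12
  group <- rep(c("a", "b"), each = n / 2)
  # identical group curves: nothing significant
  set.seed(8)
  base <- sin(2 * pi * 3 * times)
  curves <- t(replicate(n, base + stats::rnorm(64, sd = 0.3)))
  r0 <- curve_difference_test(curves, group, times, n_perm = 300, seed = 1)
  expect_equal(nrow(r0$intervals), 0)
  # planted difference restricted to 80-190 ms
  win <- times >= 0.080 & times <= 0.190
  curves2 <- curves
  curves2[group == "a", win] <- curves2[group == "a", win] + 1.2
  r1 <- curve_difference_test(curves2, group, times, n_perm = 500, seed = 2)
  expect_gt(nrow(r1$intervals), 0)
  lo <- min(r1$intervals$start_ms); hi <- max(r1$intervals$end_ms)
  inter <- max(0, min(hi, 190) - max(lo, 80))
  union <- max(hi, 190) - min(lo, 80)
  expect_gt(inter / union, 0.5)
  # reversing group labels flips every t but keeps the intervals
  r2 <- curve_difference_test(curves2, rev(group), times, n_perm = 500,
                              seed = 2)
  expect_equal(r2$t, -r1$t, tolerance = 1e-9)
  expect_error(curve_difference_test(curves2[1:2, ], c("a", "b"), times),
               "at least 2")
})
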