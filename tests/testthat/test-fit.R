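test_that("fit_scale matches closed-form and brute-force least squares", {
  p <- c(1, 2, 3)
  expect_equal(fit_scale(p, 2 * p), 2)
  expect_equal(fit_scale(c(1, 0), c(0, 5)), 0)          # orthogonal
  expect_equal(fit_scale(c(1, 0, 1), c(1, 1, 0)), 0.5)
  expect_true(is.na(fit_scale(c(0, 0, 0), c(1, 2, 3))))
  set.seed(10)
  for (i in 1:25) {
    p <- rnorm(18); y <- rnorm(18)
    b <- fit_scale(p, y)
    expect_equal(b, brute_force_scale(p, y), tolerance = 1e-10)
  }
})

test_that("fit_scale_with_offset is ordinary least squares", {
  p <- c(0, 1, 2, 5)
  expect_equal(fit_scale_with_offset(p, 3 * p + 5), c(b1 = 3, b0 = 5))
  expect_true(all(is.na(fit_scale_with_offset(rep(2, 4), 1:4))))
  # y orthogonal to p and mean-zero
  p2 <- c(1, -1, 1, -1); y2 <- c(1, 1, -1, -1)
  expect_equal(fit_scale_with_offset(p2, y2), c(b1 = 0, b0 = 0))
})

test_that("variance explained uses the uncentered total sum of squares", {
  y <- c(3, 4)
  expect_equal(variance_explained(y, y), 1)
  expect_equal(variance_explained(y, c(0, 0)), 0)       # RSS = TSS
  expect_equal(variance_explained(y, c(3, 0)), 1 - 16 / 25)
  expect_true(is.na(variance_explained(c(0, 0), c(1, 1))))
  # direct arithmetic cross-check on random vectors
  set.seed(11)
  for (i in 1:20) {
    y <- rnorm(18); yh <- rnorm(18)
    expect_equal(variance_explained(y, yh),
                 1 - sum((y - yh)^2) / sum(y^2))
  }
})

test_that("fit_timecourse matches per-cell fit_scale/variance_explained", {
  sc <- tiny_scene(seed = 21)
  ep <- tiny_epochs(sc)
  folds <- make_folds(ep, n_folds = 6, seed = 21)
  pred <- project_to_sensors(sc$gain, predict_cortical(sc$prfs,
                                                       cached_stimuli()))
  fit <- fit_timecourse(pred, ep, folds)
  for (f in c(1, 4)) {
    trE <- average_erf(ep, folds$folds[[f]]$train)
    teE <- average_erf(ep, folds$folds[[f]]$test)
    for (cell in list(c(2, 151), c(7, 301))) {
      s <- cell[1]; it <- cell[2]
      b1 <- fit_scale(pred[s, ], trE$data[, s, it])
      ve <- variance_explained(teE$data[, s, it], b1 * pred[s, ])
      expect_equal(fit$b1[f, s, it], b1, tolerance = 1e-10)
      expect_equal(fit$ve[f, s, it], ve, tolerance = 1e-10)
    }
  }
  expect_true(all(fit$ve <= 1 + 1e-12, na.rm = TRUE))
  expect_equal(fit$ve, 1 - fit$rss / fit$tss, tolerance = 1e-12)
})

test_that("offset-variant fit matches per-cell OLS", {
  sc <- tiny_scene(seed = 22)
  ep <- tiny_epochs(sc)
  folds <- make_folds(ep, n_folds = 4, seed = 22)
  pred <- project_to_sensors(sc$gain, predict_cortical(sc$prfs,
                                                       cached_stimuli()))
  fit <- fit_timecourse(pred, ep, folds, offset = TRUE)
  trE <- average_erf(ep, folds$folds[[2]]$train)
  teE <- average_erf(ep, folds$folds[[2]]$test)
  s <- 3; it <- 220
  b <- fit_scale_with_offset(pred[s, ], trE$data[, s, it])
  ve <- variance_explained(teE$data[, s, it], b["b1"] * pred[s, ] + b["b0"])
  expect_equal(fit$b1[2, s, it], unname(b["b1"]), tolerance = 1e-10)
  expect_equal(fit$b0[2, s, it], unname(b["b0"]), tolerance = 1e-10)
  expect_equal(fit$ve[2, s, it], ve, tolerance = 1e-10)
})

test_that("breaking the stimulus-label mapping collapses the fit", {
  # Shuffled labels destroy the stimulus-specific structure; what survives is
  # only the grand-mean evoked component common to all stimuli, so the
  # matched fit must explain far more variance than the shuffled one.
  sc <- tiny_scene(seed = 23, n_epochs = 20, noise_sd = 20)
  ep <- tiny_epochs(sc)
  pred <- project_to_sensors(sc$gain, predict_cortical(sc$prfs,
                                                       cached_stimuli()))
  folds <- make_folds(ep, n_folds = 20, seed = 23)
  matched <- fit_timecourse(pred, ep, folds)
  shuf <- ep
  set.seed(23)
  shuf$labels <- sample(shuf$labels)
  folds_s <- make_folds(shuf, n_folds = 20, seed = 23)
  shuffled <- fit_timecourse(pred, shuf, folds_s)
  peak <- function(fit) max(fit_summary(average_ve(fit, 1:10))$median)
  expect_gt(peak(matched), 2 * peak(shuffled))
  # pre-stimulus latencies carry no signal at all: median pooled VE <= 0
  pre <- ep$time_ms < 0
  expect_lte(max(fit_summary(average_ve(matched, 1:10))$median[pre]), 0.02)
})

test_that("pooled group average is the pooled RSS/TSS ratio, not a mean of VEs", {
  # hand-built fit_result: 2 folds x 2 sensors x 1 latency
  fr <- structure(list(
    ve = array(NA_real_, c(2, 2, 1)),
    rss = array(c(1, 1, 1, 1), c(2, 2, 1)),
    tss = array(c(2, 2, 10, 10), c(2, 2, 1)),
    b1 = array(1, c(2, 2, 1)), time_ms = 0, n_folds = 2, offset = FALSE),
    class = "fit_result")
  fr$ve <- 1 - fr$rss / fr$tss
  pooled <- average_ve(fr, 1:2)
  expect_equal(pooled[1, 1], 1 - 2 / 12)         # mean of VEs would be 0.7
  expect_equal(average_ve(fr, 2)[1, 1], 1 - 1 / 10)  # single-sensor group

  # algebraic identity: pooled VE = TSS-weighted mean of per-sensor VEs
  sc <- tiny_scene(seed = 24)
  ep <- tiny_epochs(sc)
  folds <- make_folds(ep, n_folds = 4, seed = 24)
  pred <- project_to_sensors(sc$gain, predict_cortical(sc$prfs,
                                                       cached_stimuli()))
  fit <- fit_timecourse(pred, ep, folds)
  grp <- c(2, 5, 9)
  pl <- average_ve(fit, grp)
  w <- fit$tss[, grp, , drop = FALSE]
  wmean <- apply(fit$ve[, grp, , drop = FALSE] * w, c(1, 3), sum) /
    apply(w, c(1, 3), sum)
  expect_equal(pl, wmean, tolerance = 1e-12)
})

test_that("fold summaries use linear-interpolation percentiles", {
  m <- matrix(rep(5, 20), 20, 1)
  s <- fit_summary(m)
  expect_equal(c(s$median, s$ci_low, s$ci_high), c(5, 5, 5))
  s2 <- fit_summary(matrix(1:120, 120, 1))
  expect_equal(s2$median, 60.5)
  expect_equal(s2$ci_low, 3.975)
  expect_equal(s2$ci_high, 117.025)
  # an extreme fold moves the CI but barely the median
  s3 <- fit_summary(matrix(c(1:120, 1e6), 121, 1))
  expect_lt(abs(s3$median - 61), 1)
  expect_gt(s3$ci_high, s2$ci_high)
  # missing folds are ignored
  s4 <- fit_summary(matrix(c(1:119, NA), 120, 1))
  expect_equal(s4$median, 60)
})

test_that("sensor groups implement the active/early/earliest definitions", {
  t_ms <- seq(-100, 600)
  S <- 306
  med <- matrix(-1, S, length(t_ms))
  # sensor s crosses 0.5 at latency s-1 ms after onset; sensors 301..306 never
  for (s in 1:300) med[s, t_ms >= (s - 1)] <- 0.8
  summ <- structure(list(median = med, ci_low = med, ci_high = med,
                         time_ms = t_ms, n_folds = 10), class = "fit_summary")
  g <- sensor_groups(summ)
  expect_length(g$earliest$members, 76)          # floor(0.25 * 306)
  expect_equal(g$earliest$members, 1:76)         # fastest crossers, in order
  expect_setequal(g$active$members, 1:300)
  expect_true(all(g$early$members %in% g$active$members))
  # early group: threshold reached inside 50-150 ms
  expect_setequal(g$early$members, 1:151)
  # never-crossing sensors are in no group
  expect_false(any(301:306 %in% c(g$active$members, g$early$members,
                                  g$earliest$members)))
  # fewer crossers than requested: all crossers, with a warning
  med2 <- med; med2[6:306, ] <- -1
  summ2 <- structure(list(median = med2, ci_low = med2, ci_high = med2,
                          time_ms = t_ms, n_folds = 10),
                     class = "fit_summary")
  expect_warning(g2 <- sensor_groups(summ2), "crossers")
  expect_equal(g2$earliest$members, 1:5)
})
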