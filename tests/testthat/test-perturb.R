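test_that("significant_latencies implements one-sided CI non-overlap", {
  mk <- function(lo, hi) structure(
    list(median = (lo + hi) / 2, ci_low = lo, ci_high = hi,
         time_ms = seq_along(lo), n_folds = 10), class = "fit_summary")
  base <- mk(c(0.4, 0.4, 0.4), c(0.6, 0.6, 0.6))
  expect_equal(significant_latencies(base, base), c(FALSE, FALSE, FALSE))
  shifted <- mk(c(0.0, 0.0, 0.3), c(0.1, 0.4, 0.5))
  expect_equal(significant_latencies(base, shifted), c(TRUE, FALSE, FALSE))
  touching <- mk(c(0.1, 0.1, 0.1), c(0.4, 0.4, 0.4))  # hi == baseline lo
  expect_equal(significant_latencies(base, touching), c(FALSE, FALSE, FALSE))
  expect_true(is.na(significant_latencies(base, mk(c(0, NA, 0), c(0, NA, 0)))[2]))
})

test_that("angle 0 of the shift analysis reproduces the baseline fit exactly", {
  sc <- tiny_scene(seed = 31)
  ep <- tiny_epochs(sc)
  folds <- make_folds(ep, n_folds = 5, seed = 31)
  stim <- cached_stimuli()
  pred <- project_to_sensors(sc$gain, predict_cortical(sc$prfs, stim))
  fit <- fit_timecourse(pred, ep, folds)
  sh <- run_shift_analysis(sc$prfs, stim, sc$gain, ep, folds,
                           angles = c(-90, 0, 90), keep_fits = TRUE)
  expect_identical(sh$fits[["0"]]$ve, fit$ve)
  expect_identical(sh$fits[["0"]]$b1, fit$b1)
  expect_equal(significant_latencies(sh$pooled[["0"]]$all,
                                     sh$pooled[["0"]]$all),
               rep(FALSE, length(ep$time_ms)))
  expect_error(run_shift_analysis(sc$prfs, stim, sc$gain, ep, folds,
                                  angles = c(-90, 90)), "include 0")
})

test_that("a rotation-invariant scene is unaffected by shifting", {
  # all pRFs at fixation: rotating them is the identity, so every angle must
  # give the same fit (shared folds make this exact)
  stim <- cached_stimuli()
  prfs <- prf_set(x0 = rep(0, 30), y0 = rep(0, 30),
                  sigma = seq(0.3, 1.5, length.out = 30))
  sc <- tiny_scene(seed = 32, n_vertices = 30)
  sc$prfs <- prfs
  ep <- tiny_epochs(sc)
  folds <- make_folds(ep, n_folds = 4, seed = 32)
  sh <- run_shift_analysis(prfs, stim, sc$gain, ep, folds,
                           angles = c(0, 45, 90), keep_fits = TRUE)
  expect_equal(sh$fits[["45"]]$ve, sh$fits[["0"]]$ve, tolerance = 1e-12)
  expect_equal(sh$fits[["90"]]$ve, sh$fits[["0"]]$ve, tolerance = 1e-12)
})

test_that("shifting pRFs away from truth lowers variance explained", {
  sc <- tiny_scene(seed = 33, n_vertices = 80, n_sensors = 14,
                   n_epochs = 24, noise_sd = 60)
  stim <- cached_stimuli()
  ep <- tiny_epochs(sc)
  folds <- make_folds(ep, n_folds = 24, seed = 33)
  sh <- run_shift_analysis(sc$prfs, stim, sc$gain, ep, folds,
                           angles = c(-90, 0, 90))
  peak <- vapply(sh$pooled, function(p) max(p$all$median), numeric(1))
  expect_gt(peak[["0"]], peak[["-90"]])
  expect_gt(peak[["0"]], peak[["90"]])
  # the ±90° fits are significantly worse somewhere in the response window
  resp <- ep$time_ms >= 50 & ep$time_ms <= 300
  expect_true(any(sh$significant[["90"]]$all[resp]))
})

test_that("shift_table flattens the pooled summaries", {
  sc <- tiny_scene(seed = 34)
  ep <- tiny_epochs(sc)
  folds <- make_folds(ep, n_folds = 4, seed = 34)
  sh <- run_shift_analysis(sc$prfs, cached_stimuli(), sc$gain, ep, folds,
                           angles = c(0, 90))
  tab <- shift_table(sh)
  expect_s3_class(tab, "data.frame")
  expect_setequal(unique(tab$angle_deg), c(0, 90))
  expect_true(all(c("median_ve", "ci_low", "ci_high", "significant")
                  %in% names(tab)))
  expect_equal(nrow(tab), 2 * length(unique(tab$group)) * length(ep$time_ms))
})
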