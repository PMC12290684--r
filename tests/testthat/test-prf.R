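test_that("gaussian_prf is a unit-amplitude radially symmetric Gaussian", {
  g <- make_grid(9.77, 101)
  f <- gaussian_prf(0, 0, 1.5, g)
  expect_equal(f[51, 51], 1)                      # value at the center
  # value one sigma away along x
  ix <- which.min(abs(g$x - 1.5))
  expect_equal(f[51, ix], exp(-(g$x[ix])^2 / (2 * 1.5^2)))
  expect_equal(f, t(f))                           # symmetric grid, centered pRF
  expect_error(gaussian_prf(0, 0, -1, g), "sigma")
})

test_that("the two-gamma HRF basis behaves canonically", {
  h <- hrf_kernel(c(1, 0, 0), TR = 0.1)
  expect_equal(h$times[which.max(h$values)], 5, tolerance = 0.05)
  # temporal derivative of a decaying function integrates to ~0
  hd <- hrf_kernel(c(0, 1, 0), TR = 0.1)
  expect_lt(abs(sum(hd$values) * 0.1), 0.01)
  expect_true(all(hrf_kernel(c(0, 0, 0))$values == 0))
})

test_that("predict_bold is the overlap time course convolved with the HRF", {
  g <- make_grid(10.68, 31)
  hrf <- hrf_kernel(TR = 1.5)
  n_frames <- 40
  blank <- matrix(0, n_frames, g$n_pixels^2)
  expect_true(all(predict_bold(1, 1, 0.8, blank, hrf, g)$values == 0))

  # single all-ones frame acts as an impulse of the pRF's total grid mass
  imp <- blank
  imp[1, ] <- 1
  out <- predict_bold(0.5, -0.3, 0.9, imp, hrf, g)$values
  mass <- sum(gaussian_prf(0.5, -0.3, 0.9, g))
  nk <- length(hrf$values)
  expect_equal(out[seq_len(nk)], mass * hrf$values)
  expect_true(all(out[-seq_len(nk)] == 0))

  # linearity: doubling the overlaps doubles the prediction
  two <- blank; two[1, ] <- 2
  expect_equal(predict_bold(0.5, -0.3, 0.9, two, hrf, g)$values, 2 * out)
})

test_that("fit_prf recovers noiseless pRF parameters within 0.1 deg", {
  g <- make_grid(10.68, 51)
  seqs <- fmri_bar_sequence(g)
  F <- frame_matrix(seqs)
  hrf <- hrf_kernel()
  truth <- rbind(c(2.0, 1.0, 0.8), c(-1.5, -2.5, 1.6), c(0.2, 3.0, 0.5))
  for (i in seq_len(nrow(truth))) {
    ts <- predict_bold(truth[i, 1], truth[i, 2], truth[i, 3], F, hrf, g)
    fit <- fit_prf(ts, F, hrf, g)
    expect_lt(abs(fit$x0 - truth[i, 1]), 0.1)
    expect_lt(abs(fit$y0 - truth[i, 2]), 0.1)
    expect_lt(abs(fit$sigma - truth[i, 3]), 0.1)
    expect_gt(fit$r2, 0.99)
  }
})

test_that("fit_prf degrades gracefully on noise and degenerate input", {
  g <- make_grid(10.68, 31)
  seqs <- fmri_bar_sequence(g)
  F <- frame_matrix(seqs)
  hrf <- hrf_kernel()
  set.seed(42)
  noise_fit <- fit_prf(rnorm(nrow(F)), F, hrf, g,
                       coarse = list(n_ecc = 4, n_angle = 6))
  expect_lt(noise_fit$r2, 0.3)
  flat <- fit_prf(rep(1, nrow(F)), F, hrf, g)
  expect_false(flat$reliable)
  expect_equal(flat$r2, 0)
})

test_that("vertex selection applies the three inclusion criteria", {
  p <- prf_set(x0 = c(3, 3, 0, 5, 1), y0 = c(4, 4, 0, 0, 0),
               sigma = rep(1, 5), r2 = c(0.15, 0.149, 0.5, 0.9, 0.3))
  keep <- select_vertices(p, 0.15, window_radius = 5)
  expect_equal(keep, c(TRUE, FALSE, TRUE, TRUE, TRUE))  # boundary inclusive
  keep2 <- select_vertices(p, 0.15, 5, vein_mask = c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_false(keep2[1])                          # vein trumps r2
  expect_false(select_vertices(p, 0.15, 4.9)[4])  # ecc 5 > 4.9 excluded
  expect_error(select_vertices(p, 1.5, 5), "0, 1")
})

test_that("pRF tables round-trip through CSV and TSV", {
  p <- make_synthetic_prfs(7, seed = 3)
  p$include[2] <- FALSE
  for (ext in c(".csv", ".tsv")) {
    path <- tempfile(fileext = ext)
    write_prf_set(p, path)
    q <- read_prf_set(path)
    expect_equal(q$x0, p$x0, tolerance = 1e-12)
    expect_equal(q$sigma, p$sigma, tolerance = 1e-12)
    expect_identical(q$include, p$include)
    unlink(path)
  }
})
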