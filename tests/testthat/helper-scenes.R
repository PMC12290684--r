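# Shared fixtures, built in code. Stimulus sets are cached per grid size:
# rebuilding 18 apertures for every test is pure waste.
.fixture_cache <- new.env(parent = emptyenv())

cached_stimuli <- function(n_pixels = 61, fov = 9.77) {
  key <- sprintf("stim_%d_%g", n_pixels, fov)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- meg_stimulus_set(make_grid(fov, n_pixels))
  }
  .fixture_cache[[key]]
}

# a small scene + simulated epochs, enough for fit-level tests in ~a second
tiny_scene <- function(seed = 1, n_vertices = 40, n_sensors = 10,
                       n_epochs = 8, noise_sd = 100, ...) {
  synthetic_scene(n_vertices = n_vertices, n_sensors = n_sensors,
                  n_epochs = n_epochs, noise_sd = noise_sd, seed = seed, ...)
}

tiny_epochs <- function(scene, stimuli = cached_stimuli()) {
  baseline_correct(simulate_epochs(scene, stimuli))
}

# analytic area of the strip |u| <= half_width clipped to a circle of radius R
strip_circle_area <- function(half_width, R) {
  h <- min(half_width, R)
  2 * (h * sqrt(R^2 - h^2) + R^2 * asin(h / R))
}

# brute-force 1-D least-squares minimizer: coarse grid scan followed by a
# parabolic-vertex step (exact for a quadratic objective, up to rounding).
# Uses only RSS evaluations, never the closed form it is checking.
brute_force_scale <- function(p, y, lim = 50, step = 0.25) {
  rss <- function(b) sum((y - b * p)^2)
  grid <- seq(-lim, lim, by = step)
  i <- which.min(vapply(grid, rss, 0))
  i <- min(max(i, 2L), length(grid) - 1L)
  f <- vapply(grid[(i - 1):(i + 1)], rss, 0)
  grid[i] - 0.5 * step * (f[3] - f[1]) / (f[3] - 2 * f[2] + f[1])
}
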