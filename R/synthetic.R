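#' Synthetic cortical pRF map
#'
#' Draws vertices with pRF centers uniform over the disc of radius
#' `window_radius` and sizes following the empirical eccentricity-size
#' coupling sigma = a + b * eccentricity. Fit quality r2 is drawn uniformly in
#' (0.15, 1] so every generated vertex passes [select_vertices()] at the 0.15
#' threshold.
#'
#' @param n_vertices Number of vertices (>= 1).
#' @param window_radius Radius of the stimulated visual field, degrees
#'   (default 9.77 / 2, the MEG presentation window).
#' @param seed Integer seed; the set is fully reproducible from it.
#' @param sigma_intercept,sigma_slope Coefficients of the eccentricity-size
#'   rule, degrees (defaults 0.3 and 0.15).
#' @return A [prf_set()] with all vertices included.
#' @export
make_synthetic_prfs <- function(n_vertices, window_radius = 9.77 / 2,
                                seed = 1, sigma_intercept = 0.3,
                                sigma_slope = 0.15) {
  stopifnot(n_vertices >= 1)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(as.integer(seed))
  ecc <- window_radius * sqrt(stats::runif(n_vertices))  # uniform over disc
  ang <- stats::runif(n_vertices, 0, 2 * pi)
  r2 <- stats::runif(n_vertices, 0.15, 1)
  prf_set(x0 = ecc * cos(ang), y0 = ecc * sin(ang),
          sigma = sigma_intercept + sigma_slope * ecc, r2 = r2)
}

# smooth signed "polarity" field over visual-field position: stands in for
# dipole orientation so that nearby/identical pRFs mix with the same sign
# while distant ones can cancel at a sensor
.polarity_field <- function(x, y) {
  sin(1.3 * x + 2.1 * y + 0.7)
}

#' Synthetic gain matrix with smooth overlapping sensitivity profiles
#'
#' Each sensor is assigned a preferred visual-field locus (sunflower layout
#' over the pRF disc); its weight for a vertex decays as a Gaussian of the
#' distance between that locus and the vertex's pRF center, multiplied by a
#' smooth signed polarity field of the pRF position (so columns of nearby
#' vertices are near-identical while distant vertices can cancel, mimicking
#' dipole polarity), plus small Gaussian jitter that makes the matrix full
#' rank. No dipole physics is modeled: the pipeline's contracts are
#' linear-algebraic, and smooth overlapping signed mixing is the property that
#' matters (field spread and cancellation).
#'
#' @param n_sensors Number of sensors (>= 2).
#' @param prfs A [prf_set()] (pRF centers define the vertex loci), or a
#'   two-column matrix of positions.
#' @param seed Integer seed (drives only the jitter).
#' @param spread Gaussian spatial decay of sensor sensitivity, degrees
#'   (default 2).
#' @param jitter_sd Standard deviation of the additive jitter (default 0.02;
#'   deterministic part has unit scale).
#' @return A [gain_matrix()], `n_sensors` x vertices.
#' @export
make_synthetic_gain <- function(n_sensors, prfs, seed = 1, spread = 2,
                                jitter_sd = 0.02) {
  stopifnot(n_sensors >= 2)
  pos <- if (inherits(prfs, "prf_set")) cbind(prfs$x0, prfs$y0) else as.matrix(prfs)
  V <- nrow(pos)
  R <- max(sqrt(rowSums(pos^2)), 1) * 1.1
  i <- seq_len(n_sensors)
  golden <- pi * (3 - sqrt(5))
  sx <- R * sqrt(i / n_sensors) * cos(i * golden)
  sy <- R * sqrt(i / n_sensors) * sin(i * golden)
  d2 <- outer(sx, pos[, 1], `-`)^2 + outer(sy, pos[, 2], `-`)^2
  W <- exp(-d2 / (2 * spread^2)) *
    matrix(.polarity_field(pos[, 1], pos[, 2]), n_sensors, V, byrow = TRUE)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(as.integer(seed))
  W <- W + matrix(stats::rnorm(n_sensors * V, sd = jitter_sd), n_sensors, V)
  gain_matrix(W)
}

#' Default evoked temporal kernel
#'
#' The unitless amplitude time course multiplying the sensor predictions in
#' the simulator: exactly zero up to 50 ms after stimulus onset, then two
#' positive lobes peaking near 100 ms and 200 ms with a dip near 150 ms,
#' decayed to approximately zero by 300 ms; peak amplitude normalized to 1.
#' This mimics the biphasic shape of early visual evoked fields.
#'
#' @param time_ms Time axis in ms (default -100..600 at 1 ms).
#' @return Numeric vector of kernel values, one per sample.
#' @export
make_default_kernel <- function(time_ms = seq(-100, 600)) {
  ramp <- ifelse(time_ms <= 50, 0, 1 - exp(-(time_ms - 50)^2 / (2 * 15^2)))
  k <- ramp * (exp(-(time_ms - 100)^2 / (2 * 20^2)) +
                 0.85 * exp(-(time_ms - 200)^2 / (2 * 30^2)))
  k / max(k)
}

#' Synthetic scene: ground-truth pRFs, gain and noise model
#'
#' Bundles everything [simulate_epochs()] needs: a ground-truth pRF map, a
#' gain matrix, the evoked temporal kernel, the sensor noise scale and the
#' epoch count per stimulus. The defaults (500 vertices, 60 sensors, 60
#' epochs per stimulus, 1 ms sampling over -100..600 ms, peak evoked
#' amplitude 100 sensor units with per-sample noise SD 100, i.e. single-epoch
#' peak SNR of about 1 at the best sensor) emulate a realistic visual-evoked
#' MEG regime while keeping the full pipeline plus the 9-angle perturbation
#' analysis tractable on one CPU. All randomness flows from `seed`.
#'
#' @param n_vertices,n_sensors,n_epochs Scene sizes.
#' @param noise_sd White Gaussian sensor noise SD per sample, sensor units.
#' @param signal_peak Peak absolute sensor template amplitude after scaling,
#'   sensor units (default 100).
#' @param window_radius pRF disc radius, degrees.
#' @param time_ms Epoch time axis, ms.
#' @param seed Master seed.
#' @return An object of class `synthetic_scene` with elements `prfs`, `gain`,
#'   `kernel`, `time_ms`, `noise_sd`, `signal_peak`, `n_epochs`, `seed`.
#' @export
synthetic_scene <- function(n_vertices = 500, n_sensors = 60, n_epochs = 60,
                            noise_sd = 100, signal_peak = 100,
                            window_radius = 9.77 / 2,
                            time_ms = seq(-100, 600), seed = 1) {
  seed <- as.integer(seed)
  prfs <- make_synthetic_prfs(n_vertices, window_radius, seed = seed)
  gain <- make_synthetic_gain(n_sensors, prfs, seed = seed + 1L)
  structure(
    list(prfs = prfs, gain = gain, kernel = make_default_kernel(time_ms),
         time_ms = time_ms, noise_sd = noise_sd, signal_peak = signal_peak,
         n_epochs = n_epochs, window_radius = window_radius, seed = seed),
    class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene> %d vertices, %d sensors, %d epochs/stimulus, noise SD %g (seed %d)\n",
    nrow(x$prfs), nrow(x$gain), x$n_epochs, x$noise_sd, x$seed))
  invisible(x)
}

#' Simulate noisy epoched sensor data from a scene
#'
#' Every epoch of stimulus k is
#' `template[, k] * kernel(t) + noise`, where the sensor templates are the
#' forward-model predictions `gain %*% predict_cortical(prfs, stimuli)`
#' rescaled so the largest absolute template value equals
#' `scene$signal_peak`, and the noise is independent white Gaussian with SD
#' `scene$noise_sd` per sample. Labels are balanced across stimuli
#' (`n_epochs` each). The noiseless epoch mean therefore equals
#' gain x (pRF-stimulus overlap) x kernel at every latency. Epochs are
#' returned raw (not baseline corrected); apply [baseline_correct()] as in
#' the analysis pipeline.
#'
#' @param scene A [synthetic_scene()].
#' @param stimuli A [meg_stimulus_set()].
#' @return An [epoch_data()] with attributes `templates` (sensors x stimuli,
#'   scaled) and `scene`.
#' @export
simulate_epochs <- function(scene, stimuli) {
  stopifnot(inherits(scene, "synthetic_scene"),
            inherits(stimuli, "stimulus_set"))
  cortical <- predict_cortical(scene$prfs, stimuli)
  SP <- project_to_sensors(scene$gain, cortical)
  peak <- max(abs(SP))
  if (peak == 0) stop("scene produces all-zero sensor predictions")
  SP <- SP * (scene$signal_peak / peak)
  K <- ncol(SP); S <- nrow(SP); Tn <- length(scene$time_ms)
  labels <- rep(stimuli$labels, each = scene$n_epochs)
  E <- length(labels)
  signal <- outer(t(SP[, labels, drop = FALSE]), scene$kernel)   # E x S x Tn
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(scene$seed + 2L)
  if (scene$noise_sd > 0) {
    for (s in seq_len(S)) {                      # sensor blocks: small temps
      signal[, s, ] <- signal[, s, ] +
        stats::rnorm(E * Tn, sd = scene$noise_sd)
    }
  }
  out <- epoch_data(signal, scene$time_ms, labels,
                    stimulus_labels = stimuli$labels)
  attr(out, "templates") <- SP
  attr(out, "scene") <- scene
  out
}
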