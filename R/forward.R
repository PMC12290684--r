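#' Gain matrix (lead field)
#'
#' Wraps a sensors x vertices matrix of linear mixing weights describing how
#' unit activity at each cortical vertex appears at each MEG sensor (fT for
#' magnetometers, fT/m for planar gradiometers, per unit source amplitude).
#'
#' @param weights Numeric matrix, sensors x vertices, all finite.
#' @param sensor_labels Optional character vector of sensor names.
#' @param sensor_kinds Optional character vector, `"magnetometer"` or
#'   `"gradiometer"` per sensor.
#' @return A `gain_matrix` (a numeric matrix with attributes).
#' @export
gain_matrix <- function(weights, sensor_labels = NULL, sensor_kinds = NULL) {
  weights <- as.matrix(weights)
  if (!all(is.finite(weights))) stop("gain weights must all be finite")
  if (nrow(weights) < 1 || ncol(weights) < 1) {
    stop("gain matrix needs at least one sensor and one vertex")
  }
  if (is.null(sensor_labels)) {
    sensor_labels <- sprintf("MEG%03d", seq_len(nrow(weights)))
  }
  if (is.null(sensor_kinds)) {
    sensor_kinds <- rep("magnetometer", nrow(weights))
  }
  stopifnot(length(sensor_labels) == nrow(weights),
            length(sensor_kinds) == nrow(weights))
  rownames(weights) <- sensor_labels
  structure(weights, sensor_kinds = sensor_kinds,
            class = c("gain_matrix", class(weights)))
}

#' @export
print.gain_matrix <- function(x, ...) {
  cat(sprintf("<gain_matrix> %d sensors x %d vertices\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Predict cortical responses to a stimulus set
#'
#' For every vertex and stimulus, the predicted cortical response is the
#' overlap of the vertex's pRF Gaussian with the binarized stimulus aperture:
#' the sum over pixels of Gaussian x mask (a matrix product of the flattened
#' pRF fields with the stimulus masks). Excluded vertices get all-zero rows so
#' that the result stays aligned with gain-matrix columns.
#'
#' @param prfs A [prf_set()].
#' @param stimuli A [meg_stimulus_set()] (all apertures on one grid).
#' @return Numeric matrix, vertices x stimuli, non-negative; columns named by
#'   stimulus label.
#' @export
predict_cortical <- function(prfs, stimuli) {
  stopifnot(inherits(prfs, "prf_set"), inherits(stimuli, "stimulus_set"))
  G <- .prf_field_matrix(prfs, stimuli$grid)
  M <- stimulus_matrix(stimuli)
  out <- G %*% t(M)
  colnames(out) <- stimuli$labels
  out
}

#' Project cortical predictions to sensor space
#'
#' Plain matrix product of the gain matrix (sensors x vertices) with the
#' cortical predictions (vertices x stimuli); no normalization or unit
#' conversion — the scaling factor b1 of the ERF fit absorbs all scale.
#'
#' @param gain A [gain_matrix()] (or bare sensors x vertices matrix).
#' @param cortical Vertices x stimuli matrix from [predict_cortical()].
#' @return Numeric matrix, sensors x stimuli.
#' @export
project_to_sensors <- function(gain, cortical) {
  if (ncol(gain) != nrow(cortical)) {
    stop(sprintf("gain has %d vertex columns but cortical prediction has %d rows",
                 ncol(gain), nrow(cortical)))
  }
  out <- unclass(gain) %*% cortical
  attr(out, "sensor_kinds") <- attr(gain, "sensor_kinds")
  out
}

#' Rotate pRF centers in polar angle
#'
#' Rotates every pRF center about fixation by `angle` degrees
#' (counterclockwise positive in the +x right / +y up convention); sigma, r2
#' and the inclusion mask are untouched, so eccentricity is preserved exactly
#' and the vertex set stays frozen at its unshifted state.
#'
#' @param prfs A [prf_set()].
#' @param angle Rotation in degrees; positive = counterclockwise.
#' @return A `prf_set` with rotated centers.
#' @export
shift_polar_angle <- function(prfs, angle) {
  stopifnot(inherits(prfs, "prf_set"), is.finite(angle))
  if (angle == 0) return(prfs)
  th <- angle * pi / 180
  x <- prfs$x0 * cos(th) - prfs$y0 * sin(th)
  y <- prfs$x0 * sin(th) + prfs$y0 * cos(th)
  out <- prfs
  out$x0 <- x
  out$y0 <- y
  out
}
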