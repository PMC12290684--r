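#' Visual-field pixel grid
#'
#' Constructs a square pixel grid over the visual field, in degrees of visual
#' angle, with fixation at the origin, +x to the right and +y up. Pixel centers
#' are evenly spaced and symmetric about the origin, spanning
#' (-fov/2, +fov/2) on both axes. Stimulus masks and pRF fields are sampled at
#' these pixel centers.
#'
#' @param fov_diameter Field of view (= diameter of the circular presentation
#'   window) in degrees of visual angle.
#' @param n_pixels Number of pixels per side (>= 2). Odd values place a pixel
#'   exactly at fixation.
#' @return An object of class `vf_grid` with elements `fov_diameter`,
#'   `n_pixels`, `pixel_size`, `x`, `y` (pixel-center coordinates, degrees) and
#'   matrices `X`, `Y` of per-pixel center coordinates (ny x nx; row = y,
#'   column = x, y increasing with row index).
#' @examples
#' g <- make_grid(10.68, 101)
#' g$pixel_size
#' @export
make_grid <- function(fov_diameter, n_pixels) {
  if (!is.numeric(fov_diameter) || length(fov_diameter) != 1L ||
      !is.finite(fov_diameter) || fov_diameter <= 0) {
    stop("`fov_diameter` must be a single positive number (degrees)")
  }
  if (!is.numeric(n_pixels) || length(n_pixels) != 1L ||
      n_pixels != round(n_pixels) || n_pixels < 2) {
    stop("`n_pixels` must be a single integer >= 2")
  }
  n_pixels <- as.integer(n_pixels)
  px <- fov_diameter / n_pixels
  # centers of n equal-width pixels tiling (-fov/2, fov/2)
  centers <- -fov_diameter / 2 + (seq_len(n_pixels) - 0.5) * px
  grid <- list(
    fov_diameter = fov_diameter,
    n_pixels = n_pixels,
    pixel_size = px,
    x = centers,
    y = centers,
    X = matrix(rep(centers, each = n_pixels), nrow = n_pixels),
    Y = matrix(rep(centers, times = n_pixels), nrow = n_pixels)
  )
  class(grid) <- "vf_grid"
  grid
}

#' @export
print.vf_grid <- function(x, ...) {
  cat(sprintf("<vf_grid> %d x %d pixels, fov %.3f deg, pixel %.4f deg\n",
              x$n_pixels, x$n_pixels, x$fov_diameter, x$pixel_size))
  invisible(x)
}

# circular presentation window: TRUE where a pixel center lies inside the
# window of the grid's field of view
.window_mask <- function(grid) {
  (grid$X^2 + grid$Y^2) <= (grid$fov_diameter / 2)^2
}

.new_aperture <- function(label, mask, shape_kind, geometry, grid) {
  structure(
    list(label = label, mask = mask, shape_kind = shape_kind,
         geometry = geometry, grid = grid),
    class = "stim_aperture"
  )
}

#' @export
print.stim_aperture <- function(x, ...) {
  cat(sprintf("<stim_aperture> '%s' (%s), %d of %d pixels on\n",
              x$label, x$shape_kind, sum(x$mask), length(x$mask)))
  invisible(x)
}

.orientation_deg <- function(orientation) {
  if (is.character(orientation)) {
    orientation <- match.arg(orientation, c("horizontal", "vertical"))
    return(switch(orientation, horizontal = 0, vertical = 90))
  }
  if (!is.numeric(orientation) || length(orientation) != 1L ||
      !is.finite(orientation)) {
    stop("`orientation` must be 'horizontal', 'vertical' or an angle in degrees")
  }
  orientation
}

#' Bar aperture
#'
#' Binarized bar stimulus: a strip of given width whose long axis runs at the
#' given orientation, displaced from fixation by `offset` along the bar's
#' normal, intersected with the circular presentation window. A pixel belongs
#' to the bar iff its center is within `width/2` of the bar's center line
#' (pixel-center membership, deterministic).
#'
#' @param grid A [make_grid()] grid.
#' @param orientation `"horizontal"`, `"vertical"`, or a numeric long-axis
#'   angle in degrees (0 = horizontal, 90 = vertical, counterclockwise).
#' @param offset Signed displacement of the bar center line from fixation along
#'   the unit normal `(-sin(theta), cos(theta))`, degrees. For horizontal bars
#'   positive offsets move the bar up; mirrored offsets give mirror-image masks.
#' @param width Bar width, degrees.
#' @param label Optional label; a descriptive default is generated.
#' @return A `stim_aperture`.
#' @export
bar_aperture <- function(grid, orientation, offset, width, label = NULL) {
  stopifnot(inherits(grid, "vf_grid"))
  theta <- .orientation_deg(orientation)
  if (!is.numeric(offset) || length(offset) != 1L || !is.finite(offset)) {
    stop("`offset` must be a single finite number (degrees)")
  }
  if (!is.numeric(width) || length(width) != 1L || width <= 0) {
    stop("`width` must be a single positive number (degrees)")
  }
  if (abs(offset) - width / 2 >= grid$fov_diameter / 2) {
    stop("bar lies entirely outside the presentation window")
  }
  th <- theta * pi / 180
  # perpendicular distance of each pixel center from the bar's center line
  d <- abs(-grid$X * sin(th) + grid$Y * cos(th) - offset)
  mask <- (d <= width / 2) & .window_mask(grid)
  if (is.null(label)) {
    label <- sprintf("bar_%s_off%+.2f", if (is.character(orientation))
      substr(orientation, 1, 1) else paste0(theta, "deg"), offset)
  }
  .new_aperture(label, mask, "bar",
                list(orientation_deg = theta, offset = offset, width = width),
                grid)
}

#' Circle aperture
#'
#' Binarized disc stimulus centered on the 45-degree diagonal of one visual
#' quadrant at a given eccentricity.
#'
#' @param grid A [make_grid()] grid.
#' @param quadrant Integer 1..4: quadrant 1 is upper right, counted
#'   counterclockwise (2 upper left, 3 lower left, 4 lower right).
#' @param eccentricity Distance of the disc center from fixation, degrees.
#' @param diameter Disc diameter, degrees.
#' @param label Optional label.
#' @return A `stim_aperture`.
#' @export
circle_aperture <- function(grid, quadrant, eccentricity, diameter,
                            label = NULL) {
  stopifnot(inherits(grid, "vf_grid"))
  if (!quadrant %in% 1:4) stop("`quadrant` must be 1, 2, 3 or 4")
  if (!is.numeric(eccentricity) || eccentricity <= 0) {
    stop("`eccentricity` must be positive (degrees)")
  }
  if (!is.numeric(diameter) || diameter <= 0) {
    stop("`diameter` must be positive (degrees)")
  }
  if (eccentricity + diameter / 2 > grid$fov_diameter / 2) {
    stop("disc crosses the edge of the presentation window")
  }
  ang <- (45 + 90 * (quadrant - 1)) * pi / 180
  cx <- eccentricity * cos(ang)
  cy <- eccentricity * sin(ang)
  mask <- ((grid$X - cx)^2 + (grid$Y - cy)^2) <= (diameter / 2)^2
  mask <- mask & .window_mask(grid)
  if (is.null(label)) {
    label <- sprintf("circle_q%d_ecc%.2f", quadrant, eccentricity)
  }
  .new_aperture(label, mask, "circle",
                list(quadrant = quadrant, eccentricity = eccentricity,
                     diameter = diameter, center = c(cx, cy)),
                grid)
}

.blank_aperture <- function(grid, label = "blank") {
  .new_aperture(label, matrix(FALSE, grid$n_pixels, grid$n_pixels),
                "blank", list(), grid)
}

.new_stimulus_set <- function(apertures, grid) {
  labels <- vapply(apertures, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("aperture labels must be unique")
  structure(list(apertures = apertures, labels = labels, grid = grid),
            class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("<stimulus_set> %d apertures on a %dx%d grid (fov %.2f deg)\n",
              length(x$apertures), x$grid$n_pixels, x$grid$n_pixels,
              x$grid$fov_diameter))
  invisible(x)
}

#' @export
length.stimulus_set <- function(x) length(x$apertures)

#' Stimulus masks as a matrix
#'
#' Flattens a stimulus set into a stimuli x pixels binary matrix (0/1), rows
#' ordered and named as the set's labels. This is the form used for overlap
#' prediction.
#'
#' @param stimuli A `stimulus_set`.
#' @return Numeric matrix, n_stimuli x n_pixels.
#' @export
stimulus_matrix <- function(stimuli) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  m <- t(vapply(stimuli$apertures, function(a) as.numeric(a$mask),
                numeric(stimuli$grid$n_pixels^2)))
  rownames(m) <- stimuli$labels
  m
}

#' The 18-stimulus MEG set
#'
#' Builds the fixed MEG stimulus set: 10 bars (horizontal and vertical, each at
#' offsets 0 and +/-1.28, +/-3.06 deg from fixation, width 1.25 deg) and 8
#' circles (one per quadrant at eccentricity 1.28 deg with diameter 1.25 deg,
#' and one per quadrant at eccentricity 3.06 deg with diameter 2.5 deg),
#' 18 apertures in total. Circles sit on the 45-degree diagonal of their
#' quadrant.
#'
#' @param grid A [make_grid()] grid with fov >= 9.77 deg (default geometry of
#'   the MEG presentation window).
#' @param bar_width Bar width in degrees (default 1.25).
#' @param bar_offsets Bar center offsets in degrees (default 0, +/-1.28,
#'   +/-3.06).
#' @param circle_spec Two-column matrix of (eccentricity, diameter) pairs for
#'   the circle stimuli (default (1.28, 1.25) and (3.06, 2.5)).
#' @return A `stimulus_set` of 18 apertures.
#' @examples
#' s <- meg_stimulus_set(make_grid(9.77, 101))
#' length(s)
#' @export
meg_stimulus_set <- function(grid = make_grid(9.77, 101),
                             bar_width = 1.25,
                             bar_offsets = c(0, -1.28, 1.28, -3.06, 3.06),
                             circle_spec = cbind(ecc = c(1.28, 3.06),
                                                 diam = c(1.25, 2.5))) {
  stopifnot(inherits(grid, "vf_grid"))
  if (grid$fov_diameter < 9.77) {
    stop("grid fov must cover the 9.77 deg MEG presentation window")
  }
  aps <- list()
  for (orient in c("vertical", "horizontal")) {
    for (off in bar_offsets) {
      aps[[length(aps) + 1L]] <- bar_aperture(grid, orient, off, bar_width)
    }
  }
  for (i in seq_len(nrow(circle_spec))) {
    for (q in 1:4) {
      aps[[length(aps) + 1L]] <- circle_aperture(
        grid, q, circle_spec[i, 1], circle_spec[i, 2])
    }
  }
  .new_stimulus_set(aps, grid)
}

#' fMRI pRF-mapping bar sweep sequence
#'
#' Generates the frame sequence of the pRF-mapping run: a 1.25-deg-wide bar
#' swept across the circular presentation window in 20 discrete steps, in 8
#' configurations (4 orientations, 0/45/90/135 deg, each with the two opposing
#' sweep directions), with a mean-luminance blank block after every two bar
#' passes. Each bar frame lasts 1.5 s (one TR); each blank block lasts 15 s
#' (10 frames of 1.5 s), giving 160 bar frames + 40 blank frames = 200 frames.
#'
#' @param grid A [make_grid()] grid with fov >= 10.68 deg.
#' @param bar_width Bar width, degrees (default 1.25).
#' @param n_steps Steps per sweep (default 20).
#' @param step_duration Frame duration in seconds (default 1.5, one TR).
#' @param blank_duration Blank block duration in seconds (default 15).
#' @return A list with `apertures` (list of `stim_aperture`, blanks included),
#'   `durations` (seconds per frame) and `is_blank` (logical per frame).
#' @export
fmri_bar_sequence <- function(grid = make_grid(10.68, 101), bar_width = 1.25,
                              n_steps = 20, step_duration = 1.5,
                              blank_duration = 15) {
  stopifnot(inherits(grid, "vf_grid"))
  if (grid$fov_diameter < 10.68) {
    stop("grid fov must cover the 10.68 deg fMRI presentation window")
  }
  fov <- grid$fov_diameter
  # sweep positions: centers of n_steps equal steps across the full diameter
  offsets <- -fov / 2 + (seq_len(n_steps) - 0.5) * fov / n_steps
  orientations <- c(0, 45, 90, 135)
  aps <- list()
  durations <- numeric(0)
  is_blank <- logical(0)
  n_blanks <- ceiling(blank_duration / step_duration)
  pass <- 0L
  for (theta in orientations) {
    for (direction in c(1, -1)) {
      offs <- if (direction == 1) offsets else rev(offsets)
      for (k in seq_along(offs)) {
        aps[[length(aps) + 1L]] <- bar_aperture(
          grid, theta, offs[k], bar_width,
          label = sprintf("sweep%ddeg_dir%+d_step%02d", theta, direction, k))
        durations <- c(durations, step_duration)
        is_blank <- c(is_blank, FALSE)
      }
      pass <- pass + 1L
      if (pass %% 2L == 0L) {
        for (b in seq_len(n_blanks)) {
          aps[[length(aps) + 1L]] <- .blank_aperture(
            grid, sprintf("blank%02d_%02d", pass, b))
          durations <- c(durations, step_duration)
          is_blank <- c(is_blank, TRUE)
        }
      }
    }
  }
  list(apertures = aps, durations = durations, is_blank = is_blank,
       grid = grid)
}

#' Frame masks of an fMRI sequence as a matrix
#'
#' @param seq A sequence from [fmri_bar_sequence()].
#' @return Numeric matrix, n_frames x n_pixels.
#' @export
frame_matrix <- function(seq) {
  t(vapply(seq$apertures, function(a) as.numeric(a$mask),
           numeric(seq$grid$n_pixels^2)))
}
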