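#' Population receptive field set
#'
#' A `prf_set` holds per-vertex 2D-Gaussian pRF parameters: center `x0`, `y0`
#' (degrees, Cartesian, fixation at origin), spread `sigma` (degrees, > 0 for
#' included vertices), fit quality `r2` (fraction of fMRI variance explained)
#' and the inclusion mask `include`. Vertices are kept in place when excluded
#' (rows are never dropped) so gain-matrix columns stay aligned.
#'
#' @param x0,y0 Numeric vectors, pRF centers in degrees.
#' @param sigma Numeric vector, pRF sizes in degrees.
#' @param r2 Numeric vector, variance explained by the pRF fit (<= 1).
#' @param include Logical vector; defaults to all `TRUE`.
#' @return A data frame of class `prf_set` with columns `vertex_id`, `x0`,
#'   `y0`, `sigma`, `r2`, `include`.
#' @export
prf_set <- function(x0, y0, sigma, r2 = rep(1, length(x0)),
                    include = rep(TRUE, length(x0))) {
  n <- length(x0)
  stopifnot(length(y0) == n, length(sigma) == n, length(r2) == n,
            length(include) == n)
  if (any(include & !(is.finite(sigma) & sigma > 0))) {
    stop("included vertices must have finite sigma > 0")
  }
  out <- data.frame(vertex_id = seq_len(n), x0 = x0, y0 = y0, sigma = sigma,
                    r2 = r2, include = as.logical(include))
  class(out) <- c("prf_set", "data.frame")
  out
}

#' @export
print.prf_set <- function(x, ...) {
  cat(sprintf("<prf_set> %d vertices, %d included\n", nrow(x), sum(x$include)))
  NextMethod()
}

#' Unit-amplitude 2D Gaussian pRF sampled on a grid
#'
#' The pRF model g(x, y) = exp(-((x - x0)^2 + (y - y0)^2) / (2 sigma^2)),
#' sampled at pixel centers. The Gaussian has unit amplitude, not unit volume:
#' no normalization is applied, and all scaling is absorbed downstream by the
#' fitted amplitude (BOLD fit) or scaling factor b1 (ERF fit). This convention
#' changes the magnitude of stimulus overlaps, so it is fixed here once.
#'
#' @param x0,y0 pRF center, degrees.
#' @param sigma pRF size, degrees (> 0).
#' @param grid A [make_grid()] grid.
#' @return Numeric matrix (ny x nx) of Gaussian values at pixel centers.
#' @export
gaussian_prf <- function(x0, y0, sigma, grid) {
  stopifnot(inherits(grid, "vf_grid"))
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("`sigma` must be a single positive number (degrees)")
  }
  exp(-((grid$X - x0)^2 + (grid$Y - y0)^2) / (2 * sigma^2))
}

# vertices x pixels matrix of flattened Gaussian fields; excluded vertices get
# zero rows. Vectorized over vertices (one outer product per coordinate).
.prf_field_matrix <- function(prfs, grid) {
  stopifnot(inherits(prfs, "prf_set"), inherits(grid, "vf_grid"))
  px <- as.numeric(grid$X)
  py <- as.numeric(grid$Y)
  inc <- which(prfs$include)
  G <- matrix(0, nrow(prfs), length(px))
  if (length(inc)) {
    d2 <- outer(prfs$x0[inc], px, `-`)^2 + outer(prfs$y0[inc], py, `-`)^2
    G[inc, ] <- exp(-d2 / (2 * prfs$sigma[inc]^2))
  }
  rownames(G) <- prfs$vertex_id
  G
}

#' Two-gamma HRF kernel with derivative bases
#'
#' Canonical double-gamma hemodynamic response function plus its temporal and
#' dispersion derivatives, sampled at the acquisition TR and combined linearly
#' with the given coefficients. The canonical shape is the conventional
#' difference of gamma densities (response peak 6 s, undershoot peak 16 s,
#' peak:undershoot amplitude ratio 6, unit time scale), which peaks near 5 s.
#' The temporal derivative is the time derivative of the canonical; the
#' dispersion derivative is the sensitivity of the canonical to the gamma time
#' scale. Default coefficients (1, 1, 0) weight the canonical and its temporal
#' derivative.
#'
#' @param coefficients Length-3 numeric: weights of (canonical, temporal
#'   derivative, dispersion derivative).
#' @param TR Sampling interval in seconds (> 0).
#' @param duration Kernel support in seconds (default 32).
#' @return An object of class `hrf_kernel`: list with `times` (seconds),
#'   `values` (combined kernel), `basis` (3-column matrix) and `coefficients`.
#' @export
hrf_kernel <- function(coefficients = c(1, 1, 0), TR = 1.5, duration = 32) {
  if (TR <= 0) stop("`TR` must be positive")
  stopifnot(length(coefficients) == 3)
  times <- seq(0, duration, by = TR)
  canonical <- function(t, scale = 1) {
    stats::dgamma(t, shape = 6, scale = scale) -
      stats::dgamma(t, shape = 16, scale = scale) / 6
  }
  h <- canonical(times)
  dt <- 0.1
  dh <- (canonical(times) - canonical(times - dt)) / dt
  ds <- 0.01
  hd <- (canonical(times, scale = 1 + ds) - canonical(times)) / ds
  basis <- cbind(canonical = h, temporal = dh, dispersion = hd)
  structure(
    list(times = times, values = drop(basis %*% coefficients), basis = basis,
         coefficients = coefficients, TR = TR),
    class = "hrf_kernel")
}

#' Predict a BOLD time course from a pRF and a stimulus sequence
#'
#' The neural drive at each frame is the overlap of the pRF Gaussian with the
#' frame's binary aperture (sum over pixels of Gaussian x mask); the BOLD
#' prediction is that frame time course convolved with the HRF kernel and
#' truncated to the sequence length. Frames are assumed to be sampled at the
#' HRF kernel's TR.
#'
#' @param x0,y0,sigma pRF parameters, degrees.
#' @param frames Either an [fmri_bar_sequence()] result or a frames x pixels
#'   numeric matrix (from [frame_matrix()]).
#' @param hrf An [hrf_kernel()].
#' @param grid Grid the frames live on; required when `frames` is a matrix.
#' @return An object of class `bold_ts`: list with `values` (one sample per
#'   frame, arbitrary units absorbed by the fitted amplitude) and `TR`.
#' @export
predict_bold <- function(x0, y0, sigma, frames, hrf, grid = NULL) {
  F <- .as_frame_matrix(frames, grid)
  grid <- .frames_grid(frames, grid)
  g <- as.numeric(gaussian_prf(x0, y0, sigma, grid))
  overlap <- drop(F %*% g)
  values <- .causal_convolve(overlap, hrf$values)
  structure(list(values = values, TR = hrf$TR), class = "bold_ts")
}

.as_frame_matrix <- function(frames, grid) {
  if (is.matrix(frames)) return(frames)
  if (is.list(frames) && !is.null(frames$apertures)) return(frame_matrix(frames))
  stop("`frames` must be an fmri_bar_sequence() result or a frames x pixels matrix")
}

.frames_grid <- function(frames, grid) {
  if (is.list(frames) && !is.null(frames$grid)) return(frames$grid)
  if (is.null(grid)) stop("`grid` is required when frames are given as a matrix")
  grid
}

# causal convolution truncated to length(x): out[t] = sum_k kernel[k] x[t-k+1]
.causal_convolve <- function(x, kernel) {
  n <- length(x)
  m <- length(kernel)
  padded <- stats::filter(c(rep(0, m - 1), x), kernel, method = "convolution",
                          sides = 1)
  as.numeric(padded[m - 1 + seq_len(n)])
}

#' Fit a pRF to a BOLD time course by coarse-to-fine search
#'
#' Stage 1 evaluates a coarse grid of candidate (x0, y0, sigma) triplets:
#' positions sampled in polar coordinates over the stimulated disc and sizes
#' log-spaced. For every candidate the prediction amplitude is fitted by least
#' squares through the origin and the candidate maximizing variance explained
#' wins (ties broken by lowest candidate index). Stage 2 refines the winner by
#' Nelder-Mead on (x0, y0, log sigma), with positions clipped to the search
#' disc. The returned r2 is the conventional mean-referenced coefficient of
#' determination of the refined fit.
#'
#' @param ts A `bold_ts` (or bare numeric vector) of the measured response,
#'   one sample per frame.
#' @param frames Frame sequence or matrix, as in [predict_bold()].
#' @param hrf An [hrf_kernel()].
#' @param grid Grid (required when frames is a matrix).
#' @param coarse Coarse-grid specification: list with `max_ecc` (degrees;
#'   default half the grid fov), `n_ecc`, `n_angle`, `sigmas` (vector,
#'   degrees).
#' @return List with `x0`, `y0`, `sigma`, `amplitude`, `r2` and `reliable`
#'   (FALSE when the input is constant, in which case r2 is 0).
#' @export
fit_prf <- function(ts, frames, hrf, grid = NULL,
                    coarse = list()) {
  y <- if (inherits(ts, "bold_ts")) ts$values else as.numeric(ts)
  F <- .as_frame_matrix(frames, grid)
  grid <- .frames_grid(frames, grid)
  if (length(y) != nrow(F)) stop("time series length must match frame count")
  if (stats::sd(y) == 0 || !all(is.finite(y))) {
    return(list(x0 = NA_real_, y0 = NA_real_, sigma = NA_real_,
                amplitude = NA_real_, r2 = 0, reliable = FALSE))
  }
  spec <- utils::modifyList(
    list(max_ecc = grid$fov_diameter / 2, n_ecc = 8, n_angle = 12,
         sigmas = exp(seq(log(0.1), log(5), length.out = 8))),
    coarse)

  ecc <- seq(0, spec$max_ecc, length.out = spec$n_ecc)
  ang <- seq(0, 2 * pi, length.out = spec$n_angle + 1)[seq_len(spec$n_angle)]
  pos <- unique(cbind(x0 = as.numeric(outer(ecc, ang, function(e, a) e * cos(a))),
                      y0 = as.numeric(outer(ecc, ang, function(e, a) e * sin(a)))))
  cand <- cbind(x0 = rep(pos[, 1], times = length(spec$sigmas)),
                y0 = rep(pos[, 2], times = length(spec$sigmas)),
                sigma = rep(spec$sigmas, each = nrow(pos)))

  # all candidate Gaussians at once: candidates x pixels, then frames x cand
  px <- as.numeric(grid$X); py <- as.numeric(grid$Y)
  d2 <- outer(cand[, "x0"], px, `-`)^2 + outer(cand[, "y0"], py, `-`)^2
  G <- exp(-d2 / (2 * cand[, "sigma"]^2))
  P <- F %*% t(G)                              # frames x candidates (overlaps)
  P <- apply(P, 2, .causal_convolve, kernel = hrf$values)

  ssy <- sum((y - mean(y))^2)
  score <- function(p) {
    spp <- sum(p^2)
    if (spp == 0) return(-Inf)
    b <- sum(p * y) / spp
    1 - sum((y - b * p)^2) / ssy
  }
  r2s <- apply(P, 2, score)
  best <- which.max(r2s)                       # which.max: first index on ties

  obj <- function(par) {
    x0 <- par[1]; y0 <- par[2]; sg <- exp(par[3])
    e <- sqrt(x0^2 + y0^2)
    if (e > spec$max_ecc) {                    # clip back onto the disc
      x0 <- x0 * spec$max_ecc / e; y0 <- y0 * spec$max_ecc / e
    }
    p <- .causal_convolve(drop(F %*% as.numeric(gaussian_prf(x0, y0, sg, grid))),
                          hrf$values)
    -score(p)
  }
  start <- c(cand[best, "x0"], cand[best, "y0"], log(cand[best, "sigma"]))
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-10))
  x0 <- opt$par[1]; y0 <- opt$par[2]; sg <- exp(opt$par[3])
  e <- sqrt(x0^2 + y0^2)
  if (e > spec$max_ecc) {
    x0 <- x0 * spec$max_ecc / e; y0 <- y0 * spec$max_ecc / e
  }
  p <- .causal_convolve(drop(F %*% as.numeric(gaussian_prf(x0, y0, sg, grid))),
                        hrf$values)
  b <- sum(p * y) / sum(p^2)
  list(x0 = unname(x0), y0 = unname(y0), sigma = unname(sg),
       amplitude = unname(b), r2 = unname(-opt$value), reliable = TRUE)
}

#' Vertex inclusion criteria
#'
#' A vertex is included iff (i) it is not flagged as lying under a vein,
#' (ii) its pRF explains at least `r2_threshold` of the measured fMRI response
#' (boundary inclusive) and (iii) its pRF center lies inside the circular
#' stimulus window (eccentricity <= `window_radius`, boundary inclusive).
#'
#' @param prfs A [prf_set()].
#' @param r2_threshold Fraction in [0, 1]; default 0.15.
#' @param window_radius Stimulus window radius, degrees.
#' @param vein_mask Optional logical per vertex: TRUE = under a vein.
#' @return Logical inclusion mask, one entry per vertex.
#' @export
select_vertices <- function(prfs, r2_threshold = 0.15, window_radius,
                            vein_mask = NULL) {
  stopifnot(inherits(prfs, "prf_set"))
  if (r2_threshold < 0 || r2_threshold > 1) {
    stop("`r2_threshold` must be in [0, 1]")
  }
  keep <- prfs$r2 >= r2_threshold &
    sqrt(prfs$x0^2 + prfs$y0^2) <= window_radius
  if (!is.null(vein_mask)) {
    stopifnot(length(vein_mask) == nrow(prfs))
    keep <- keep & !vein_mask
  }
  keep
}

#' Read / write pRF tables
#'
#' pRF sets round-trip through CSV/TSV with columns `vertex_id`, `x0_deg`,
#' `y0_deg`, `sigma_deg`, `r2`, `include`.
#'
#' @param prfs A [prf_set()].
#' @param path File path; `.tsv` extension selects tab separation.
#' @return `read_prf_set` returns a `prf_set`; `write_prf_set` returns `path`
#'   invisibly.
#' @export
write_prf_set <- function(prfs, path) {
  stopifnot(inherits(prfs, "prf_set"))
  out <- data.frame(vertex_id = prfs$vertex_id, x0_deg = prfs$x0,
                    y0_deg = prfs$y0, sigma_deg = prfs$sigma, r2 = prfs$r2,
                    include = prfs$include)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_prf_set
#' @export
read_prf_set <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep)
  need <- c("vertex_id", "x0_deg", "y0_deg", "sigma_deg", "r2", "include")
  if (!all(need %in% names(d))) {
    stop("pRF table must have columns ", paste(need, collapse = ", "))
  }
  out <- prf_set(d$x0_deg, d$y0_deg, d$sigma_deg, d$r2, as.logical(d$include))
  out$vertex_id <- d$vertex_id
  out
}
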