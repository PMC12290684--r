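#' Epoched MEG sensor data
#'
#' Container for stimulus-locked epochs: a 3D array epochs x sensors x time,
#' a per-epoch stimulus label, and a time axis in milliseconds relative to
#' stimulus onset. The time axis must be strictly increasing, uniformly
#' sampled, and cover the -100..600 ms analysis window; `stimulus_labels`
#' fixes the canonical stimulus ordering and every epoch label must be one of
#' them.
#'
#' @param data Numeric array, epochs x sensors x time.
#' @param time_ms Numeric vector of sample times, ms from stimulus onset.
#' @param labels Character (or factor) vector, one stimulus label per epoch.
#' @param stimulus_labels Character vector defining the stimulus ordering;
#'   defaults to the sorted unique epoch labels.
#' @return An object of class `epoch_data`.
#' @export
epoch_data <- function(data, time_ms, labels,
                       stimulus_labels = sort(unique(as.character(labels)))) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  labels <- as.character(labels)
  if (dim(data)[1] != length(labels)) {
    stop("one label per epoch is required")
  }
  if (dim(data)[3] != length(time_ms)) {
    stop("time axis length must match the third dimension of `data`")
  }
  if (any(diff(time_ms) <= 0)) stop("time axis must be strictly increasing")
  steps <- diff(time_ms)
  if (max(steps) - min(steps) > 1e-9 * max(steps)) {
    stop("time axis must be uniformly sampled")
  }
  if (min(time_ms) > -100 || max(time_ms) < 600) {
    stop("epoch window must cover -100..600 ms")
  }
  if (!all(labels %in% stimulus_labels)) {
    stop("every epoch label must be one of `stimulus_labels`")
  }
  structure(list(data = data, time_ms = as.numeric(time_ms), labels = labels,
                 stimulus_labels = stimulus_labels),
            class = "epoch_data")
}

#' @export
print.epoch_data <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_data> %d epochs x %d sensors x %d samples (%g..%g ms), %d stimuli\n",
              d[1], d[2], d[3], min(x$time_ms), max(x$time_ms),
              length(x$stimulus_labels)))
  invisible(x)
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and sensor, the mean amplitude over the baseline
#' window (default -100 to 0 ms from stimulus onset, endpoints included) from
#' the entire epoch. Idempotent.
#'
#' @param epochs An [epoch_data()].
#' @param baseline_window Length-2 numeric, ms; must lie within the epoch
#'   window and contain at least one sample.
#' @return A baseline-corrected `epoch_data`.
#' @export
baseline_correct <- function(epochs, baseline_window = c(-100, 0)) {
  stopifnot(inherits(epochs, "epoch_data"), length(baseline_window) == 2)
  sel <- epochs$time_ms >= baseline_window[1] &
    epochs$time_ms <= baseline_window[2]
  if (!any(sel)) stop("baseline window contains no samples")
  base <- rowMeans(epochs$data[, , sel, drop = FALSE], dims = 2)  # E x S
  out <- epochs
  out$data <- epochs$data - as.numeric(base)   # recycles over the time dim
  out
}

#' Split-half cross-validation folds
#'
#' For each fold and stimulus independently, randomly partitions that
#' stimulus's epochs into disjoint train and test halves; when the epoch count
#' is odd the train half gets the smaller part (floor(n/2)). Folds are
#' independent random splits, all driven by one master seed, so the whole
#' specification is reproducible.
#'
#' @param epochs An [epoch_data()], or a named integer vector of epoch counts
#'   per stimulus (for planning without data; indices are then within
#'   stimulus).
#' @param n_folds Number of folds (default 120).
#' @param seed Master seed (integer).
#' @return An object of class `fold_spec`: list with `folds` (per fold, a list
#'   with `train` and `test`, each a list of epoch index vectors per
#'   stimulus), `stimulus_labels`, `n_folds`, `seed`.
#' @export
make_folds <- function(epochs, n_folds = 120, seed = 1) {
  if (inherits(epochs, "epoch_data")) {
    stim <- epochs$stimulus_labels
    idx <- lapply(stim, function(s) which(epochs$labels == s))
    names(idx) <- stim
  } else {
    counts <- epochs
    stim <- names(counts)
    if (is.null(stim)) stop("epoch counts must be a named vector")
    off <- cumsum(c(0, counts[-length(counts)]))
    idx <- lapply(seq_along(counts), function(i) off[i] + seq_len(counts[i]))
    names(idx) <- stim
  }
  n_per <- lengths(idx)
  if (any(n_per < 2)) {
    stop("every stimulus needs at least 2 epochs to split; short: ",
         paste(names(idx)[n_per < 2], collapse = ", "))
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(as.integer(seed))
  folds <- lapply(seq_len(n_folds), function(f) {
    tr <- lapply(idx, function(ii) {
      sort(sample(ii, floor(length(ii) / 2)))
    })
    te <- Map(setdiff, idx, tr)
    list(train = tr, test = te)
  })
  structure(list(folds = folds, stimulus_labels = stim, n_folds = n_folds,
                 seed = as.integer(seed)),
            class = "fold_spec")
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.fold_spec <- function(x, ...) {
  cat(sprintf("<fold_spec> %d folds x %d stimuli (seed %d)\n",
              x$n_folds, length(x$stimulus_labels), x$seed))
  invisible(x)
}

#' Average epochs into per-stimulus ERFs
#'
#' Arithmetic mean across the selected epochs of each stimulus, per sensor and
#' timepoint.
#'
#' @param epochs An [epoch_data()].
#' @param selection Optional list of epoch index vectors, one per stimulus
#'   (e.g. one fold's `train` or `test`); default: all epochs of each
#'   stimulus.
#' @return An object of class `erf_set`: list with `data` (array stimuli x
#'   sensors x time, stimulus axis ordered as `stimulus_labels`), `time_ms`,
#'   `stimulus_labels`.
#' @export
average_erf <- function(epochs, selection = NULL) {
  stopifnot(inherits(epochs, "epoch_data"))
  stim <- epochs$stimulus_labels
  if (is.null(selection)) {
    selection <- lapply(stim, function(s) which(epochs$labels == s))
    names(selection) <- stim
  }
  if (length(selection) != length(stim)) {
    stop("`selection` needs one index set per stimulus")
  }
  if (any(lengths(selection) == 0)) {
    stop("empty epoch selection for stimulus: ",
         paste(stim[lengths(selection) == 0], collapse = ", "))
  }
  d <- dim(epochs$data)
  out <- array(0, c(length(stim), d[2], d[3]),
               dimnames = list(stim, NULL, NULL))
  for (i in seq_along(stim)) {
    ii <- selection[[i]]
    out[i, , ] <- if (length(ii) == 1L) epochs$data[ii, , ]
    else colMeans(epochs$data[ii, , , drop = FALSE], dims = 1)
  }
  structure(list(data = out, time_ms = epochs$time_ms,
                 stimulus_labels = stim),
            class = "erf_set")
}
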