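#' Polar-angle perturbation analysis
#'
#' Rotates every pRF center away from its estimated polar angle by each angle
#' in `angles`, rebuilds the sensor predictions
#' ([shift_polar_angle()] -> [predict_cortical()] -> [project_to_sensors()])
#' and refits the ERFs with [fit_timecourse()] using the *same* fold
#' specification for every angle (paired design: differences between angles
#' are attributable to the shift, not to resampling). If the fMRI-estimated
#' pRFs drive the ERFs, variance explained should fall as pRFs are rotated
#' away from their estimated positions.
#'
#' @param prfs A [prf_set()].
#' @param stimuli A [meg_stimulus_set()].
#' @param gain A [gain_matrix()].
#' @param epochs A baseline-corrected [epoch_data()].
#' @param folds A [make_folds()] specification, shared across angles.
#' @param angles Shift angles in degrees; must include 0 (the unperturbed
#'   baseline). Default `c(-90, -60, -45, -30, 0, 30, 45, 60, 90)`.
#' @param offset Fit the offset variant (default `FALSE`).
#' @param keep_fits Keep the full per-angle `fit_result` objects (memory
#'   heavy); default only summaries are kept.
#' @return An object of class `shift_result`: per angle, the per-sensor
#'   `fit_summary`, pooled group summaries (`all` plus the non-empty
#'   [sensor_groups()] of the 0-degree fit), per-latency significance masks
#'   versus the 0-degree fit, and metadata.
#' @export
run_shift_analysis <- function(prfs, stimuli, gain, epochs, folds,
                               angles = c(-90, -60, -45, -30, 0, 30, 45, 60, 90),
                               offset = FALSE, keep_fits = FALSE) {
  if (!any(angles == 0)) stop("`angles` must include 0 (the baseline)")
  preds <- lapply(angles, function(a) {
    project_to_sensors(gain, predict_cortical(shift_polar_angle(prfs, a),
                                              stimuli))
  })
  fits <- .fit_folds(preds, epochs, folds, offset = offset)
  names(fits) <- as.character(angles)
  i0 <- which(angles == 0)[1]

  summaries <- lapply(fits, fit_summary)
  groups <- suppressWarnings(sensor_groups(summaries[[i0]]))
  groups <- Filter(function(g) length(g$members) > 0, groups)
  group_idx <- c(list(all = seq_len(dim(fits[[i0]]$ve)[2])),
                 lapply(groups, `[[`, "members"))

  pooled <- lapply(fits, function(fit) {
    lapply(group_idx, function(g)
      fit_summary(average_ve(fit, g), time_ms = fit$time_ms))
  })
  significant <- lapply(seq_along(angles), function(i) {
    lapply(names(group_idx), function(g)
      significant_latencies(pooled[[i0]][[g]], pooled[[i]][[g]]))
  })
  names(significant) <- as.character(angles)
  significant <- lapply(significant, function(s) {
    names(s) <- names(group_idx); s
  })
  structure(
    list(angles = angles, summaries = summaries, pooled = pooled,
         significant = significant, groups = groups,
         baseline_angle_index = i0, time_ms = epochs$time_ms,
         offset = offset,
         fits = if (keep_fits) fits else fits[i0]),
    class = "shift_result")
}

#' @export
print.shift_result <- function(x, ...) {
  cat(sprintf("<shift_result> angles %s deg, %d latencies, groups: %s\n",
              paste(x$angles, collapse = "/"), length(x$time_ms),
              paste(c("all", names(x$groups)), collapse = ", ")))
  invisible(x)
}

#' Latencies where a shifted fit is significantly worse
#'
#' One-sided confidence-interval comparison: a latency is flagged when the
#' shifted fit's CI lies entirely below the baseline fit's CI
#' (`shifted.high < baseline.low`). Intervals sharing an endpoint count as
#' overlapping (conservative). Latencies where either CI is missing yield
#' `NA`.
#'
#' @param baseline,shifted [fit_summary()] objects on a common latency axis
#'   (per-latency vectors, or sensors x latencies matrices compared
#'   elementwise).
#' @return Logical vector/matrix per latency.
#' @export
significant_latencies <- function(baseline, shifted) {
  stopifnot(inherits(baseline, "fit_summary"), inherits(shifted, "fit_summary"))
  if (length(baseline$ci_low) != length(shifted$ci_high)) {
    stop("summaries must share one latency axis")
  }
  shifted$ci_high < baseline$ci_low
}

#' Shift-analysis results as a long table
#'
#' Flattens the pooled group summaries of a [run_shift_analysis()] result
#' into a data frame (angle x group x latency with median, CI and the
#' significance flag), convenient for CSV export and plotting.
#'
#' @param shift A `shift_result`.
#' @return A data frame with columns `angle_deg`, `group`, `time_ms`,
#'   `median_ve`, `ci_low`, `ci_high`, `significant`.
#' @export
shift_table <- function(shift) {
  stopifnot(inherits(shift, "shift_result"))
  rows <- list()
  for (i in seq_along(shift$angles)) {
    a <- as.character(shift$angles[i])
    for (g in names(shift$pooled[[i]])) {
      s <- shift$pooled[[i]][[g]]
      rows[[length(rows) + 1L]] <- data.frame(
        angle_deg = shift$angles[i], group = g, time_ms = shift$time_ms,
        median_ve = s$median, ci_low = s$ci_low, ci_high = s$ci_high,
        significant = shift$significant[[a]][[g]])
    }
  }
  do.call(rbind, rows)
}
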