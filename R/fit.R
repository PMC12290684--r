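#' Least-squares scaling factor through the origin
#'
#' Fits the scaling factor b1 that maps a sensor's 18-stimulus prediction
#' vector onto a training ERF vector with the offset fixed at 0:
#' b1 = sum(p * y) / sum(p^2). This brings the (unitless) pRF predictions to
#' ERF units.
#'
#' @param prediction Numeric vector (one value per stimulus); not all zero.
#' @param train_erf Numeric vector, same length.
#' @return The scalar b1; `NA` when the prediction is all zero (an undefined
#'   fit, propagated as missing rather than coerced to 0).
#' @export
fit_scale <- function(prediction, train_erf) {
  stopifnot(length(prediction) == length(train_erf))
  spp <- sum(prediction^2)
  if (spp == 0) return(NA_real_)
  sum(prediction * train_erf) / spp
}

#' Least-squares scale and offset
#'
#' Ordinary least squares of the training ERF on the prediction plus a
#' constant: yhat = b1 * p + b0. Used by the offset variant of the
#' cross-validated fit; the variance-explained computation is unchanged.
#'
#' @inheritParams fit_scale
#' @return Named numeric `c(b1, b0)`; both `NA` when the prediction vector is
#'   constant (undefined fit).
#' @export
fit_scale_with_offset <- function(prediction, train_erf) {
  stopifnot(length(prediction) == length(train_erf))
  n <- length(prediction)
  sxx <- sum(prediction^2) - sum(prediction)^2 / n
  if (sxx == 0) return(c(b1 = NA_real_, b0 = NA_real_))
  sxy <- sum(prediction * train_erf) - sum(prediction) * sum(train_erf) / n
  b1 <- sxy / sxx
  b0 <- mean(train_erf) - b1 * mean(prediction)
  c(b1 = b1, b0 = b0)
}

#' Cross-validated variance explained (uncentered)
#'
#' VE = 1 - RSS / TSS with TSS the *uncentered* total sum of squares of the
#' test ERF (sum of squared test values across stimuli). A scaled prediction
#' of zero therefore gives VE = 0, and VE is bounded above by 1 but unbounded
#' below under cross-validation.
#'
#' @param test_erf Numeric vector of test-half ERF values per stimulus.
#' @param scaled_pred Numeric vector, the scaled prediction yhat.
#' @return Scalar VE; `NA` when the test ERF is all zero (TSS = 0, VE
#'   undefined).
#' @export
variance_explained <- function(test_erf, scaled_pred) {
  stopifnot(length(test_erf) == length(scaled_pred))
  tss <- sum(test_erf^2)
  if (tss == 0) return(NA_real_)
  1 - sum((test_erf - scaled_pred)^2) / tss
}

# Core fitting engine. pred_list: list of sensors x stimuli prediction
# matrices sharing one stimulus ordering. The expensive per-fold train/test
# ERF averages are obtained from one chunked matrix product of the flattened
# epoch data with the fold/stimulus train indicators (the test half follows
# by subtracting the train sum from the per-stimulus total), and are shared
# across all predictions — this is what makes the paired-fold perturbation
# analysis affordable.
.fit_folds <- function(pred_list, epochs, folds, offset = FALSE) {
  stopifnot(inherits(epochs, "epoch_data"), inherits(folds, "fold_spec"))
  if (!identical(folds$stimulus_labels, epochs$stimulus_labels)) {
    stop("fold spec and epochs disagree on the stimulus ordering")
  }
  K <- length(epochs$stimulus_labels)
  E <- dim(epochs$data)[1]
  S <- dim(epochs$data)[2]
  Tn <- dim(epochs$data)[3]
  nf <- folds$n_folds
  pred_list <- lapply(pred_list, function(P) {
    P <- as.matrix(P)
    if (nrow(P) != S || ncol(P) != K) {
      stop(sprintf("prediction must be %d sensors x %d stimuli", S, K))
    }
    if (!is.null(colnames(P)) &&
        !identical(colnames(P), epochs$stimulus_labels)) {
      P <- P[, epochs$stimulus_labels, drop = FALSE]
    }
    P
  })
  J <- length(pred_list)
  sumP2 <- lapply(pred_list, function(P) rowSums(P^2))
  sumP <- lapply(pred_list, function(P) rowSums(P))
  # per-sensor, per-prediction 1 x stimuli rows (shared across folds); kept
  # separate per prediction so a multi-prediction run is bit-identical to
  # running each prediction alone
  PsT <- lapply(seq_len(S), function(s) {
    lapply(pred_list, function(P) matrix(P[s, ], 1, K))
  })

  # flattened epoch data: epochs x (time fastest, then sensor), so each
  # sensor occupies a contiguous column block; kept in Matrix dense form so
  # the sparse-indicator products below take the fast CHOLMOD path
  DmT <- aperm(epochs$data, c(1, 3, 2))
  attributes(DmT) <- NULL                            # avoid a second copy
  DmT <- methods::new(
    methods::getClassDef("dgeMatrix", where = asNamespace("Matrix")),
    x = DmT, Dim = as.integer(c(E, Tn * S)))
  lab_idx <- match(epochs$labels, epochs$stimulus_labels)
  Lab <- Matrix::sparseMatrix(i = seq_len(E), j = lab_idx, x = 1,
                              dims = c(E, K))
  total <- as.matrix(Matrix::t(Lab) %*% DmT)         # per-stimulus epoch sums
  n_all <- Matrix::colSums(Lab)

  n_tr <- matrix(0L, nf, K)                          # train half sizes
  wi <- vector("list", nf)
  for (f in seq_len(nf)) {
    tr <- folds$folds[[f]]$train
    n_tr[f, ] <- lengths(tr)
    wi[[f]] <- unlist(tr, use.names = FALSE)
  }
  W <- Matrix::sparseMatrix(                         # train indicators
    i = unlist(wi, use.names = FALSE),
    j = rep(seq_len(nf * K),
            times = as.integer(t(n_tr))),
    x = 1, dims = c(E, nf * K))

  blank <- function() array(NA_real_, c(nf, S, Tn))
  res <- lapply(pred_list, function(P) {
    r <- list(ve = blank(), b1 = blank(), rss = blank(), tss = blank())
    if (offset) r$b0 <- blank()
    r
  })

  folds_per_chunk <- max(1L, floor(3.2e7 / (S * Tn * K)))
  scols <- lapply(seq_len(S), function(s) ((s - 1L) * Tn + 1L):(s * Tn))
  for (f0 in seq(1L, nf, by = folds_per_chunk)) {
    fs <- f0:min(f0 + folds_per_chunk - 1L, nf)
    cols <- rep((fs - 1L) * K, each = K) + seq_len(K)
    TrS <- as.matrix(Matrix::t(W[, cols, drop = FALSE]) %*% DmT)
    for (j2 in seq_along(fs)) {
      f <- fs[j2]
      Str <- TrS[(j2 - 1L) * K + seq_len(K), , drop = FALSE]  # K x (Tn*S)
      Mtr <- Str / n_tr[f, ]                         # fold train ERF
      Mte <- (total - Str) / (n_all - n_tr[f, ])
      tss <- .colSums(Mte * Mte, K, Tn * S)
      dim(tss) <- c(Tn, S); tss <- t(tss)
      if (offset) {
        sumYtr <- t(`dim<-`(.colSums(Mtr, K, Tn * S), c(Tn, S)))
        sumYte <- t(`dim<-`(.colSums(Mte, K, Tn * S), c(Tn, S)))
      }
      # per-sensor projections onto all predictions at once
      numTrL <- lapply(seq_len(J), function(j) matrix(0, S, Tn))
      numTeL <- numTrL
      for (s in seq_len(S)) {
        Mtrs <- Mtr[, scols[[s]], drop = FALSE]    # K x Tn, contiguous block
        Mtes <- Mte[, scols[[s]], drop = FALSE]
        for (j in seq_len(J)) {
          numTrL[[j]][s, ] <- PsT[[s]][[j]] %*% Mtrs
          numTeL[[j]][s, ] <- PsT[[s]][[j]] %*% Mtes
        }
      }
      for (j in seq_len(J)) {
        numTr <- numTrL[[j]]
        numTe <- numTeL[[j]]
        if (!offset) {
          b1 <- numTr / sumP2[[j]]                   # recycles by sensor row
          b1[sumP2[[j]] == 0, ] <- NA_real_
          rss <- pmax(tss - 2 * b1 * numTe + b1^2 * sumP2[[j]], 0)
        } else {
          sxx <- K * sumP2[[j]] - sumP[[j]]^2        # per sensor
          b1 <- (K * numTr - sumP[[j]] * sumYtr) / sxx
          b1[sxx == 0, ] <- NA_real_
          b0 <- (sumYtr - b1 * sumP[[j]]) / K
          rss <- pmax(tss - 2 * b1 * numTe - 2 * b0 * sumYte +
                        2 * b1 * b0 * sumP[[j]] + b1^2 * sumP2[[j]] +
                        K * b0^2, 0)
          res[[j]]$b0[f, , ] <- b0
        }
        ve <- 1 - rss / tss
        ve[tss == 0] <- NA_real_
        res[[j]]$ve[f, , ] <- ve
        res[[j]]$b1[f, , ] <- b1
        res[[j]]$rss[f, , ] <- rss
        res[[j]]$tss[f, , ] <- tss
      }
    }
  }
  lapply(res, function(r) {
    structure(c(r, list(time_ms = epochs$time_ms, n_folds = nf,
                        offset = offset)),
              class = "fit_result")
  })
}

#' Time-resolved cross-validated fit of sensor predictions to ERFs
#'
#' For every cross-validation fold, sensor and latency: the scaling factor b1
#' is fitted on the fold's training ERF ([fit_scale()]; with `offset = TRUE`,
#' [fit_scale_with_offset()]), and the cross-validated variance explained of
#' the scaled prediction is evaluated on the fold's test ERF
#' ([variance_explained()], uncentered TSS). Undefined fits (all-zero
#' prediction vector, or zero test TSS) propagate as `NA`, never as 0.
#'
#' @param sensor_predictions Sensors x stimuli matrix from
#'   [project_to_sensors()]; columns ordered (or named) as the epochs'
#'   stimulus labels.
#' @param epochs A (baseline-corrected) [epoch_data()].
#' @param folds A [make_folds()] specification.
#' @param offset If `TRUE`, fit scale and offset (the offset variant).
#' @return An object of class `fit_result`: arrays `ve`, `b1`, `rss`, `tss`
#'   (and `b0` for the offset variant) of shape folds x sensors x latencies,
#'   plus `time_ms`.
#' @export
fit_timecourse <- function(sensor_predictions, epochs, folds, offset = FALSE) {
  .fit_folds(list(sensor_predictions), epochs, folds, offset = offset)[[1]]
}

#' @export
print.fit_result <- function(x, ...) {
  d <- dim(x$ve)
  cat(sprintf("<fit_result> %d folds x %d sensors x %d latencies%s\n",
              d[1], d[2], d[3], if (isTRUE(x$offset)) " (offset variant)" else ""))
  invisible(x)
}

#' Pooled variance explained over a sensor group
#'
#' The group average at each fold and latency is the pooled ratio
#' 1 - sum(RSS over sensors) / sum(TSS over sensors) — not the mean of the
#' per-sensor VEs. Sensors whose fit is undefined (missing RSS) are excluded
#' from both sums; if no group sensor is defined the cell is `NA`.
#'
#' @param fit A [fit_timecourse()] result.
#' @param group Integer vector of sensor indices (or a `sensor_group`).
#' @return Numeric matrix, folds x latencies.
#' @export
average_ve <- function(fit, group) {
  stopifnot(inherits(fit, "fit_result"))
  if (inherits(group, "sensor_group")) group <- group$members
  group <- as.integer(group)
  if (length(group) == 0) stop("sensor group is empty")
  rss <- fit$rss[, group, , drop = FALSE]
  tss <- fit$tss[, group, , drop = FALSE]
  tss[is.na(rss)] <- NA_real_               # exclude undefined sensors
  num <- colSums(aperm(rss, c(2, 1, 3)), na.rm = TRUE, dims = 1)
  den <- colSums(aperm(tss, c(2, 1, 3)), na.rm = TRUE, dims = 1)
  ndef <- colSums(aperm(!is.na(rss), c(2, 1, 3)), dims = 1)
  out <- 1 - num / den
  out[ndef == 0 | den == 0] <- NA_real_
  out
}

# quantiles across the fold dimension of a folds x ... array; linear
# interpolation (type 7) percentiles, missing folds ignored. Complete cells
# take a vectorized path (one radix sort of the whole array); cells with
# missing folds fall back to stats::quantile per cell.
.fold_quantiles <- function(x, probs) {
  d <- dim(x)
  nf <- d[1]
  m <- matrix(x, nrow = nf)
  if (!anyNA(m)) {
    o <- order(rep(seq_len(ncol(m)), each = nf), m)
    ms <- matrix(m[o], nrow = nf)
    q <- matrix(0, length(probs), ncol(m))
    for (i in seq_along(probs)) {
      h <- (nf - 1) * probs[i] + 1
      lo <- floor(h)
      v <- ms[lo, ]
      if (lo < nf) v <- v + (h - lo) * (ms[lo + 1, ] - v)
      q[i, ] <- v
    }
  } else {
    q <- apply(m, 2, function(col) {
      col <- col[!is.na(col)]
      if (!length(col)) return(rep(NA_real_, length(probs)))
      stats::quantile(col, probs, names = FALSE, type = 7)
    })
    if (!is.matrix(q)) q <- matrix(q, nrow = length(probs))
  }
  lapply(seq_along(probs), function(i) {
    v <- q[i, ]
    if (length(d) > 2) dim(v) <- d[-1]
    v
  })
}

#' Summarize a fit across folds
#'
#' Reduces the fold dimension to the median and a 95% percentile confidence
#' interval (2.5th and 97.5th percentiles across folds, linear-interpolation
#' definition, fixed for bit-reproducibility). Missing folds are ignored; a
#' cell with no defined fold is missing.
#'
#' @param x A `fit_result` (summarized per sensor x latency) or a folds x
#'   latencies matrix from [average_ve()] (summarized per latency).
#' @param ... Unused.
#' @return An object of class `fit_summary` with `median`, `ci_low`,
#'   `ci_high` (matrices sensors x latencies, or vectors per latency) and
#'   `time_ms` when known.
#' @export
fit_summary <- function(x, ...) UseMethod("fit_summary")

#' @export
fit_summary.fit_result <- function(x, ...) {
  q <- .fold_quantiles(x$ve, c(0.5, 0.025, 0.975))
  structure(list(median = q[[1]], ci_low = q[[2]], ci_high = q[[3]],
                 time_ms = x$time_ms, n_folds = x$n_folds),
            class = "fit_summary")
}

#' @param time_ms Optional time axis for matrix input.
#' @rdname fit_summary
#' @export
fit_summary.matrix <- function(x, time_ms = NULL, ...) {
  if (nrow(x) < 2) stop("need at least 2 folds to summarize")
  q <- .fold_quantiles(x, c(0.5, 0.025, 0.975))
  structure(list(median = q[[1]], ci_low = q[[2]], ci_high = q[[3]],
                 time_ms = time_ms, n_folds = nrow(x)),
            class = "fit_summary")
}

#' @export
print.fit_summary <- function(x, ...) {
  n <- if (is.matrix(x$median)) {
    sprintf("%d sensors x %d latencies", nrow(x$median), ncol(x$median))
  } else sprintf("%d latencies", length(x$median))
  cat(sprintf("<fit_summary> median + 95%% CI over %d folds, %s\n",
              x$n_folds, n))
  invisible(x)
}

#' Sensor groups from a fit summary
#'
#' Three groups defined on the fold-median VE time course of each sensor:
#' \describe{
#'   \item{active}{median VE reaches `threshold` at any latency in the whole
#'     epoch window.}
#'   \item{early}{median VE reaches `threshold` at any latency inside
#'     `early_window` (default 50-150 ms).}
#'   \item{earliest}{the `floor(fraction * S)` sensors (default the 25%
#'     fastest) whose median VE first reaches `threshold` at the smallest
#'     latency, searching from stimulus onset (t >= 0); ties broken by sensor
#'     index. If fewer sensors ever cross, the group is all crossers (with a
#'     warning).}
#' }
#'
#' @param summary A per-sensor [fit_summary()] spanning the full epoch window.
#' @param threshold VE threshold (default 0.5).
#' @param early_window Length-2 numeric, ms (default `c(50, 150)`).
#' @param fraction Fraction of sensors in the earliest group (default 0.25).
#' @return Named list of `sensor_group` objects (`kind`, `members`,
#'   `params`; for `earliest` also `crossing_ms` per member).
#' @export
sensor_groups <- function(summary, threshold = 0.5, early_window = c(50, 150),
                          fraction = 0.25) {
  stopifnot(inherits(summary, "fit_summary"), is.matrix(summary$median))
  med <- summary$median
  t_ms <- summary$time_ms
  if (is.null(t_ms)) stop("summary must carry a time axis")
  S <- nrow(med)
  cross <- function(cols) {
    m <- med[, cols, drop = FALSE]
    apply(m, 1, function(v) any(v >= threshold, na.rm = TRUE))
  }
  active <- which(cross(seq_along(t_ms)))
  early <- which(cross(which(t_ms >= early_window[1] & t_ms <= early_window[2])))
  post <- which(t_ms >= 0)
  first_cross <- apply(med[, post, drop = FALSE], 1, function(v) {
    i <- which(v >= threshold)[1]
    if (is.na(i)) NA_real_ else t_ms[post[i]]
  })
  crossers <- which(!is.na(first_cross))
  k <- floor(fraction * S)
  if (length(crossers) < k) {
    warning(sprintf("only %d of %d required sensors ever reach %.0f%% VE; ",
                    length(crossers), k, 100 * threshold),
            "'earliest' group contains all crossers")
    earliest <- crossers[order(first_cross[crossers], crossers)]
  } else {
    earliest <- crossers[order(first_cross[crossers], crossers)][seq_len(k)]
  }
  grp <- function(kind, members, params, ...) {
    structure(list(kind = kind, members = members, params = params, ...),
              class = "sensor_group")
  }
  list(
    active = grp("active", active, list(threshold = threshold)),
    early = grp("early", early,
                list(threshold = threshold, window_ms = early_window)),
    earliest = grp("earliest", earliest,
                   list(threshold = threshold, fraction = fraction),
                   crossing_ms = first_cross[earliest])
  )
}

#' @export
print.sensor_group <- function(x, ...) {
  cat(sprintf("<sensor_group> '%s': %d sensors\n", x$kind, length(x$members)))
  invisible(x)
}
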