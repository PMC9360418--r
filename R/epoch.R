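#' Epoch a continuous recording around non-target events
#'
#' Cuts one epoch per non-target event on the recording's sampling grid using
#' the half-open convention \[`window_ms[1]`, `window_ms[2]`): the onset
#' sample is the first sample at or after the event time, and the epoch holds
#' the samples whose latency k/rate (ms) satisfies window_ms[1] <= t <
#' window_ms[2]. Target events never enter ERP epochs. Events too close to a
#' recording edge are skipped and logged.
#'
#' @param rec An `eeg_recording` (average-referenced in the standard path).
#' @param events Event tibble with `onset_ms`, `condition`, `is_target`.
#' @param window_ms Epoch window (ms relative to onset), default c(-100, 613).
#' @param baseline Subtract the prestimulus (t < 0) mean per channel and
#'   epoch? Default `TRUE`.
#' @return An `epoch_set`: per-condition arrays trials x channels x samples, a
#'   shared `times_ms` axis, and a rejection log.
#' @export
epoch_recording <- function(rec, events, window_ms = c(-100, 613),
                            baseline = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"), window_ms[1] < window_ms[2])
  fs <- rec$rate
  k_lo <- ceiling(window_ms[1] * fs / 1000)
  k_hi <- as.integer(ceiling(window_ms[2] * fs / 1000) - 1)
  offs <- k_lo:k_hi
  times_ms <- offs * 1000 / fs
  n_samp <- ncol(rec$signal)

  ev <- events[!events$is_target, , drop = FALSE]
  conds <- unique(ev$condition)
  epochs <- list()
  log <- list()
  for (cond in conds) {
    evc <- ev[ev$condition == cond, , drop = FALSE]
    arrs <- list()
    for (i in seq_len(nrow(evc))) {
      onset_idx <- as.integer(ceiling(evc$onset_ms[i] * fs / 1000)) + 1L
      idx <- onset_idx + offs
      if (idx[1] < 1 || idx[length(idx)] > n_samp) {
        log[[length(log) + 1]] <- tibble::tibble(
          condition = cond, epoch = i, reason = "recording-edge"
        )
        next
      }
      x <- rec$signal[, idx, drop = FALSE]
      if (baseline) {
        pre <- times_ms < 0
        if (any(pre)) x <- x - rowMeans(x[, pre, drop = FALSE])
      }
      arrs[[length(arrs) + 1]] <- x
    }
    a <- array(0, dim = c(length(arrs), nrow(rec$signal), length(offs)))
    for (j in seq_along(arrs)) a[j, , ] <- arrs[[j]]
    dimnames(a) <- list(NULL, rec$montage$channels, NULL)
    epochs[[cond]] <- a
  }
  structure(
    list(
      epochs = epochs,
      times_ms = times_ms,
      rate = fs,
      montage = rec$montage,
      subject = rec$meta$subject %||% NA_character_,
      timepoint = rec$meta$timepoint %||% NA_character_,
      baseline = baseline,
      rejection_log = if (length(log)) dplyr::bind_rows(log) else
        tibble::tibble(condition = character(), epoch = integer(), reason = character())
    ),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(
    "<epoch_set>",
    paste(sprintf("%s: %d", names(x$epochs), vapply(x$epochs, function(a) dim(a)[1], 0L)),
      collapse = ", "
    ),
    sprintf(
      "epochs; %d channels, %.0f-%.0f ms @ %g Hz\n",
      dim(x$epochs[[1]])[2], min(x$times_ms), max(x$times_ms), x$rate
    )
  )
  invisible(x)
}

#' Amplitude-threshold epoch rejection
#'
#' Discards every epoch in which any sample on any channel exceeds the
#' absolute amplitude threshold, and logs the removals.
#'
#' @param es An `epoch_set`.
#' @param threshold_uv Absolute amplitude criterion (uV), default 200.
#' @return `epoch_set` with offending epochs removed and the rejection log
#'   extended.
#' @export
reject_epochs <- function(es, threshold_uv = 200) {
  stopifnot(inherits(es, "epoch_set"), threshold_uv > 0)
  log <- list(es$rejection_log)
  for (cond in names(es$epochs)) {
    a <- es$epochs[[cond]]
    if (dim(a)[1] == 0) next
    bad <- apply(abs(a) > threshold_uv, 1, any)
    if (any(bad)) {
      log[[length(log) + 1]] <- tibble::tibble(
        condition = cond, epoch = which(bad), reason = "amplitude"
      )
      es$epochs[[cond]] <- a[!bad, , , drop = FALSE]
    }
  }
  es$rejection_log <- dplyr::bind_rows(log)
  es
}

#' Epoch counts per condition
#'
#' @param es An `epoch_set`.
#' @return Tibble `condition`, `n_epochs`.
#' @export
epoch_counts <- function(es) {
  tibble::tibble(
    condition = names(es$epochs),
    n_epochs = vapply(es$epochs, function(a) dim(a)[1], integer(1))
  )
}

#' Minimum-epoch inclusion rule
#'
#' A subject-visit is included if and only if every required condition retains
#' at least `min_epochs` epochs after rejection (the bound is inclusive).
#'
#' @param es An `epoch_set` after [reject_epochs()].
#' @param min_epochs Minimum per-condition count, default 20.
#' @param conditions Required conditions; a condition absent from the epoch
#'   set excludes the subject with reason `"missing-condition"`.
#' @return One-row tibble `subject`, `timepoint`, one `n_<condition>` column
#'   per required condition, `included`, `reason`.
#' @export
apply_inclusion_rule <- function(es, min_epochs = 20,
                                 conditions = c("DIG", "LET", "FF")) {
  stopifnot(inherits(es, "epoch_set"))
  counts <- stats::setNames(
    vapply(conditions, function(cond) {
      if (is.null(es$epochs[[cond]])) 0L else dim(es$epochs[[cond]])[1]
    }, integer(1)),
    conditions
  )
  missing <- conditions[!conditions %in% names(es$epochs)]
  included <- length(missing) == 0 && all(counts >= min_epochs)
  reason <- if (length(missing) > 0) {
    "missing-condition"
  } else if (!included) {
    "below-minimum"
  } else {
    NA_character_
  }
  out <- tibble::tibble(subject = es$subject, timepoint = es$timepoint)
  for (cond in conditions) out[[paste0("n_", cond)]] <- counts[[cond]]
  out$included <- included
  out$reason <- reason
  out
}
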