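#' Per-condition ERP averages
#'
#' Pointwise mean over the retained epochs of each condition.
#'
#' @param es An `epoch_set` (after rejection).
#' @return Named list of `erp_average` objects (one per condition): waveform
#'   channels x samples, `n_epochs`, time axis, subject/timepoint metadata.
#' @export
average_condition <- function(es) {
  stopifnot(inherits(es, "epoch_set"))
  lapply(stats::setNames(nm = names(es$epochs)), function(cond) {
    a <- es$epochs[[cond]]
    n <- dim(a)[1]
    if (n == 0) {
      stop(
        "condition ", cond, " has zero retained epochs; ",
        "the inclusion rule should have excluded this subject-visit"
      )
    }
    wf <- apply(a, c(2, 3), mean)
    structure(
      list(
        waveform = wf, n_epochs = n, condition = cond,
        subject = es$subject, timepoint = es$timepoint,
        times_ms = es$times_ms, rate = es$rate, montage = es$montage
      ),
      class = "erp_average"
    )
  })
}

#' Global field power
#'
#' GFP(t) = sqrt( (1/N) * sum_i (u_i(t) - mean(u(t)))^2 ): the population
#' standard deviation of the voltages across channels at each sample. It is
#' reference-independent up to a constant channel offset and always
#' non-negative.
#'
#' @param x A channels x samples matrix, a single map (numeric vector), or an
#'   `erp_average`.
#' @return Numeric vector of per-sample GFP (scalar for a single map).
#' @examples
#' gfp(c(1, 1, -1, -1)) # 1
#' @export
gfp <- function(x) {
  if (inherits(x, "erp_average")) x <- x$waveform
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  stopifnot(nrow(x) >= 2)
  mu <- colMeans(x)
  g <- sqrt(colMeans(sweep(x, 2, mu)^2))
  if (length(g) == 1) g[[1]] else g
}

#' Grand-average GFP trace for one timepoint
#'
#' The unweighted mean ERP across all supplied condition averages (all
#' subjects, all conditions pooled) is computed first; its GFP is the trace
#' used for data-driven N1 window selection.
#'
#' @param erps List of `erp_average` objects (across subjects and conditions).
#' @return A `gfp_trace`: tibble `time_ms`, `gfp`, with provenance attributes
#'   (`n_erps`, `timepoint`).
#' @export
grand_gfp <- function(erps) {
  stopifnot(length(erps) >= 1)
  wf <- Reduce(`+`, lapply(erps, function(e) e$waveform)) / length(erps)
  out <- tibble::tibble(time_ms = erps[[1]]$times_ms, gfp = gfp(wf))
  attr(out, "n_erps") <- length(erps)
  attr(out, "timepoint") <- erps[[1]]$timepoint
  class(out) <- c("gfp_trace", class(out))
  out
}

#' Data-driven N1 window: +/- 30 ms around the second GFP local maximum
#'
#' Scans the GFP trace inside the post-stimulus search range for local maxima
#' (strictly greater than both neighbors; plateaus count once, at their
#' center sample, after optional moving-average smoothing) in order of
#' latency, and returns the window centred on the second one. An optional
#' topography check can veto a candidate (e.g. requiring posterior
#' negativity), advancing to the next.
#'
#' @param trace A `gfp_trace` (or tibble with `time_ms`, `gfp`).
#' @param search_ms Latency range searched, default c(80, 350).
#' @param half_width_ms Half window width, default 30 (window = peak +/- 30).
#' @param smooth_ms Moving-average width (ms); 0 disables smoothing.
#' @param which_max Index of the local maximum to take, default 2 (the first
#'   is the earlier positive component).
#' @param topo_check Optional function(peak_ms) -> logical; `FALSE` vetoes.
#' @return An `n1_window`: list with `start_ms`, `end_ms`, `peak_ms`,
#'   `candidates` (all local maxima found, for audit), `timepoint`.
#' @examples
#' tr <- tibble::tibble(
#'   time_ms = seq(-100, 612, by = 2),
#'   gfp = exp(-(seq(-100, 612, by = 2) - 120)^2 / 500) +
#'     2 * exp(-(seq(-100, 612, by = 2) - 228)^2 / 800)
#' )
#' find_n1_window(tr)
#' @export
find_n1_window <- function(trace, search_ms = c(80, 350), half_width_ms = 30,
                           smooth_ms = 0, which_max = 2, topo_check = NULL) {
  t_ms <- trace$time_ms
  g <- trace$gfp
  stopifnot(length(t_ms) == length(g), !is.unsorted(t_ms))
  if (min(t_ms) > search_ms[1] || max(t_ms) < search_ms[2]) {
    stop("GFP trace does not cover the search range")
  }
  if (smooth_ms > 0) {
    dt <- stats::median(diff(t_ms))
    w <- max(1L, round(smooth_ms / dt))
    if (w %% 2 == 0) w <- w + 1L
    g <- stats::filter(g, rep(1 / w, w), sides = 2)
    g[is.na(g)] <- trace$gfp[is.na(g)]
    g <- as.numeric(g)
  }
  peaks <- local_maxima(g)
  keep <- t_ms[peaks] >= search_ms[1] & t_ms[peaks] <= search_ms[2]
  peaks <- peaks[keep]
  cand <- tibble::tibble(peak_ms = t_ms[peaks], gfp = g[peaks])
  if (!is.null(topo_check)) {
    ok <- vapply(cand$peak_ms, topo_check, logical(1))
    cand <- cand[ok, , drop = FALSE]
  }
  if (nrow(cand) < which_max) {
    stop(
      "found only ", nrow(cand), " GFP local maxima in the search range; ",
      "cannot select maximum #", which_max,
      " - enter the analysis window manually"
    )
  }
  peak_ms <- cand$peak_ms[which_max]
  # snap endpoints to the sampling grid, both endpoints included downstream
  start_ms <- t_ms[which.min(abs(t_ms - (peak_ms - half_width_ms)))]
  end_ms <- t_ms[which.min(abs(t_ms - (peak_ms + half_width_ms)))]
  structure(
    list(
      start_ms = start_ms, end_ms = end_ms, peak_ms = peak_ms,
      candidates = cand, timepoint = attr(trace, "timepoint")
    ),
    class = "n1_window"
  )
}

# indices of strict local maxima; plateaus resolved to their center sample
local_maxima <- function(g) {
  n <- length(g)
  if (n < 3) {
    return(integer(0))
  }
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (g[i] > g[i - 1L]) {
      j <- i
      while (j < n && g[j + 1L] == g[i]) j <- j + 1L
      if (j < n && g[j + 1L] < g[i]) {
        out <- c(out, as.integer(floor((i + j) / 2)))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

#' @export
print.n1_window <- function(x, ...) {
  cat(sprintf(
    "<n1_window> %s%g-%g ms (peak %g ms)\n",
    if (!is.null(x$timepoint) && !is.na(x$timepoint)) paste0(x$timepoint, ": ") else "",
    x$start_ms, x$end_ms, x$peak_ms
  ))
  invisible(x)
}

#' Mean amplitude over an electrode cluster and time window
#'
#' Mean of the ERP over the cluster channels and all samples from
#' `w$start_ms` to `w$end_ms` inclusive (both endpoints on the sampling
#' grid). Linear in the ERP.
#'
#' @param erp An `erp_average` (or channels x samples matrix with a `times_ms`
#'   attribute supplied via `times_ms`).
#' @param w An `n1_window`.
#' @param montage Montage supplying cluster membership.
#' @param cluster Cluster name, e.g. `"LOT"`.
#' @return Scalar mean amplitude (uV).
#' @export
cluster_mean_amplitude <- function(erp, w, montage = NULL, cluster = "LOT") {
  stopifnot(inherits(erp, "erp_average"), inherits(w, "n1_window"))
  montage <- montage %||% erp$montage
  ch <- montage$clusters[[cluster]]
  if (is.null(ch) || length(ch) == 0) stop("empty or unknown cluster: ", cluster)
  if (w$start_ms < min(erp$times_ms) || w$end_ms > max(erp$times_ms)) {
    stop("window lies outside the epoch span")
  }
  rows <- match(ch, montage$channels)
  cols <- which(erp$times_ms >= w$start_ms - 1e-9 & erp$times_ms <= w$end_ms + 1e-9)
  mean(erp$waveform[rows, cols])
}

#' Long-format N1 amplitude table
#'
#' One row per subject x timepoint x condition x hemisphere: the unit of
#' analysis for the mixed model.
#'
#' @param erps List of `erp_average` objects (all subjects/conditions).
#' @param windows Named list of `n1_window` per timepoint (or a single window).
#' @param montage Montage supplying the clusters.
#' @param clusters Hemisphere cluster names.
#' @return Tibble `subject`, `timepoint`, `condition`, `hemisphere`,
#'   `n1_mean_amplitude`, `n_epochs`.
#' @export
amplitude_table <- function(erps, windows, montage = NULL,
                            clusters = c("LOT", "ROT")) {
  rows <- lapply(erps, function(e) {
    w <- if (inherits(windows, "n1_window")) windows else windows[[e$timepoint]]
    if (is.null(w)) stop("no window for timepoint ", e$timepoint)
    tibble::tibble(
      subject = e$subject, timepoint = e$timepoint, condition = e$condition,
      hemisphere = clusters,
      n1_mean_amplitude = vapply(
        clusters,
        function(cl) cluster_mean_amplitude(e, w, montage %||% e$montage, cl),
        numeric(1)
      ),
      n_epochs = e$n_epochs
    )
  })
  dplyr::bind_rows(rows) %>%
    dplyr::arrange(.data$subject, .data$timepoint, .data$condition, .data$hemisphere)
}

#' Coarse and fine sensitivity differences
#'
#' Signed per-subject amplitude differences: coarse = DIG - FF, fine =
#' DIG - LET (negative values mean a stronger, more negative, N1 to digits).
#' Subject-visits missing a condition are skipped and reported in the
#' `skipped` attribute.
#'
#' @param amp Amplitude tibble as from [amplitude_table()] (columns `subject`,
#'   `timepoint`, `condition`, `hemisphere`, `n1_mean_amplitude`).
#' @param contrasts Named list of condition pairs (minuend, subtrahend).
#' @return Tibble `subject`, `timepoint`, `hemisphere`, `contrast`,
#'   `difference_uv`.
#' @export
sensitivity_differences <- function(amp,
                                    contrasts = list(
                                      coarse = c("DIG", "FF"),
                                      fine = c("DIG", "LET")
                                    )) {
  wide <- amp %>%
    dplyr::select(
      "subject", "timepoint", "hemisphere", "condition", "n1_mean_amplitude"
    ) %>%
    tidyr::pivot_wider(
      names_from = "condition", values_from = "n1_mean_amplitude"
    )
  out <- list()
  skipped <- list()
  for (nm in names(contrasts)) {
    pair <- contrasts[[nm]]
    if (!all(pair %in% names(wide))) {
      skipped[[nm]] <- pair
      next
    }
    d <- wide[[pair[1]]] - wide[[pair[2]]]
    ok <- !is.na(d)
    if (any(!ok)) {
      skipped[[length(skipped) + 1]] <- wide[!ok, c("subject", "timepoint", "hemisphere")]
    }
    out[[nm]] <- wide[ok, c("subject", "timepoint", "hemisphere")] %>%
      dplyr::mutate(contrast = nm, difference_uv = d[ok])
  }
  res <- dplyr::bind_rows(out) %>%
    dplyr::arrange(.data$subject, .data$timepoint, .data$hemisphere, .data$contrast)
  attr(res, "skipped") <- skipped
  res
}
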