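#' Plot a GFP trace with the selected N1 window
#'
#' @param trace A `gfp_trace`.
#' @param window Optional `n1_window` to shade.
#' @return A ggplot.
#' @export
plot_gfp <- function(trace, window = NULL) {
  p <- ggplot2::ggplot(trace, ggplot2::aes(x = .data$time_ms, y = .data$gfp)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Time (ms)", y = expression(GFP ~ (mu * V)),
      title = attr(trace, "timepoint")
    ) +
    ggplot2::theme_minimal()
  if (!is.null(window)) {
    p <- p +
      ggplot2::annotate("rect",
        xmin = window$start_ms, xmax = window$end_ms,
        ymin = -Inf, ymax = Inf, alpha = 0.2, fill = "gold"
      ) +
      ggplot2::geom_vline(xintercept = window$peak_ms, linetype = "dashed")
  }
  p
}

#' Cluster ERP waveforms per condition
#'
#' Averages the supplied condition ERPs over the subjects present and plots
#' the cluster mean waveform per condition and hemisphere.
#'
#' @param erps List of `erp_average` objects (one timepoint).
#' @param montage Montage with LOT/ROT clusters.
#' @param window Optional `n1_window` to shade.
#' @return A ggplot, one facet per hemisphere.
#' @export
plot_cluster_erps <- function(erps, montage = NULL, window = NULL) {
  montage <- montage %||% erps[[1]]$montage
  rows <- list()
  for (e in erps) {
    for (cl in names(montage$clusters)) {
      idx <- match(montage$clusters[[cl]], montage$channels)
      rows[[length(rows) + 1]] <- tibble::tibble(
        time_ms = e$times_ms,
        amplitude_uv = colMeans(e$waveform[idx, , drop = FALSE]),
        condition = e$condition, hemisphere = cl, subject = e$subject
      )
    }
  }
  df <- dplyr::bind_rows(rows) %>%
    dplyr::group_by(.data$time_ms, .data$condition, .data$hemisphere) %>%
    dplyr::summarise(amplitude_uv = mean(.data$amplitude_uv), .groups = "drop")
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$time_ms, y = .data$amplitude_uv, colour = .data$condition
  )) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~hemisphere) +
    ggplot2::labs(x = "Time (ms)", y = expression(Amplitude ~ (mu * V))) +
    ggplot2::theme_minimal()
  if (!is.null(window)) {
    p <- p + ggplot2::annotate("rect",
      xmin = window$start_ms, xmax = window$end_ms,
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "gold"
    )
  }
  p
}

#' @export
autoplot.tanova_result <- function(object, alpha = 0.05, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$p)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(
      data = dplyr::filter(df, .data$p < alpha), colour = "darkorange"
    ) +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Time (ms)", y = "permutation p",
      title = paste(attr(object, "conditions"), collapse = " vs ")
    ) +
    ggplot2::theme_minimal()
}

#' Mean N1 amplitudes per condition, timepoint and hemisphere
#'
#' @param amp Amplitude tibble ([amplitude_table()] format).
#' @return A ggplot with group means and 95% confidence intervals.
#' @export
plot_amplitudes <- function(amp) {
  df <- amp %>%
    dplyr::group_by(.data$timepoint, .data$condition, .data$hemisphere) %>%
    dplyr::summarise(
      mean = mean(.data$n1_mean_amplitude),
      ci = 1.96 * sd(.data$n1_mean_amplitude) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$timepoint, y = .data$mean,
    colour = .data$condition, group = .data$condition
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean - .data$ci, ymax = .data$mean + .data$ci
    )) +
    ggplot2::facet_wrap(~hemisphere) +
    ggplot2::labs(x = NULL, y = expression(N1 ~ mean ~ amplitude ~ (mu * V))) +
    ggplot2::theme_minimal()
}

#' Scatter of a correlation-grid cell
#'
#' @param differences Tibble from [sensitivity_differences()].
#' @param behavior Behavior score tibble.
#' @param timepoint,hemisphere,contrast,measure Cell selectors.
#' @return A ggplot with a rank-based trend annotation.
#' @export
plot_brain_behavior <- function(differences, behavior, timepoint = "T4",
                                hemisphere = "LOT", contrast = "coarse",
                                measure = "arithmetic_pr") {
  nv <- dplyr::filter(
    differences,
    .data$timepoint == !!timepoint, .data$hemisphere == !!hemisphere,
    .data$contrast == !!contrast
  )
  bv <- dplyr::filter(
    behavior, .data$measure == !!measure, .data$timepoint == !!timepoint
  )
  j <- dplyr::inner_join(
    dplyr::select(nv, "subject", "difference_uv"),
    dplyr::select(bv, "subject", "score"),
    by = "subject"
  )
  s <- spearman(j$difference_uv, j$score)
  ggplot2::ggplot(j, ggplot2::aes(x = .data$score, y = .data$difference_uv)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(
      x = measure, y = expression(Delta ~ N1 ~ (mu * V)),
      subtitle = sprintf("Spearman rho = %.2f, p = %.3g, n = %d", s$rho, s$p, s$n)
    ) +
    ggplot2::theme_minimal()
}
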