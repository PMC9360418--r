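#' Tidy the fixed-effect F-table of a fitted N1 mixed model
#'
#' @param x An `n1_lmm`.
#' @param ... Unused.
#' @return Tibble `term`, `num_df`, `den_df`, `F`, `p`.
#' @export
tidy.n1_lmm <- function(x, ...) {
  x$anova
}

#' One-row model summary for a fitted N1 mixed model
#'
#' @param x An `n1_lmm`.
#' @param ... Unused.
#' @return Tibble with sample sizes, exclusion count, variance components,
#'   log-likelihood, AIC and BIC.
#' @export
glance.n1_lmm <- function(x, ...) {
  vc <- nlme::VarCorr(x$fit)
  tibble::tibble(
    nobs = nrow(x$data_used),
    n_subjects = nlevels(x$data_used$subject),
    n_excluded = x$n_excluded,
    sd_subject = as.numeric(vc["(Intercept)", "StdDev"]),
    sigma = x$fit$sigma,
    logLik = as.numeric(stats::logLik(x$fit)),
    AIC = stats::AIC(x$fit),
    BIC = stats::BIC(x$fit)
  )
}

#' @export
tidy.tanova_result <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.tanova_result <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x),
    n_significant = sum(x$p < 0.05),
    min_p = min(x$p),
    n_permutations = attr(x, "n_permutations"),
    n_subjects = attr(x, "n_subjects")
  )
}

#' @export
tidy.n1_window <- function(x, ...) {
  tibble::tibble(
    timepoint = x$timepoint %||% NA_character_,
    start_ms = x$start_ms, peak_ms = x$peak_ms, end_ms = x$end_ms
  )
}

#' Report a results object in the field's reporting template
#'
#' Formats F-tests as `F(df1,df2) = ..., p = ...` and correlation cells as
#' `rho = ..., p = ..., p_FDR = ...` lines.
#'
#' @param res An `n1_results` from [run_analysis()].
#' @return Character vector of report lines (invisibly printed).
#' @export
report_lines <- function(res) {
  stopifnot(inherits(res, "n1_results"))
  lines <- character(0)
  fmt_p <- function(p) ifelse(p < 0.001, "p < 0.001", sprintf("p = %.3f", p))
  if (!is.null(res$lmm_main)) {
    a <- res$lmm_main$anova
    lines <- c(lines, "Main model (hemisphere x condition x timepoint):")
    lines <- c(lines, sprintf(
      "  %s: F(%d,%d) = %.2f, %s",
      a$term, a$num_df, a$den_df, a$F, fmt_p(a$p)
    ))
  }
  for (nm in c("contrasts_coarse", "contrasts_fine")) {
    ct <- res[[nm]]
    if (is.null(ct)) next
    lines <- c(lines, paste0(sub("contrasts_", "", nm), " contrasts per timepoint:"))
    lines <- c(lines, sprintf(
      "  %s %s: t(%d) = %.2f, %s",
      ct$timepoint, ct$contrast, as.integer(ct$df), ct$t, fmt_p(ct$p)
    ))
  }
  if (!is.null(res$correlations)) {
    cg <- dplyr::filter(res$correlations, !.data$insufficient)
    lines <- c(lines, "Brain-behavior correlations (grid):")
    lines <- c(lines, sprintf(
      "  %s %s %s ~ %s@%s: rho = %.2f, %s, p_FDR = %.3f (n = %d)",
      cg$neural_timepoint, cg$hemisphere, cg$contrast, cg$measure,
      cg$behavior_timepoint, cg$rho, fmt_p(cg$p), cg$p_fdr, cg$n
    ))
  }
  lines
}
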