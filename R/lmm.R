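#' Random-intercept mixed model on N1 mean amplitudes
#'
#' Fits `n1_mean_amplitude ~ hemisphere * condition * timepoint` (factors with
#' a single observed level are dropped from the formula) with a per-subject
#' random intercept via [nlme::lme()], computes normalized residuals, excludes
#' observations whose normalized residual exceeds `outlier_threshold` in
#' absolute value, and refits once. Both fits are kept; reported F-tests and
#' contrasts come from the refit.
#'
#' @param data Long-format tibble with columns `subject`, `timepoint`,
#'   `condition`, `hemisphere`, and the response.
#' @param conditions Optional condition subset (e.g. `c("DIG", "FF")` for the
#'   coarse-sensitivity model); default uses all conditions present.
#' @param response Response column name.
#' @param outlier_threshold Normalized-residual cutoff, default 3; `Inf`
#'   disables exclusion.
#' @param method Estimation method passed to `lme`, default `"ML"`.
#' @return An `n1_lmm` object: `fit` (after exclusion), `fit_initial`,
#'   `anova` (F-table tibble), `excluded` (rows dropped), `data_used`, `spec`.
#' @export
fit_n1_lmm <- function(data, conditions = NULL,
                       response = "n1_mean_amplitude",
                       outlier_threshold = 3, method = "ML") {
  stopifnot(response %in% names(data))
  d <- dplyr::as_tibble(data)
  if (!is.null(conditions)) {
    missing_lv <- setdiff(conditions, unique(d$condition))
    if (length(missing_lv)) {
      stop("condition level(s) absent from data: ", paste(missing_lv, collapse = ", "))
    }
    d <- dplyr::filter(d, .data$condition %in% conditions)
  }
  for (f in c("subject", "timepoint", "condition", "hemisphere")) {
    d[[f]] <- factor(d[[f]])
    empty <- names(which(table(d[[f]]) == 0))
    if (nlevels(d[[f]]) < 1 || length(empty)) {
      stop(
        "factor ", f, " has empty level(s): ", paste(empty, collapse = ", ")
      )
    }
  }
  if (length(unique(d$subject)) < 2) stop("need at least 2 subjects")

  terms <- c("hemisphere", "condition", "timepoint")
  terms <- terms[vapply(terms, function(f) nlevels(d[[f]]) > 1, logical(1))]
  if (length(terms) == 0) stop("no fixed factor with >1 level")
  fml <- stats::as.formula(
    paste(response, "~", paste(terms, collapse = " * "))
  )

  fit0 <- nlme::lme(fml,
    random = ~ 1 | subject, data = d, method = method,
    control = nlme::lmeControl(opt = "optim", maxIter = 200, msMaxIter = 200)
  )
  r <- stats::resid(fit0, type = "normalized")
  out_idx <- which(abs(r) > outlier_threshold)
  excluded <- d[out_idx, , drop = FALSE]
  if (length(out_idx) > 0) {
    d_used <- d[-out_idx, , drop = FALSE]
    fit <- nlme::lme(fml,
      random = ~ 1 | subject, data = d_used, method = method,
      control = nlme::lmeControl(opt = "optim", maxIter = 200, msMaxIter = 200)
    )
  } else {
    d_used <- d
    fit <- fit0
  }

  an <- as.data.frame(stats::anova(fit))
  an_tbl <- tibble::tibble(
    term = rownames(an),
    num_df = an$numDF, den_df = an$denDF,
    F = an$`F-value`, p = an$`p-value`
  ) %>% dplyr::filter(.data$term != "(Intercept)")

  structure(
    list(
      fit = fit, fit_initial = fit0, anova = an_tbl,
      excluded = excluded, n_excluded = length(out_idx),
      normalized_residuals = r, data_used = d_used,
      spec = list(
        formula = fml, response = response, method = method,
        outlier_threshold = outlier_threshold, terms = terms
      )
    ),
    class = "n1_lmm"
  )
}

#' @export
print.n1_lmm <- function(x, ...) {
  cat("<n1_lmm> ", deparse(x$spec$formula), " + (1 | subject), ",
    x$spec$method, "\n",
    sep = ""
  )
  cat(
    "  n =", nrow(x$data_used), "after excluding", x$n_excluded,
    "point(s) with |normalized residual| >", x$spec$outlier_threshold, "\n"
  )
  print(x$anova)
  invisible(x)
}

#' Signed per-timepoint condition contrasts
#'
#' Pairwise condition contrasts at each timepoint from the fitted mixed model
#' (estimated marginal means, containment degrees of freedom). Contrasts are
#' signed first-minus-second as given in `pairs`, so digit-sensitivity
#' effects appear as negative t values (digits minus control, N1 polarity).
#'
#' @param model An `n1_lmm`.
#' @param pairs List of condition pairs; defaults to the three pairwise
#'   contrasts restricted to conditions in the model.
#' @param by Conditioning factor, default `"timepoint"` (use `NULL` for an
#'   overall contrast).
#' @return Tibble `timepoint` (if `by`), `contrast`, `estimate`, `se`, `df`,
#'   `t`, `p` (unadjusted).
#' @export
posthoc_contrasts <- function(model, pairs = NULL, by = "timepoint") {
  stopifnot(inherits(model, "n1_lmm"))
  conds <- levels(model$data_used$condition)
  if (is.null(pairs)) {
    pairs <- Filter(
      function(p) all(p %in% conds),
      list(c("DIG", "FF"), c("DIG", "LET"), c("LET", "FF"))
    )
  }
  for (p in pairs) {
    if (!all(p %in% conds)) {
      stop("unknown condition pair: ", paste(p, collapse = "-"))
    }
  }
  if (!"condition" %in% model$spec$terms) stop("model has no condition factor")
  spec_fml <- if (!is.null(by) && by %in% model$spec$terms) {
    stats::as.formula(paste("~ condition |", by))
  } else {
    by <- NULL
    ~condition
  }
  # emmeans notes that marginal means average over interacting factors; that
  # averaging is exactly what the per-timepoint contrast is defined as
  em <- suppressMessages(
    emmeans::emmeans(model$fit, spec_fml, data = model$data_used)
  )
  methods <- lapply(pairs, function(p) {
    v <- stats::setNames(rep(0, length(conds)), conds)
    v[p[1]] <- 1
    v[p[2]] <- -1
    v
  })
  names(methods) <- vapply(pairs, paste, "", collapse = "-")
  ct <- summary(emmeans::contrast(em, method = methods))
  out <- tibble::as_tibble(ct) %>%
    dplyr::rename(
      estimate = "estimate", se = "SE", t = "t.ratio", p = "p.value"
    )
  if (!is.null(by)) out <- dplyr::rename(out, timepoint = !!by)
  dplyr::select(out, dplyr::any_of(c(
    "timepoint", "contrast", "estimate", "se", "df", "t", "p"
  )))
}
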