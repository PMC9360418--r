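#' Behavior ground truth: latent skill and brain-behavior coupling
#'
#' Behavioral scores are monotone transforms of a per-child latent skill.
#' The coupling between latent skill and the simulated neural sensitivity
#' effect is imposed through a Gaussian copula on ranks, so that the target
#' Spearman correlation `brain_behavior_rho` holds between the coupled
#' behavioral measure and the simulated sensitivity value at the coupling
#' cell (positive rho: better skills go with a less negative, i.e. weaker,
#' digit-sensitivity difference).
#'
#' @param brain_behavior_rho Target Spearman correlation in \[-1, 1\].
#' @param coupling Cell the coupling acts on: list with `timepoint`,
#'   `hemisphere`, `contrast`, `measure`.
#' @param reliability Named vector of per-measure rank reliabilities in
#'   (0, 1\]; the coupled measure at the coupling timepoint is always taken at
#'   reliability 1 so the imposed rank association is exact.
#' @return A `behavior_truth` list.
#' @export
behavior_truth <- function(brain_behavior_rho = 0.6,
                           coupling = list(
                             timepoint = "T4", hemisphere = "LOT",
                             contrast = "coarse", measure = "arithmetic_pr"
                           ),
                           reliability = c(
                             number_knowledge = 0.8, arithmetic_pr = 0.9,
                             arithmetic_raw = 0.9, reading_pr = 0.8
                           )) {
  stopifnot(brain_behavior_rho >= -1, brain_behavior_rho <= 1)
  structure(
    list(
      brain_behavior_rho = brain_behavior_rho,
      coupling = coupling,
      reliability = reliability
    ),
    class = "behavior_truth"
  )
}

# measure -> timepoints it is administered at
behavior_schedule <- list(
  number_knowledge = c("T1", "T2", "T3", "T4"),
  arithmetic_pr = c("T4", "T5"),
  arithmetic_raw = c("T4", "T5"),
  reading_pr = c("T3", "T4", "T5")
)

#' Simulate behavioral score tables coupled to a neural measure
#'
#' @param visit_pattern Logical matrix subjects x timepoints.
#' @param btruth A [behavior_truth()].
#' @param seed Integer seed.
#' @param neural Optional tibble (`subject`, `value`) of simulated sensitivity
#'   values at the coupling cell; when supplied, latent skill is generated by
#'   a Gaussian copula on the ranks of `value` with the configured Spearman
#'   target. Subjects absent from `neural` get independent latent skill.
#' @return Tibble `subject`, `timepoint`, `measure`, `score`; the latent skill
#'   vector is attached as attribute `latent_skill`.
#' @export
simulate_behavior_table <- function(visit_pattern, btruth = behavior_truth(),
                                    seed = 1L, neural = NULL) {
  subjects <- rownames(visit_pattern)
  timepoints <- colnames(visit_pattern)
  with_seed(seed, {
    latent <- stats::setNames(rnorm(length(subjects)), subjects)
    if (!is.null(neural) && nrow(neural) > 1 && btruth$brain_behavior_rho != 0) {
      # Pearson correlation on normal scores reproducing the Spearman target
      r <- 2 * sin(pi * btruth$brain_behavior_rho / 6)
      m <- nrow(neural)
      z_x <- qnorm((rank(neural$value, ties.method = "average") - 0.5) / m)
      latent[neural$subject] <- r * z_x + sqrt(1 - r^2) * rnorm(m)
    }

    rows <- list()
    for (meas in names(behavior_schedule)) {
      lam0 <- unname(btruth$reliability[meas])
      for (tp in intersect(behavior_schedule[[meas]], timepoints)) {
        lam <- if (meas == btruth$coupling$measure &&
          tp == btruth$coupling$timepoint) 1 else lam0
        here <- subjects[visit_pattern[, tp]]
        g <- lam * latent[here] + sqrt(1 - lam^2) * rnorm(length(here))
        score <- switch(meas,
          number_knowledge = pmin(21, pmax(0, round(
            c(T1 = 15, T2 = 18, T3 = 19, T4 = 20.5)[[tp]] + 2.5 * g
          ))),
          arithmetic_pr = 100 * pnorm(g),
          arithmetic_raw = pmax(0, round(
            c(T4 = 62, T5 = 125)[[tp]] + 15 * g
          )),
          reading_pr = 100 * pnorm(g)
        )
        rows[[length(rows) + 1]] <- tibble::tibble(
          subject = here, timepoint = tp, measure = meas,
          score = as.numeric(score)
        )
      }
    }
    out <- dplyr::arrange(
      dplyr::bind_rows(rows), .data$subject, .data$timepoint, .data$measure
    )
    attr(out, "latent_skill") <- latent
    out
  })
}

#' Simulate a longitudinal amplitude-record table
#'
#' Direct generator at the mixed model's unit of analysis: one N1 mean
#' amplitude per subject x visit x condition x hemisphere, composed of the
#' ground-truth condition amplitude at that timepoint, a subject-level offset
#' shared across visits (the random intercept), a subject-specific deviation
#' of the digit response (coarse-sensitivity heterogeneity), and residual
#' noise.
#'
#' @param cohort A [cohort_spec()].
#' @param truth A [ground_truth()].
#' @param seed Integer seed.
#' @param visit_pattern Optional pre-drawn pattern (else drawn from `seed`).
#' @return Tibble `subject`, `timepoint`, `condition`, `hemisphere`,
#'   `n1_mean_amplitude`; subject offsets and digit deviations are attached as
#'   attributes `subject_offset` and `dig_deviation`.
#' @export
simulate_amplitude_table <- function(cohort, truth, seed = 1L,
                                     visit_pattern = NULL) {
  stopifnot(inherits(cohort, "cohort_spec"), inherits(truth, "ground_truth"))
  vp <- visit_pattern %||% draw_visit_pattern(cohort, derive_seed(seed, 1))
  subjects <- rownames(vp)
  conditions <- rownames(truth$condition_amplitude_uv)
  with_seed(derive_seed(seed, 2), {
    offset <- stats::setNames(truth$subject_sd_uv * rnorm(length(subjects)), subjects)
    dig_dev <- stats::setNames(truth$coarse_effect_sd_uv * rnorm(length(subjects)), subjects)
    grid <- expand.grid(
      subject = subjects, timepoint = colnames(vp),
      condition = conditions, hemisphere = c("LOT", "ROT"),
      stringsAsFactors = FALSE
    )
    grid <- grid[vp[cbind(grid$subject, grid$timepoint)], ]
    amp <- truth$condition_amplitude_uv[cbind(grid$condition, grid$timepoint)] +
      offset[grid$subject] +
      ifelse(grid$condition == "DIG", dig_dev[grid$subject], 0) +
      truth$amplitude_noise_sd_uv * rnorm(nrow(grid))
    out <- tibble::as_tibble(grid)
    out$n1_mean_amplitude <- as.numeric(amp)
    out <- dplyr::arrange(
      out, .data$subject, .data$timepoint, .data$condition, .data$hemisphere
    )
    attr(out, "subject_offset") <- offset
    attr(out, "dig_deviation") <- dig_dev
    out
  })
}

#' Simulate a complete study bundle
#'
#' One call produces everything downstream stages consume. In `"amplitude"`
#' mode (the default, used for statistical parameter-recovery work) the bundle
#' carries the amplitude-record table directly; in `"signal"` mode it carries
#' one continuous recording plus event table per subject-visit, generated by
#' the forward model, from which the full preprocessing/ERP path derives the
#' amplitudes. Behavioral scores are coupled to the simulated coarse
#' sensitivity at the configured cell via the rank copula.
#'
#' @param cohort A [cohort_spec()].
#' @param truth A [ground_truth()]; in signal mode its topography must be
#'   built on `montage`.
#' @param behavior A [behavior_truth()].
#' @param seed Master seed; all per-subject and per-stage seeds derive from it.
#' @param mode `"amplitude"` or `"signal"`.
#' @param montage Montage for signal mode.
#' @param design A [design_spec()] for signal mode.
#' @param rate Native simulation rate (Hz) for signal mode.
#' @return An `n1_bundle` list with `visit_pattern`, `behavior_table`,
#'   `manifest` (per subject x timepoint x condition injected amplitudes), and
#'   either `amplitude_table` or `recordings` + `events`.
#' @export
simulate_cohort <- function(cohort = cohort_spec(), truth, behavior = behavior_truth(),
                            seed = 1L, mode = c("amplitude", "signal"),
                            montage = NULL, design = design_spec(), rate = 1000) {
  mode <- match.arg(mode)
  stopifnot(inherits(truth, "ground_truth"))
  vp <- draw_visit_pattern(cohort, derive_seed(seed, 1))
  subjects <- rownames(vp)

  bundle <- list(
    mode = mode, cohort = cohort, truth = truth, behavior_truth = behavior,
    visit_pattern = vp, seed = seed
  )

  if (mode == "amplitude") {
    amp <- simulate_amplitude_table(cohort, truth, seed = seed, visit_pattern = vp)
    bundle$amplitude_table <- amp
    offset <- attr(amp, "subject_offset")
    dig_dev <- attr(amp, "dig_deviation")
    diffs <- sensitivity_differences(amp)
    neural <- diffs %>%
      dplyr::filter(
        .data$timepoint == behavior$coupling$timepoint,
        .data$hemisphere == behavior$coupling$hemisphere,
        .data$contrast == behavior$coupling$contrast
      ) %>%
      dplyr::select(subject = "subject", value = "difference_uv")
  } else {
    stopifnot(inherits(montage, "eeg_montage"))
    with_seed(derive_seed(seed, 2), {
      offset <- stats::setNames(truth$subject_sd_uv * rnorm(length(subjects)), subjects)
      dig_dev <- stats::setNames(truth$coarse_effect_sd_uv * rnorm(length(subjects)), subjects)
    })
    recordings <- list()
    events <- list()
    k <- 0L
    for (s in subjects) {
      for (tp in colnames(vp)[vp[s, ]]) {
        k <- k + 1L
        id <- paste(s, tp, sep = "_")
        events[[id]] <- make_design(design, seed = derive_seed(seed, 100 + k))
        recordings[[id]] <- simulate_subject(
          montage, events[[id]], truth, tp,
          seed = derive_seed(seed, 10000 + k), rate = rate,
          subject_offset_uv = offset[[s]],
          condition_offset_uv = c(DIG = dig_dev[[s]]),
          subject = s
        )
      }
    }
    bundle$recordings <- recordings
    bundle$events <- events
    # couple behavior to the injected coarse effect at the coupling timepoint
    tp0 <- behavior$coupling$timepoint
    base <- truth$condition_amplitude_uv["DIG", tp0] -
      truth$condition_amplitude_uv["FF", tp0]
    here <- subjects[vp[, tp0]]
    neural <- tibble::tibble(subject = here, value = base + dig_dev[here])
  }

  bundle$behavior_table <- simulate_behavior_table(
    vp, behavior, seed = derive_seed(seed, 3), neural = neural
  )

  visits <- which(vp, arr.ind = TRUE)
  man <- tidyr::expand_grid(
    i = seq_len(nrow(visits)),
    condition = rownames(truth$condition_amplitude_uv)
  )
  man$subject <- rownames(vp)[visits[man$i, "row"]]
  man$timepoint <- colnames(vp)[visits[man$i, "col"]]
  man$injected_amplitude_uv <-
    truth$condition_amplitude_uv[cbind(man$condition, man$timepoint)] +
    offset[man$subject] + ifelse(man$condition == "DIG", dig_dev[man$subject], 0)
  bundle$manifest <- man %>%
    dplyr::select("subject", "timepoint", "condition", "injected_amplitude_uv") %>%
    dplyr::arrange(.data$subject, .data$timepoint, .data$condition)

  structure(bundle, class = "n1_bundle")
}

#' @export
print.n1_bundle <- function(x, ...) {
  cat(sprintf(
    "<n1_bundle> mode: %s; %d subjects, %d visits over %s\n",
    x$mode, nrow(x$visit_pattern), sum(x$visit_pattern),
    paste(colnames(x$visit_pattern), collapse = ", ")
  ))
  invisible(x)
}

#' Write the ground-truth manifest as structured text
#'
#' @param bundle An `n1_bundle`.
#' @param path Output file (tab-separated).
#' @export
write_manifest <- function(bundle, path) {
  utils::write.table(bundle$manifest, path,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
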