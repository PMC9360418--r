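#' Pipeline run configuration
#'
#' Bundles every stage parameter with its standard default: 0.1-30 Hz
#' band-pass, 50 Hz notch, 500 Hz analysis rate, +/-200 uV rejection, 20-epoch
#' inclusion minimum, 80-350 ms window search with a +/-30 ms window around
#' the second GFP maximum, 5000 permutations, +/-3 normalized-residual
#' exclusion, and the 36-cell correlation grid.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param ... Overrides for any default field.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    low_hz = 0.1, high_hz = 30, notch_hz = 50, target_rate = 500,
    reject_threshold_uv = 200, min_epochs = 20,
    window_search_ms = c(80, 350), window_half_width_ms = 30,
    baseline = TRUE,
    n_permutations = 5000,
    outlier_threshold = 3,
    grid = default_correlation_grid(),
    native_rate = 1000,
    conditions = c("DIG", "LET", "FF")
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Simulate a study bundle from a configuration
#'
#' Thin orchestration over [simulate_cohort()]: builds the montage, ground
#' truth and cohort from the configuration (or accepts them via arguments)
#' and returns the bundle; optionally writes tables, recordings and the
#' ground-truth manifest to a directory.
#'
#' @param config A [run_config()].
#' @param cohort,truth,behavior Optional specs; defaults are the study
#'   conditions ([cohort_spec()], [ground_truth()], [behavior_truth()]).
#' @param mode `"amplitude"` (default) or `"signal"`.
#' @param montage Montage for signal mode; default [make_montage()] when
#'   needed.
#' @param design A [design_spec()] for signal mode.
#' @param outdir Optional output directory.
#' @return The `n1_bundle`.
#' @export
run_simulate <- function(config = run_config(), cohort = cohort_spec(),
                         truth = NULL, behavior = behavior_truth(),
                         mode = c("amplitude", "signal"), montage = NULL,
                         design = design_spec(), outdir = NULL) {
  mode <- match.arg(mode)
  if (mode == "signal" && is.null(montage)) montage <- make_montage()
  if (is.null(truth)) {
    truth <- ground_truth(montage %||% make_montage(), timepoints = cohort$timepoints)
  }
  bundle <- simulate_cohort(cohort, truth, behavior,
    seed = config$seed, mode = mode,
    montage = montage, design = design, rate = config$native_rate
  )
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_manifest(bundle, file.path(outdir, "manifest.tsv"))
    utils::write.csv(bundle$behavior_table, file.path(outdir, "behavior.csv"),
      row.names = FALSE
    )
    if (mode == "amplitude") {
      utils::write.csv(bundle$amplitude_table, file.path(outdir, "amplitudes.csv"),
        row.names = FALSE
      )
    } else {
      write_montage(montage, file.path(outdir, "montage.csv"))
      for (id in names(bundle$recordings)) {
        write_recording(bundle$recordings[[id]], file.path(outdir, paste0(id, ".tsv")))
        write_events(bundle$events[[id]], file.path(outdir, paste0(id, "_events.tsv")))
      }
    }
  }
  bundle
}

#' Run the full analysis on a bundle
#'
#' Signal-mode bundles go through the complete path: filtering and
#' downsampling, average reference, epoching, amplitude rejection, the
#' 20-epoch inclusion rule, condition averaging, grand-GFP window selection
#' per timepoint, cluster amplitudes. Amplitude-mode bundles enter directly
#' at the amplitude table. Then, in both modes: sensitivity differences, the
#' main and per-pair mixed models with outlier exclusion, per-timepoint
#' contrasts, TANOVA per timepoint and condition pair (signal mode), and the
#' brain-behavior correlation grid.
#'
#' @param bundle An `n1_bundle` from [run_simulate()].
#' @param config A [run_config()].
#' @return An `n1_results` list: `amplitudes`, `differences`, `windows`,
#'   `inclusion`, `lmm_main`, `lmm_coarse`, `lmm_fine`, `contrasts_coarse`,
#'   `contrasts_fine`, `tanova`, `correlations`.
#' @export
run_analysis <- function(bundle, config = run_config()) {
  stopifnot(inherits(bundle, "n1_bundle"))
  res <- list(config = config, mode = bundle$mode)

  if (bundle$mode == "signal") {
    erps <- list()
    inclusion <- list()
    for (id in names(bundle$recordings)) {
      rec <- bundle$recordings[[id]]
      rec <- bandpass_notch_downsample(rec,
        low_hz = config$low_hz, high_hz = config$high_hz,
        notch_hz = config$notch_hz, target_rate = config$target_rate
      )
      rec <- rereference_average(rec)
      es <- epoch_recording(rec, bundle$events[[id]], baseline = config$baseline)
      es <- reject_epochs(es, threshold_uv = config$reject_threshold_uv)
      dec <- apply_inclusion_rule(es,
        min_epochs = config$min_epochs,
        conditions = config$conditions
      )
      inclusion[[id]] <- dec
      if (dec$included) erps[[id]] <- average_condition(es)
    }
    res$inclusion <- dplyr::bind_rows(inclusion)
    erps_flat <- unlist(erps, recursive = FALSE)
    tps <- sort(unique(vapply(erps_flat, function(e) e$timepoint, "")))
    windows <- list()
    tanova <- list()
    for (tp in tps) {
      e_tp <- Filter(function(e) e$timepoint == tp, erps_flat)
      g <- grand_gfp(e_tp)
      windows[[tp]] <- find_n1_window(g,
        search_ms = config$window_search_ms,
        half_width_ms = config$window_half_width_ms
      )
      for (pair in list(c("DIG", "FF"), c("DIG", "LET"))) {
        e_pair <- Filter(function(e) e$condition %in% pair, e_tp)
        subj_ok <- table(vapply(e_pair, function(e) e$subject, ""))
        e_pair <- Filter(function(e) subj_ok[e$subject] == 2, e_pair)
        if (length(e_pair) >= 4) {
          ms <- map_set(e_pair, windows[[tp]])
          tanova[[paste(tp, paste(pair, collapse = "-"), sep = ": ")]] <-
            tanova_permutation_test(ms,
              n_permutations = config$n_permutations,
              seed = derive_seed(config$seed, 20 + match(tp, tps))
            )
        }
      }
    }
    res$windows <- windows
    res$tanova <- tanova
    res$amplitudes <- amplitude_table(erps_flat, windows)
  } else {
    res$amplitudes <- bundle$amplitude_table
  }

  res$differences <- sensitivity_differences(res$amplitudes)
  res$lmm_main <- fit_n1_lmm(res$amplitudes,
    outlier_threshold = config$outlier_threshold
  )
  have <- unique(res$amplitudes$condition)
  if (all(c("DIG", "FF") %in% have)) {
    res$lmm_coarse <- fit_n1_lmm(res$amplitudes,
      conditions = c("DIG", "FF"),
      outlier_threshold = config$outlier_threshold
    )
    res$contrasts_coarse <- posthoc_contrasts(res$lmm_coarse, list(c("DIG", "FF")))
  }
  if (all(c("DIG", "LET") %in% have)) {
    res$lmm_fine <- fit_n1_lmm(res$amplitudes,
      conditions = c("DIG", "LET"),
      outlier_threshold = config$outlier_threshold
    )
    res$contrasts_fine <- posthoc_contrasts(res$lmm_fine, list(c("DIG", "LET")))
  }
  if (!is.null(bundle$behavior_table)) {
    res$correlations <- correlation_grid(
      res$differences, bundle$behavior_table,
      grid = config$grid
    )
  }
  structure(res, class = "n1_results")
}

#' @export
print.n1_results <- function(x, ...) {
  cat("<n1_results> mode:", x$mode, "\n")
  cat("  amplitude records:", nrow(x$amplitudes), "\n")
  if (!is.null(x$lmm_main)) {
    cat("  main model F-tests:\n")
    print(x$lmm_main$anova)
  }
  invisible(x)
}

#' Parameter-recovery and calibration suite
#'
#' Re-runs the simulation-based checks that validate the statistical engine
#' under the study conditions: TANOVA type-I calibration on exchangeable-null
#' cohorts, coarse-contrast recovery (power and bias) with the per-timepoint
#' group sizes and a -2 uV injected effect, Spearman rank-coupling recovery
#' at n = 27, and the empirical false-discovery proportion of the BH-corrected
#' grid under a global null.
#'
#' @param seed Master seed.
#' @param n_null_cohorts Replicates for the TANOVA calibration.
#' @param n_recovery_cohorts Replicates for the mixed-model recovery.
#' @param n_rho_reps Replicates for the Spearman recovery.
#' @param n_permutations Permutations per TANOVA replicate.
#' @param alpha Nominal level.
#' @return Tibble `metric`, `value`, `target`, `pass`.
#' @export
run_recovery_suite <- function(seed = 1L, n_null_cohorts = 500,
                               n_recovery_cohorts = 100, n_rho_reps = 200,
                               n_permutations = 500, alpha = 0.05) {
  cal <- tanova_null_calibration(
    n_reps = n_null_cohorts, n_permutations = n_permutations,
    seed = derive_seed(seed, 41), alpha = alpha
  )
  rec <- coarse_recovery(
    n_reps = n_recovery_cohorts, seed = derive_seed(seed, 42)
  )
  rho <- spearman_recovery(
    n_reps = n_rho_reps, seed = derive_seed(seed, 43)
  )
  fdrv <- fdr_null_calibration(
    n_reps = n_rho_reps, seed = derive_seed(seed, 44), alpha = alpha
  )
  tibble::tibble(
    metric = c(
      "tanova_null_rejection_rate", "coarse_power", "coarse_bias_uv",
      "spearman_coverage", "empirical_fdr"
    ),
    value = c(
      cal$rejection_rate, rec$power, rec$bias, rho$coverage, fdrv$fdr
    ),
    target = c(
      "[0.03, 0.07]", ">= 0.95", "|bias| < 0.1", ">= 0.90", "<= 0.05"
    ),
    pass = c(
      cal$rejection_rate >= 0.03 && cal$rejection_rate <= 0.07,
      rec$power >= 0.95,
      abs(rec$bias) < 0.1,
      rho$coverage >= 0.90,
      fdrv$fdr <= alpha
    )
  )
}

#' TANOVA type-I calibration on exchangeable-null map sets
#'
#' @param n_reps Replicate cohorts.
#' @param n_subjects,n_channels,n_samples Map-set dimensions per replicate.
#' @param n_permutations Permutations per test.
#' @param seed Integer seed.
#' @param alpha Nominal level.
#' @return List with `rejection_rate` and `n_tests`.
#' @export
tanova_null_calibration <- function(n_reps = 500, n_subjects = 12,
                                    n_channels = 16, n_samples = 4,
                                    n_permutations = 500, seed = 1L,
                                    alpha = 0.05) {
  rej <- 0L
  tot <- 0L
  for (r in seq_len(n_reps)) {
    ms <- with_seed(derive_seed(seed, r), {
      maps <- array(rnorm(n_subjects * 2 * n_channels * n_samples),
        c(n_subjects, 2, n_channels, n_samples)
      )
      for (s in seq_len(n_subjects)) {
        for (cc in 1:2) maps[s, cc, , ] <- normalize_map(maps[s, cc, , ])
      }
      structure(
        list(
          maps = maps, subjects = paste0("S", seq_len(n_subjects)),
          conditions = c("A", "B"),
          times_ms = seq_len(n_samples), normalized = TRUE
        ),
        class = "map_set"
      )
    })
    tr <- tanova_permutation_test(ms,
      n_permutations = n_permutations,
      seed = derive_seed(seed, 100000 + r)
    )
    rej <- rej + sum(tr$p < alpha)
    tot <- tot + nrow(tr)
  }
  list(rejection_rate = rej / tot, n_tests = tot)
}

#' Coarse-contrast recovery under the study's group sizes
#'
#' Simulates amplitude-level cohorts with the per-timepoint group sizes and a
#' -2 uV digits-vs-false-fonts effect, runs the coarse mixed model with
#' outlier exclusion, and summarizes per-timepoint contrast significance and
#' bias.
#'
#' @param n_reps Number of cohorts.
#' @param seed Integer seed.
#' @param effect_uv Injected coarse effect (uV).
#' @return List `power` (share of cohorts with all per-timepoint contrasts
#'   negative and p < 0.05), `bias` (mean contrast estimate minus injected),
#'   `estimates` (per-cohort mean contrast estimates).
#' @export
coarse_recovery <- function(n_reps = 100, seed = 1L, effect_uv = -2) {
  cohort <- cohort_spec()
  all_sig <- logical(n_reps)
  est <- numeric(n_reps)
  amp <- default_condition_amplitudes()
  amp["DIG", ] <- amp["FF", ] + effect_uv
  truth <- ground_truth(make_montage(24), condition_amplitude_uv = amp)
  for (r in seq_len(n_reps)) {
    tab <- simulate_amplitude_table(cohort, truth, seed = derive_seed(seed, r))
    fit <- fit_n1_lmm(tab, conditions = c("DIG", "FF"))
    ct <- posthoc_contrasts(fit, list(c("DIG", "FF")))
    all_sig[r] <- all(ct$t < 0 & ct$p < 0.05)
    est[r] <- mean(ct$estimate)
  }
  list(power = mean(all_sig), bias = mean(est) - effect_uv, estimates = est)
}

#' Spearman rank-coupling recovery at the study's n
#'
#' @param n_reps Replicates.
#' @param n Paired observations per replicate (default 27).
#' @param rho_true Target rank correlation.
#' @param seed Integer seed.
#' @param band Recovery band checked per replicate.
#' @return List `coverage` (share of replicates with recovered rho inside the
#'   band), `rhos`.
#' @export
spearman_recovery <- function(n_reps = 200, n = 27, rho_true = 0.6, seed = 1L,
                              band = c(0.3, 0.85)) {
  rhos <- numeric(n_reps)
  r <- 2 * sin(pi * rho_true / 6)
  for (i in seq_len(n_reps)) {
    rhos[i] <- with_seed(derive_seed(seed, i), {
      x <- rnorm(n)
      z <- r * qnorm((rank(x) - 0.5) / n) + sqrt(1 - r^2) * rnorm(n)
      spearman(x, 100 * pnorm(z))$rho
    })
  }
  list(coverage = mean(rhos >= band[1] & rhos <= band[2]), rhos = rhos)
}

#' Empirical FDR of the BH-corrected grid under a global null
#'
#' Simulates grids of independent null cells (36 by default), applies the
#' BH correction, and reports the average false-discovery proportion.
#'
#' @param n_reps Replicates.
#' @param n_cells Grid size.
#' @param n Observations per cell.
#' @param seed Integer seed.
#' @param alpha FDR level.
#' @return List `fdr` (mean false-discovery proportion), `any_discovery_rate`.
#' @export
fdr_null_calibration <- function(n_reps = 200, n_cells = 36, n = 27, seed = 1L,
                                 alpha = 0.05) {
  fdp <- numeric(n_reps)
  any_disc <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    p <- with_seed(derive_seed(seed, i), {
      vapply(seq_len(n_cells), function(j) {
        spearman(rnorm(n), rnorm(n))$p
      }, numeric(1))
    })
    padj <- bh_fdr(p)
    disc <- sum(padj < alpha)
    fdp[i] <- if (disc > 0) 1 else 0 # all discoveries are false under the null
    any_disc[i] <- disc > 0
  }
  list(fdr = mean(fdp), any_discovery_rate = mean(any_disc))
}
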