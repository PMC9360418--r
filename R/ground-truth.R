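#' Ground truth for the synthetic N1 forward model
#'
#' Encodes everything the signal simulator injects: per-timepoint N1 latency,
#' component width, per-condition peak amplitudes at the occipito-temporal
#' clusters, zero-mean spatial topographies, an earlier positive component
#' (so the global field power shows the canonical first-then-second local
#' maximum structure), 1/f background noise, white sensor noise, and the rates
#' of high-amplitude artifact epochs and frontal blink transients.
#'
#' Default condition amplitudes encode the developmental effect structure the
#' pipeline is meant to recover: digits 2 uV more negative than false fonts at
#' every timepoint (coarse sensitivity), and letters transiently enhanced at
#' T2 so the digit-letter (fine) difference vanishes there.
#'
#' @param montage An [make_montage()] montage (topographies are built on it).
#' @param timepoints Ordered timepoint labels.
#' @param n1_latency_ms Named per-timepoint N1 peak latency (ms).
#' @param n1_width_ms Full width at half maximum of the N1 temporal kernel (ms).
#' @param condition_amplitude_uv Matrix conditions x timepoints of peak cluster
#'   amplitudes (uV, negative); dimnames required.
#' @param p1_latency_ms,p1_amplitude_uv,p1_width_ms Earlier positive component.
#' @param noise_spectrum_exponent Exponent alpha of the 1/f^alpha background.
#' @param pink_noise_sd_uv,sensor_noise_sd_uv Noise standard deviations (uV).
#' @param artifact_epoch_rate,blink_rate Per-epoch probabilities in \[0, 1\].
#' @param subject_sd_uv SD of the subject-level amplitude offset shared across
#'   visits (gives the mixed model a non-degenerate random intercept).
#' @param amplitude_noise_sd_uv Residual SD of cluster mean amplitudes in the
#'   amplitude-level generator (uV).
#' @param coarse_effect_sd_uv SD of the subject-specific deviation of the digit
#'   response (uV), shared across visits; gives each child their own coarse
#'   sensitivity, the quantity the brain-behavior coupling acts on.
#' @return A `ground_truth` list; topographies are exactly zero-mean across
#'   channels and scaled to unit mean over their cluster channels.
#' @export
ground_truth <- function(montage,
                         timepoints = paste0("T", 1:5),
                         n1_latency_ms = c(T1 = 228, T2 = 218, T3 = 220, T4 = 210, T5 = 208),
                         n1_width_ms = 60,
                         condition_amplitude_uv = default_condition_amplitudes(timepoints),
                         p1_latency_ms = 120,
                         p1_amplitude_uv = 5,
                         p1_width_ms = 70,
                         noise_spectrum_exponent = 1,
                         pink_noise_sd_uv = 6,
                         sensor_noise_sd_uv = 2,
                         artifact_epoch_rate = 0.05,
                         blink_rate = 0.05,
                         subject_sd_uv = 2,
                         amplitude_noise_sd_uv = 1.8,
                         coarse_effect_sd_uv = 1) {
  stopifnot(inherits(montage, "eeg_montage"))
  n1_latency_ms <- n1_latency_ms[timepoints]
  stopifnot(
    !anyNA(n1_latency_ms),
    all(is.finite(condition_amplitude_uv)),
    setequal(colnames(condition_amplitude_uv), timepoints),
    artifact_epoch_rate >= 0, artifact_epoch_rate <= 1,
    blink_rate >= 0, blink_rate <= 1
  )
  topo <- component_topography(montage, clusters = c("LOT", "ROT"))
  topo_p1 <- component_topography(montage, clusters = c("LOT", "ROT"), sigma = 1.0)
  structure(
    list(
      timepoints = timepoints,
      n1_latency_ms = n1_latency_ms,
      n1_width_ms = n1_width_ms,
      condition_amplitude_uv = condition_amplitude_uv[, timepoints, drop = FALSE],
      topography = topo,
      p1 = list(
        latency_ms = p1_latency_ms, amplitude_uv = p1_amplitude_uv,
        width_ms = p1_width_ms, topography = topo_p1
      ),
      noise_spectrum_exponent = noise_spectrum_exponent,
      pink_noise_sd_uv = pink_noise_sd_uv,
      sensor_noise_sd_uv = sensor_noise_sd_uv,
      artifact_epoch_rate = artifact_epoch_rate,
      blink_rate = blink_rate,
      subject_sd_uv = subject_sd_uv,
      amplitude_noise_sd_uv = amplitude_noise_sd_uv,
      coarse_effect_sd_uv = coarse_effect_sd_uv
    ),
    class = "ground_truth"
  )
}

#' @rdname ground_truth
#' @export
default_condition_amplitudes <- function(timepoints = paste0("T", 1:5)) {
  amp <- rbind(
    DIG = rep(-8, length(timepoints)),
    LET = rep(-7, length(timepoints)),
    FF  = rep(-6, length(timepoints))
  )
  colnames(amp) <- timepoints
  if ("T2" %in% timepoints) amp["LET", "T2"] <- -8 # letter enhancement at T2
  amp
}

#' Zero-mean bilateral occipito-temporal topography
#'
#' Gaussian-on-sphere patterns centred on the cluster centroids with a
#' compensating anterior lobe; the map is mean-centred across channels
#' (consistent with the average reference) and scaled so that its mean over
#' the cluster channels equals 1, so a condition amplitude of a uV yields a
#' cluster mean amplitude of a uV in the noiseless forward model.
#'
#' @param montage An `eeg_montage`.
#' @param clusters Cluster names the pattern is centred on.
#' @param sigma Angular width (radians) of the Gaussian lobes.
#' @param anterior_weight Relative amplitude of the anterior counter-lobe.
#' @return Named numeric vector over montage channels; zero mean.
#' @export
component_topography <- function(montage, clusters = c("LOT", "ROT"),
                                 sigma = 0.6, anterior_weight = 0.8) {
  pos <- montage$positions
  ang <- function(dir) acos(pmin(1, pmax(-1, pos %*% dir)))
  w <- rep(0, nrow(pos))
  for (cl in clusters) {
    w <- w + exp(-ang(cluster_centroid(montage, cl))^2 / (2 * sigma^2))
  }
  w <- w - anterior_weight * exp(-ang(.front_dir)^2 / (2 * sigma^2))
  w <- w - mean(w)
  ch <- unlist(montage$clusters[clusters], use.names = FALSE)
  w <- w / mean(w[montage$channels %in% ch])
  stats::setNames(as.numeric(w), montage$channels)
}

gaussian_kernel <- function(times_ms, latency_ms, width_ms) {
  s <- width_ms / (2 * sqrt(2 * log(2))) # FWHM -> sd
  exp(-(times_ms - latency_ms)^2 / (2 * s^2))
}

#' Longitudinal cohort specification
#'
#' Defaults mirror the study structure the package emulates: five timepoints
#' (kindergarten to fifth grade) with 23/22/27/27/42 children contributing at
#' T1..T5, drawn from a pool of 62 children who each attend between one and
#' five visits.
#'
#' @param timepoints Ordered labels.
#' @param group_size Per-timepoint number of participants (same length).
#' @param n_subjects Size of the longitudinal pool.
#' @param visit_pattern Optional logical matrix (subjects x timepoints)
#'   overriding the sampled pattern; column sums must equal `group_size`.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(timepoints = paste0("T", 1:5),
                        group_size = c(23, 22, 27, 27, 42),
                        n_subjects = 62L,
                        visit_pattern = NULL) {
  stopifnot(
    length(group_size) == length(timepoints), all(group_size >= 1),
    all(group_size <= n_subjects)
  )
  if (!is.null(visit_pattern)) {
    stopifnot(
      is.matrix(visit_pattern), nrow(visit_pattern) == n_subjects,
      ncol(visit_pattern) == length(timepoints),
      all(colSums(visit_pattern) == group_size),
      all(rowSums(visit_pattern) >= 1)
    )
  }
  structure(
    list(
      timepoints = timepoints,
      group_size = stats::setNames(as.integer(group_size), timepoints),
      n_subjects = as.integer(n_subjects),
      visit_pattern = visit_pattern
    ),
    class = "cohort_spec"
  )
}

#' Draw a visit pattern consistent with the per-timepoint group sizes
#'
#' Samples, per timepoint, which subjects attend (without replacement), and
#' redraws until every subject in the pool attends at least one visit, so the
#' per-timepoint counts always equal the configured group sizes exactly.
#'
#' @param cohort A [cohort_spec()].
#' @param seed Integer seed.
#' @return Logical matrix subjects x timepoints.
#' @export
draw_visit_pattern <- function(cohort, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_spec"))
  if (!is.null(cohort$visit_pattern)) {
    return(cohort$visit_pattern)
  }
  with_seed(seed, {
    repeat {
      vp <- vapply(cohort$group_size, function(g) {
        attend <- rep(FALSE, cohort$n_subjects)
        attend[sample.int(cohort$n_subjects, g)] <- TRUE
        attend
      }, logical(cohort$n_subjects))
      if (all(rowSums(vp) >= 1)) break
    }
    rownames(vp) <- sprintf("S%02d", seq_len(cohort$n_subjects))
    colnames(vp) <- cohort$timepoints
    vp
  })
}
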