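#' Simulate one continuous multichannel recording
#'
#' Forward model for one subject-visit: for every non-target event the N1
#' temporal kernel (Gaussian, peak at the timepoint's latency) times the
#' zero-mean spatial topography times the condition amplitude (plus the
#' subject's shared amplitude offset) is added to a background of 1/f noise
#' and white sensor noise; an earlier positive component is injected with a
#' condition-independent amplitude. A configurable fraction of epochs carries
#' boxcar artifact deflections exceeding the rejection threshold on a random
#' channel subset, and frontal low-frequency blink transients occur at their
#' own rate.
#'
#' @param montage An `eeg_montage`.
#' @param events Event tibble from [make_design()].
#' @param truth A [ground_truth()].
#' @param timepoint Timepoint label (selects latency and amplitudes).
#' @param seed Integer seed; recordings are reproducible.
#' @param rate Native sampling rate (Hz), default 1000; set 500 to generate
#'   directly on the analysis grid.
#' @param subject_offset_uv Subject-level amplitude offset (uV), shared across
#'   this subject's visits by [simulate_cohort()].
#' @param condition_offset_uv Optional named vector of per-condition amplitude
#'   offsets (uV), e.g. a subject-specific deviation of the digit response.
#' @param subject Subject id stored in the recording metadata.
#' @param pad_ms Silence appended after the last stimulus offset.
#' @return An `eeg_recording`: list with `signal` (channels x samples matrix,
#'   uV), `rate`, `montage`, `reference_state`, and `meta`.
#' @export
simulate_subject <- function(montage, events, truth, timepoint, seed = 1L,
                             rate = 1000, subject_offset_uv = 0,
                             condition_offset_uv = NULL,
                             subject = "S01", pad_ms = 1000) {
  stopifnot(inherits(montage, "eeg_montage"), inherits(truth, "ground_truth"))
  if (!timepoint %in% truth$timepoints) {
    stop("unknown timepoint: ", timepoint)
  }
  dur_ms <- max(events$onset_ms) + 613 + pad_ms
  n_samp <- ceiling(dur_ms * rate / 1000)
  if (max(events$onset_ms) * rate / 1000 + 1 > n_samp) {
    stop("events do not fit within the recording length")
  }
  n_ch <- length(montage$channels)

  with_seed(seed, {
    sig <- matrix(0, n_ch, n_samp)
    if (truth$pink_noise_sd_uv > 0) {
      sig <- sig + truth$pink_noise_sd_uv *
        pink_noise(n_ch, n_samp, truth$noise_spectrum_exponent)
    }
    if (truth$sensor_noise_sd_uv > 0) {
      sig <- sig + truth$sensor_noise_sd_uv * matrix(rnorm(n_ch * n_samp), n_ch)
    }

    lat <- truth$n1_latency_ms[[timepoint]]
    span_ms <- 3 * truth$n1_width_ms
    ev <- events[!events$is_target, , drop = FALSE]
    front_ch <- order(montage$positions %*% .front_dir, decreasing = TRUE)[1:8]

    for (i in seq_len(nrow(ev))) {
      onset_idx <- ceiling(ev$onset_ms[i] * rate / 1000) + 1L
      k0 <- floor(-100 * rate / 1000)
      k1 <- ceiling((lat + span_ms) * rate / 1000)
      idx <- (onset_idx + k0):(onset_idx + k1)
      keep <- idx >= 1 & idx <= n_samp
      idx <- idx[keep]
      t_rel <- ((idx - onset_idx) / rate) * 1000
      cond_off <- 0
      if (!is.null(condition_offset_uv) &&
        ev$condition[i] %in% names(condition_offset_uv)) {
        cond_off <- condition_offset_uv[[ev$condition[i]]]
      }
      amp <- truth$condition_amplitude_uv[ev$condition[i], timepoint] +
        subject_offset_uv + cond_off
      kern <- amp * gaussian_kernel(t_rel, lat, truth$n1_width_ms) +
        truth$p1$amplitude_uv *
          gaussian_kernel(t_rel, truth$p1$latency_ms, truth$p1$width_ms)
      sig[, idx] <- sig[, idx] + outer(truth$topography, kern)

      if (runif(1) < truth$artifact_epoch_rate) {
        ch <- sample.int(n_ch, max(1L, round(0.1 * n_ch)))
        a0 <- idx[1] + sample.int(max(1L, length(idx) - round(0.1 * rate)), 1)
        a1 <- min(a0 + round(0.1 * rate), n_samp)
        sig[ch, a0:a1] <- sig[ch, a0:a1] +
          sample(c(-1, 1), 1) * runif(1, 280, 400)
      }
      if (runif(1) < truth$blink_rate) {
        b0 <- idx[1] + sample.int(max(1L, length(idx) - round(0.3 * rate)), 1)
        bidx <- b0:min(b0 + round(0.3 * rate), n_samp)
        bk <- 260 * sin(pi * seq_along(bidx) / length(bidx))^2
        sig[front_ch, bidx] <- sig[front_ch, bidx] +
          matrix(bk, length(front_ch), length(bidx), byrow = TRUE)
      }
    }
    rownames(sig) <- montage$channels
    new_recording(sig, rate, montage, "recording-reference",
      meta = list(subject = subject, timepoint = timepoint, seed = seed)
    )
  })
}

new_recording <- function(signal, rate, montage, reference_state, meta = list()) {
  stopifnot(
    is.matrix(signal), nrow(signal) == length(montage$channels),
    rate > 0, all(is.finite(signal))
  )
  structure(
    list(
      signal = signal, rate = rate, montage = montage,
      reference_state = reference_state, meta = meta
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), reference: %s\n",
    nrow(x$signal), ncol(x$signal), x$rate, ncol(x$signal) / x$rate,
    x$reference_state
  ))
  invisible(x)
}

# 1/f^alpha noise per channel via spectral shaping of white noise,
# standardized to unit variance per channel.
pink_noise <- function(n_ch, n_samp, alpha = 1) {
  freqs <- seq_len(floor(n_samp / 2))
  scale <- freqs^(-alpha / 2)
  out <- matrix(0, n_ch, n_samp)
  for (ch in seq_len(n_ch)) {
    w <- stats::fft(rnorm(n_samp))
    shape <- numeric(n_samp)
    shape[1] <- 0 # no DC
    shape[1 + freqs] <- scale
    if (n_samp > 1) {
      neg <- seq(n_samp, by = -1, length.out = length(freqs))
      shape[neg] <- pmax(shape[neg], scale)
    }
    x <- Re(stats::fft(w * shape, inverse = TRUE)) / n_samp
    out[ch, ] <- x / sd(x)
  }
  out
}
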