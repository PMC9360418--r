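#' Zero-phase band-pass + notch filtering and downsampling
#'
#' Applies, per channel, a zero-phase (forward-backward) Butterworth cascade:
#' order-2 high-pass at `low_hz`, order-2 low-pass at `high_hz`, and an
#' order-2 band-stop of width `notch_width_hz` around `notch_hz`; then
#' decimates to `target_rate`. The low-pass doubles as the anti-aliasing
#' filter, so `high_hz` must lie below the target Nyquist. Channel order is
#' preserved.
#'
#' @param rec An `eeg_recording`.
#' @param low_hz,high_hz Band edges (Hz), defaults 0.1 and 30.
#' @param notch_hz Mains frequency (Hz), default 50; `NULL` disables the notch.
#' @param target_rate Output rate (Hz); must divide the input rate.
#' @param notch_width_hz Half-width of the band-stop (Hz), default 2.
#' @return Filtered, resampled `eeg_recording`.
#' @export
bandpass_notch_downsample <- function(rec, low_hz = 0.1, high_hz = 30,
                                      notch_hz = 50, target_rate = 500,
                                      notch_width_hz = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$rate
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2 &&
    high_hz < target_rate / 2)) {
    stop(
      "invalid band edges: need 0 < low < high < Nyquist of both the ",
      "input rate (", fs / 2, " Hz) and the target rate (", target_rate / 2, " Hz)"
    )
  }
  filters <- list(
    signal::butter(2, low_hz / (fs / 2), type = "high"),
    signal::butter(2, high_hz / (fs / 2), type = "low")
  )
  if (!is.null(notch_hz)) {
    if (notch_hz + notch_width_hz >= fs / 2) stop("notch exceeds Nyquist")
    filters <- c(filters, list(signal::butter(
      2, c(notch_hz - notch_width_hz, notch_hz + notch_width_hz) / (fs / 2),
      type = "stop"
    )))
  }
  sig <- rec$signal
  for (ch in seq_len(nrow(sig))) {
    x <- sig[ch, ]
    for (f in filters) x <- signal::filtfilt(f, x)
    sig[ch, ] <- x
  }
  if (target_rate != fs) {
    if (fs %% target_rate != 0) {
      stop("target_rate must divide the recording rate (", fs, " Hz)")
    }
    sig <- sig[, seq(1, ncol(sig), by = fs / target_rate), drop = FALSE]
  }
  new_recording(sig, target_rate, rec$montage, rec$reference_state, rec$meta)
}

#' Topographic interpolation of bad channels
#'
#' Replaces each bad channel by the inverse-distance-weighted mean of its `k`
#' nearest good neighbors on the sphere (chord distance). All other channels
#' are untouched.
#'
#' @param rec An `eeg_recording`.
#' @param bad Character vector of channel labels to interpolate.
#' @param k Number of neighbors, default 4.
#' @param max_bad Cap on `length(bad)` (quality-control convention), default 5.
#' @return `eeg_recording` with bad channels replaced.
#' @export
interpolate_channels <- function(rec, bad, k = 4, max_bad = 5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(bad) == 0) {
    return(rec)
  }
  ch <- rec$montage$channels
  if (!all(bad %in% ch)) {
    stop("unknown channels: ", paste(setdiff(bad, ch), collapse = ", "))
  }
  if (length(bad) > max_bad) {
    stop("more than ", max_bad, " channels marked bad (", length(bad), ")")
  }
  good <- setdiff(ch, bad)
  if (length(good) == 0) stop("all channels are bad; nothing to interpolate from")
  pos <- rec$montage$positions
  sig <- rec$signal
  for (b in bad) {
    d <- sqrt(colSums((t(pos[good, , drop = FALSE]) - pos[b, ])^2))
    nb <- good[order(d)[seq_len(min(k, length(good)))]]
    w <- 1 / d[order(d)[seq_len(min(k, length(good)))]]
    # rec$signal, not sig: interpolate from original values only
    sig[b, ] <- as.numeric(w %*% rec$signal[nb, , drop = FALSE]) / sum(w)
  }
  new_recording(sig, rec$rate, rec$montage, rec$reference_state, rec$meta)
}

#' Common average reference
#'
#' Subtracts, at every sample, the mean over all channels; afterwards the
#' channel mean is zero at each sample (a projection: applying it twice
#' equals applying it once).
#'
#' @param rec An `eeg_recording` with at least 2 channels.
#' @return Average-referenced `eeg_recording` (`reference_state = "average"`).
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"), nrow(rec$signal) >= 2)
  sig <- sweep(rec$signal, 2, colMeans(rec$signal))
  new_recording(sig, rec$rate, rec$montage, "average", rec$meta)
}
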