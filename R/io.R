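#' Write / read a continuous recording as a plain-text array container
#'
#' The container is a tab-separated channels-in-columns matrix of physical
#' values (uV) with a JSON sidecar (`<path>.json`) carrying the sampling rate,
#' channel order, and reference state, so a recording round-trips without
#' loss of metadata. Montage geometry travels separately via
#' [write_montage()].
#'
#' @param rec An `eeg_recording`.
#' @param path Data file path; the sidecar is written next to it.
#' @param digits Significant digits kept in the text representation.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns an `eeg_recording` (montage positions are rebuilt from
#'   `montage`, or a montage read from the sidecar's `montage_path` if set).
#' @export
write_recording <- function(rec, path, digits = 6) {
  stopifnot(inherits(rec, "eeg_recording"))
  m <- t(rec$signal)
  colnames(m) <- rec$montage$channels
  utils::write.table(signif(m, digits), path,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  side <- list(
    rate = rec$rate,
    channels = rec$montage$channels,
    reference_state = rec$reference_state,
    units = "uV",
    meta = rec$meta
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_recording
#' @param montage Montage to attach on read (channel order must match).
#' @export
read_recording <- function(path, montage) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE))
  stopifnot(identical(colnames(m), side$channels))
  if (!identical(montage$channels, side$channels)) {
    stop("montage channel order does not match the recording sidecar")
  }
  sig <- t(m)
  rownames(sig) <- side$channels
  new_recording(sig, side$rate, montage, side$reference_state,
    meta = as.list(side$meta)
  )
}

#' Write / read an event table (tab-separated)
#'
#' @param events Event tibble from [make_design()].
#' @param path File path.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE))
}
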