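# Shared small fixtures, built in code. 24 channels is the smallest montage
# exercised routinely: both 9-channel clusters plus 6 filler electrodes.

tiny_montage <- function(n = 24) make_montage(n)

quiet_truth <- function(montage = tiny_montage(), ...) {
  args <- utils::modifyList(
    list(
      pink_noise_sd_uv = 0, sensor_noise_sd_uv = 0,
      artifact_epoch_rate = 0, blink_rate = 0
    ),
    list(...)
  )
  do.call(ground_truth, c(list(montage), args))
}

tiny_design <- function(blocks = 1, items = 8, targets = 1) {
  design_spec(
    blocks_per_condition = blocks, items_per_block = items,
    targets_per_condition = targets
  )
}

# a flat recording with given constant value per channel
const_recording <- function(values, n_samp = 100, rate = 500,
                            montage = tiny_montage()) {
  sig <- matrix(values, length(values), n_samp)
  rownames(sig) <- montage$channels[seq_along(values)]
  sub <- montage
  sub$channels <- montage$channels[seq_along(values)]
  sub$positions <- montage$positions[seq_along(values), , drop = FALSE]
  sub$clusters <- lapply(montage$clusters, function(ch) intersect(ch, sub$channels))
  n1sense:::new_recording(sig, rate, sub, "recording-reference")
}

# epoch_set built directly from arrays (trials x channels x samples)
manual_epochs <- function(arrays, times_ms, rate = 500, montage = tiny_montage(),
                          subject = "S01", timepoint = "T1") {
  structure(
    list(
      epochs = arrays, times_ms = times_ms, rate = rate, montage = montage,
      subject = subject, timepoint = timepoint, baseline = FALSE,
      rejection_log = tibble::tibble(
        condition = character(), epoch = integer(), reason = character()
      )
    ),
    class = "epoch_set"
  )
}

# map_set built directly from an array subject x condition x channel x sample
manual_map_set <- function(maps, normalized = TRUE) {
  structure(
    list(
      maps = maps,
      subjects = dimnames(maps)[[1]] %||% paste0("S", seq_len(dim(maps)[1])),
      conditions = dimnames(maps)[[2]] %||% LETTERS[seq_len(dim(maps)[2])],
      times_ms = seq_len(dim(maps)[4]),
      normalized = normalized
    ),
    class = "map_set"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
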