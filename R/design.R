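#' Specify the single-character target-detection design
#'
#' The default reproduces the task structure used throughout the package:
#' three visual character conditions (digits DIG, letters LET, false fonts FF)
#' presented in separate parts, four blocks of 15 items per condition with six
#' target trials per condition (hence 54 non-target trials entering the ERPs),
#' 613 ms stimulus duration and an interstimulus interval of 331 or 695 ms,
#' with 6 or 12 s fixation gaps between blocks.
#'
#' @param conditions Character vector of condition labels.
#' @param blocks_per_condition,items_per_block,targets_per_condition Counts.
#' @param stimulus_duration_ms Stimulus duration (ms).
#' @param isi_choices_ms Possible interstimulus intervals (ms).
#' @param fixation_gaps_ms Possible inter-block fixation gaps (ms).
#' @return A `design_spec` list.
#' @export
design_spec <- function(conditions = c("DIG", "LET", "FF"),
                        blocks_per_condition = 4L,
                        items_per_block = 15L,
                        targets_per_condition = 6L,
                        stimulus_duration_ms = 613,
                        isi_choices_ms = c(331, 695),
                        fixation_gaps_ms = c(6000, 12000)) {
  stopifnot(
    length(conditions) >= 1, !anyDuplicated(conditions),
    blocks_per_condition >= 1, items_per_block >= 1,
    targets_per_condition >= 0,
    targets_per_condition <= blocks_per_condition * items_per_block,
    stimulus_duration_ms > 0, all(isi_choices_ms > 0), all(fixation_gaps_ms > 0)
  )
  structure(
    list(
      conditions = conditions,
      blocks_per_condition = as.integer(blocks_per_condition),
      items_per_block = as.integer(items_per_block),
      targets_per_condition = as.integer(targets_per_condition),
      stimulus_duration_ms = stimulus_duration_ms,
      isi_choices_ms = isi_choices_ms,
      fixation_gaps_ms = fixation_gaps_ms
    ),
    class = "design_spec"
  )
}

#' Generate a pseudorandomized event table for one session
#'
#' Conditions are presented in separate parts; within each condition, items are
#' laid out block by block with target positions pseudorandomized across the
#' whole condition, and each onset follows the previous stimulus by its
#' duration plus a randomly sampled interstimulus interval. Blocks (and
#' condition parts) are separated by fixation gaps.
#'
#' @param spec A [design_spec()].
#' @param seed Integer seed; the table is reproducible.
#' @param t0_ms Onset of the first stimulus (ms into the recording).
#' @return Tibble with columns `onset_ms`, `condition`, `is_target`, `block`
#'   (within condition), `part` (condition part index).
#' @examples
#' ev <- make_design(design_spec(), seed = 1)
#' table(ev$condition, ev$is_target)
#' @export
make_design <- function(spec = design_spec(), seed = 1L, t0_ms = 2000) {
  stopifnot(inherits(spec, "design_spec"))
  with_seed(seed, {
    n_items <- spec$blocks_per_condition * spec$items_per_block
    parts <- sample(spec$conditions) # pseudorandom part order
    cursor <- t0_ms
    rows <- vector("list", length(parts))
    for (pi in seq_along(parts)) {
      cond <- parts[pi]
      target_pos <- sample.int(n_items, spec$targets_per_condition)
      onset <- numeric(n_items)
      block <- integer(n_items)
      item <- 0L
      for (b in seq_len(spec$blocks_per_condition)) {
        for (k in seq_len(spec$items_per_block)) {
          item <- item + 1L
          onset[item] <- cursor
          block[item] <- b
          cursor <- cursor + spec$stimulus_duration_ms +
            sample1(spec$isi_choices_ms)
        }
        cursor <- cursor + sample1(spec$fixation_gaps_ms)
      }
      rows[[pi]] <- tibble::tibble(
        onset_ms = onset,
        condition = cond,
        is_target = seq_len(n_items) %in% target_pos,
        block = block,
        part = pi
      )
    }
    dplyr::bind_rows(rows)
  })
}
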