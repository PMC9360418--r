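#' Strength-normalize a scalp map
#'
#' Divides a map (or each column of a channels x samples matrix) by its
#' global field power, so comparisons reflect the spatial configuration of the
#' field irrespective of its strength. Maps with zero GFP are returned
#' unchanged and flagged in the `zero_gfp` attribute.
#'
#' @param map Numeric vector (one map) or channels x samples matrix.
#' @return Normalized map(s); unit GFP wherever the input GFP was nonzero.
#' @export
normalize_map <- function(map) {
  vec <- is.null(dim(map))
  m <- if (vec) matrix(map, ncol = 1) else map
  stopifnot(nrow(m) >= 2)
  g <- gfp(m)
  g <- as.numeric(g)
  zero <- g == 0
  scale <- ifelse(zero, 1, g)
  out <- sweep(m, 2, scale, "/")
  if (vec) out <- stats::setNames(as.numeric(out), names(map))
  attr(out, "zero_gfp") <- which(zero)
  out
}

#' Assemble a window-restricted map set for topographic testing
#'
#' Collects, for every subject and condition, the ERP maps inside the N1
#' window and (by default) strength-normalizes each subject-condition map at
#' each sample.
#'
#' @param erps List of `erp_average` for one timepoint (all subjects must
#'   contribute every condition).
#' @param w An `n1_window`.
#' @param normalize Normalize each map to unit GFP? Default `TRUE`.
#' @return A `map_set`: array `maps` (subject x condition x channel x sample),
#'   plus `conditions`, `subjects`, `times_ms`, `normalized`.
#' @export
map_set <- function(erps, w, normalize = TRUE) {
  subjects <- sort(unique(vapply(erps, function(e) e$subject, "")))
  conditions <- sort(unique(vapply(erps, function(e) e$condition, "")))
  t_all <- erps[[1]]$times_ms
  cols <- which(t_all >= w$start_ms - 1e-9 & t_all <= w$end_ms + 1e-9)
  n_ch <- nrow(erps[[1]]$waveform)
  maps <- array(NA_real_, c(length(subjects), length(conditions), n_ch, length(cols)),
    dimnames = list(subjects, conditions, rownames(erps[[1]]$waveform), NULL)
  )
  for (e in erps) {
    m <- e$waveform[, cols, drop = FALSE]
    if (normalize) m <- normalize_map(m)
    maps[e$subject, e$condition, , ] <- m
  }
  if (anyNA(maps)) stop("map_set requires every subject x condition cell")
  structure(
    list(
      maps = maps, subjects = subjects, conditions = conditions,
      times_ms = t_all[cols], normalized = normalize
    ),
    class = "map_set"
  )
}

#' Generalized topographic dissimilarity statistic
#'
#' For condition grand-average maps M_c (mean over subjects) and their mean
#' M-bar, the statistic is s = sqrt( (1/K) * sum_c GFP(M_c - M-bar)^2 ): zero
#' iff all condition grand maps are identical, and invariant to per-subject
#' positive rescaling when maps are normalized first.
#'
#' @param maps Array subject x condition x channel (one sample), or a list of
#'   per-condition matrices subject x channel.
#' @return Scalar statistic (>= 0).
#' @export
tanova_statistic <- function(maps) {
  if (is.list(maps)) {
    grand <- t(vapply(maps, colMeans, numeric(ncol(maps[[1]]))))
  } else {
    stopifnot(length(dim(maps)) == 3, dim(maps)[1] >= 1, dim(maps)[2] >= 2)
    grand <- apply(maps, c(2, 3), mean) # condition x channel
  }
  if (any(!is.finite(grand))) stop("condition with no subjects or non-finite maps")
  center <- colMeans(grand)
  dev <- sweep(grand, 2, center)
  sqrt(mean(apply(dev, 1, function(r) gfp(r)^2)))
}

#' TANOVA: within-subject permutation test of topographic differences
#'
#' At each sample of the map set, compares the observed generalized
#' dissimilarity between condition grand-average maps against a null built by
#' independently permuting condition labels within each subject (paired
#' design). P-values use the add-one convention p = (1 + #\{s_perm >=
#' s_obs\}) / (1 + B), so the smallest attainable p is 1/(B+1).
#'
#' @param ms A [map_set()] (normalized in the standard analysis).
#' @param n_permutations Number of label permutations, default 5000.
#' @param seed Integer seed; results are reproducible.
#' @return A `tanova_result` tibble: `time_ms`, `statistic`, `p`; attributes
#'   `n_permutations`, `seed`, `conditions`, `n_subjects`.
#' @export
tanova_permutation_test <- function(ms, n_permutations = 5000, seed = 1L) {
  stopifnot(inherits(ms, "map_set"))
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  dm <- dim(ms$maps)
  n_sub <- dm[1]
  n_cond <- dm[2]
  n_ch <- dm[3]
  n_t <- dm[4]
  stopifnot(n_sub >= 2, n_cond >= 2)

  obs <- vapply(
    seq_len(n_t),
    function(ti) tanova_statistic(ms$maps[, , , ti, drop = TRUE]),
    numeric(1)
  )
  exceed <- with_seed(seed, {
    if (n_cond == 2) {
      # Within-subject label swap == sign flip of the per-subject difference
      # map; the statistic reduces to GFP(mean difference)/2. Vectorized over
      # permutations and samples via one matrix product.
      d <- ms$maps[, 1, , , drop = FALSE] - ms$maps[, 2, , , drop = FALSE]
      dim(d) <- c(n_sub, n_ch * n_t)
      signs <- matrix(sample(c(-1, 1), n_permutations * n_sub, replace = TRUE),
        n_permutations, n_sub
      )
      dbar <- (signs %*% d) / n_sub # B x (ch*t)
      ex <- integer(n_t)
      for (ti in seq_len(n_t)) {
        block <- dbar[, (ti - 1) * n_ch + seq_len(n_ch), drop = FALSE]
        mu <- rowMeans(block)
        s_perm <- sqrt(rowMeans((block - mu)^2)) / 2
        ex[ti] <- sum(s_perm >= obs[ti] - 1e-15)
      }
      ex
    } else {
      ex <- integer(n_t)
      for (b in seq_len(n_permutations)) {
        perm <- vapply(seq_len(n_sub), function(s) sample.int(n_cond), integer(n_cond))
        shuffled <- ms$maps
        for (s in seq_len(n_sub)) shuffled[s, , , ] <- ms$maps[s, perm[, s], , ]
        for (ti in seq_len(n_t)) {
          sl <- shuffled[, , , ti]
          dim(sl) <- c(n_sub, n_cond, n_ch)
          if (tanova_statistic(sl) >= obs[ti] - 1e-15) ex[ti] <- ex[ti] + 1L
        }
      }
      ex
    }
  })
  out <- tibble::tibble(
    time_ms = ms$times_ms,
    statistic = obs,
    p = (1 + exceed) / (1 + n_permutations)
  )
  attr(out, "n_permutations") <- n_permutations
  attr(out, "seed") <- seed
  attr(out, "conditions") <- ms$conditions
  attr(out, "n_subjects") <- n_sub
  class(out) <- c("tanova_result", class(out))
  out
}

#' Electrode-wise one-sample t map
#'
#' One-sample t statistics against zero, per electrode, on per-subject
#' difference maps (typically window-averaged condition differences).
#' Electrodes with zero variance across subjects get `t = +/-Inf` and are
#' flagged.
#'
#' @param diffs Matrix subjects x channels of difference values (uV).
#' @return Tibble `channel`, `mean_uv`, `t`, `df`, `p`, `zero_variance`.
#' @export
electrode_t_map <- function(diffs) {
  stopifnot(is.matrix(diffs), nrow(diffs) >= 2)
  n <- nrow(diffs)
  mu <- colMeans(diffs)
  s <- apply(diffs, 2, sd)
  zero <- s == 0
  tval <- ifelse(zero,
    ifelse(mu == 0, 0, sign(mu) * Inf),
    mu / (s / sqrt(n))
  )
  tibble::tibble(
    channel = colnames(diffs) %||% paste0("ch", seq_along(mu)),
    mean_uv = mu,
    t = tval,
    df = n - 1L,
    p = ifelse(is.infinite(tval), 0, 2 * pt(-abs(tval), n - 1)),
    zero_variance = zero
  )
}
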