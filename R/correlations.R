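#' Spearman rank correlation
#'
#' Rank correlation with midranks for ties. The p-value comes from exact
#' enumeration of all rank permutations for n <= 9 (two-sided, by absolute
#' value) and from the t approximation t = rho * sqrt((n-2)/(1-rho^2))
#' otherwise. Zero rank variance in either variable yields `rho = NA` with
#' `defined = FALSE`.
#'
#' @param x,y Paired numeric vectors, n >= 4, finite values.
#' @return One-row tibble `rho`, `p`, `n`, `defined`.
#' @examples
#' spearman(1:6, c(2, 4, 3, 7, 9, 8))
#' @export
spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 paired finite observations")
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(tibble::tibble(rho = NA_real_, p = NA_real_, n = n, defined = FALSE))
  }
  rho <- stats::cor(rx, ry)
  p <- if (n <= 9) {
    perms <- all_permutations(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rho_perm <- as.numeric(matrix(ryc[perms], nrow(perms)) %*% rxc) / denom
    mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    tval <- rho * sqrt((n - 2) / max(1e-300, 1 - rho^2))
    2 * pt(-abs(tval), n - 2)
  }
  tibble::tibble(rho = rho, p = min(1, p), n = n, defined = TRUE)
}

# all permutations of 1:n as a matrix (n! rows); n <= 9 only
all_permutations <- function(n) {
  if (n == 1) {
    return(matrix(1L, 1, 1))
  }
  sub <- all_permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    left <- sub[, seq_len(pos - 1), drop = FALSE]
    right <- if (pos < n) sub[, pos:(n - 1), drop = FALSE] else sub[, integer(0), drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- cbind(left, n, right)
    r <- r + nrow(sub)
  }
  out
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values (monotone, capped at 1), same order as input.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Default 36-cell brain-behavior correlation grid
#'
#' 2 hemispheres x 2 contrasts x 9 behavior/timepoint combinations: number
#' knowledge at T1, concurrent arithmetic (percentile and raw) and reading at
#' T4 and T5, and the two prediction cells pairing T1 neural sensitivity with
#' the latest available arithmetic and reading scores.
#'
#' @return Tibble with columns `neural_timepoint`, `hemisphere`, `contrast`,
#'   `measure`, `behavior_timepoint` (`"latest"` = T5 score, else T4).
#' @export
default_correlation_grid <- function() {
  combos <- tibble::tribble(
    ~neural_timepoint, ~measure, ~behavior_timepoint,
    "T1", "number_knowledge", "T1",
    "T4", "arithmetic_pr", "T4",
    "T4", "arithmetic_raw", "T4",
    "T4", "reading_pr", "T4",
    "T5", "arithmetic_pr", "T5",
    "T5", "arithmetic_raw", "T5",
    "T5", "reading_pr", "T5",
    "T1", "arithmetic_pr", "latest",
    "T1", "reading_pr", "latest"
  )
  tidyr::expand_grid(
    combos,
    hemisphere = c("LOT", "ROT"),
    contrast = c("coarse", "fine")
  ) %>%
    dplyr::select(
      "neural_timepoint", "hemisphere", "contrast", "measure",
      "behavior_timepoint"
    )
}

#' Brain-behavior Spearman correlation grid with FDR control
#'
#' Joins neural sensitivity differences with behavioral scores on subject
#' (and the configured timepoints), computes the Spearman correlation for
#' every grid cell, and applies Benjamini-Hochberg FDR correction across the
#' whole grid. Each cell is computed both on all paired observations and
#' after excluding neural-measure outliers (|value - median| > `mad_k` * MAD
#' within the cell); both variants are FDR-corrected across the grid
#' separately.
#'
#' @param differences Tibble from [sensitivity_differences()].
#' @param behavior Tibble `subject`, `timepoint`, `measure`, `score`.
#' @param grid Grid specification, default [default_correlation_grid()].
#' @param min_n Minimum paired n per cell; smaller cells are flagged
#'   `insufficient` and excluded from the FDR family.
#' @param mad_k MAD multiplier for the neural outlier rule, default 3.
#' @return A `correlation_grid` tibble: the grid columns plus `n`, `rho`,
#'   `p`, `p_fdr`, `n_excluded`, `rho_excl`, `p_excl`, `p_fdr_excl`,
#'   `insufficient`.
#' @export
correlation_grid <- function(differences, behavior,
                             grid = default_correlation_grid(),
                             min_n = 5, mad_k = 3) {
  resolve_behavior <- function(measure, behavior_timepoint) {
    b <- dplyr::filter(behavior, .data$measure == !!measure)
    if (behavior_timepoint == "latest") {
      b %>%
        dplyr::group_by(.data$subject) %>%
        dplyr::slice_max(.data$timepoint, n = 1, with_ties = FALSE) %>%
        dplyr::ungroup()
    } else {
      dplyr::filter(b, .data$timepoint == !!behavior_timepoint)
    }
  }
  rows <- purrr::pmap(grid, function(neural_timepoint, hemisphere, contrast,
                                     measure, behavior_timepoint) {
    nv <- dplyr::filter(
      differences,
      .data$timepoint == !!neural_timepoint,
      .data$hemisphere == !!hemisphere,
      .data$contrast == !!contrast
    )
    bv <- resolve_behavior(measure, behavior_timepoint)
    j <- dplyr::inner_join(
      dplyr::select(nv, "subject", "difference_uv"),
      dplyr::select(bv, "subject", "score"),
      by = "subject"
    )
    base <- tibble::tibble(
      neural_timepoint = neural_timepoint, hemisphere = hemisphere,
      contrast = contrast, measure = measure,
      behavior_timepoint = behavior_timepoint, n = nrow(j)
    )
    if (nrow(j) < min_n) {
      return(dplyr::mutate(base,
        rho = NA_real_, p = NA_real_, n_excluded = NA_integer_,
        rho_excl = NA_real_, p_excl = NA_real_, insufficient = TRUE
      ))
    }
    s_all <- spearman(j$difference_uv, j$score)
    md <- stats::median(j$difference_uv)
    madv <- stats::mad(j$difference_uv)
    keep <- abs(j$difference_uv - md) <= mad_k * madv
    s_excl <- if (sum(keep) >= min_n) {
      spearman(j$difference_uv[keep], j$score[keep])
    } else {
      tibble::tibble(rho = NA_real_, p = NA_real_)
    }
    dplyr::mutate(base,
      rho = s_all$rho, p = s_all$p,
      n_excluded = sum(!keep),
      rho_excl = s_excl$rho, p_excl = s_excl$p,
      insufficient = FALSE
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_fdr <- NA_real_
  out$p_fdr[!out$insufficient] <- bh_fdr(out$p[!out$insufficient])
  out$p_fdr_excl <- NA_real_
  ok <- !out$insufficient & !is.na(out$p_excl)
  out$p_fdr_excl[ok] <- bh_fdr(out$p_excl[ok])
  out <- dplyr::relocate(out, "p_fdr", .after = "p")
  class(out) <- c("correlation_grid", class(out))
  out
}
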