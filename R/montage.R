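#' Occipito-temporal electrode clusters of the 128-channel geodesic net
#'
#' Channel labels of the left (LOT) and right (ROT) occipito-temporal clusters
#' used for N1 mean-amplitude extraction, and the four cheek channels that are
#' removed from the 128-channel net before analysis.
#'
#' @format Named list of character vectors.
#' @export
ot_clusters <- list(
  LOT = c("E57", "E58", "E65", "E70", "E63", "E64", "E69", "E68", "E73"),
  ROT = c("E83", "E90", "E96", "E100", "E89", "E95", "E99", "E88", "E94")
)

cheek_channels <- c("E43", "E48", "E119", "E120")

# Unit directions used to anchor the synthetic layout: left/right
# occipito-temporal centroids and a frontal direction for blink/compensation
# topographies. Coordinates: x right, y anterior, z superior.
.lot_dir <- c(-0.60, -0.65, -0.15) / sqrt(sum(c(-0.60, -0.65, -0.15)^2))
.rot_dir <- c(0.60, -0.65, -0.15) / sqrt(sum(c(0.60, -0.65, -0.15)^2))
.front_dir <- c(0, 0.90, 0.44) / sqrt(sum(c(0, 0.90, 0.44)^2))

#' Build a geodesic-style EEG montage with occipito-temporal clusters
#'
#' Lays `n_channels` electrodes on the unit sphere as a mirror-symmetric
#' Fibonacci-style lattice (the right half is generated and reflected across
#' the midsagittal plane, as in real sensor nets) and assigns labels so that
#' the nine left and nine right occipito-temporal cluster channels
#' ([ot_clusters]) sit around the left/right posterior-inferior centroids,
#' with the left cluster the exact mirror image of the right one.
#' With the default `n_channels = 124` (the 128-channel net minus the four
#' cheek channels) the montage carries exactly the standard LOT/ROT membership.
#'
#' The layout is fully deterministic; `seed` is accepted for interface
#' symmetry with the other generators.
#'
#' @param n_channels Number of electrodes, at least 18 (both clusters must fit).
#' @param seed Integer seed (layout is deterministic; kept for API symmetry).
#' @return An object of class `eeg_montage`: list with `channels` (labels),
#'   `positions` (n x 3 matrix of unit vectors, rownames = labels) and
#'   `clusters` (named list of channel subsets).
#' @examples
#' m <- make_montage(124)
#' lengths(m$clusters)
#' @export
make_montage <- function(n_channels = 124, seed = 1L) {
  cluster_labels <- unlist(ot_clusters, use.names = FALSE)
  if (n_channels < length(cluster_labels)) {
    missing <- cluster_labels[seq(n_channels + 1L, length(cluster_labels))]
    stop(
      "n_channels = ", n_channels, " cannot hold the occipito-temporal ",
      "clusters; missing channels: ", paste(missing, collapse = ", ")
    )
  }
  # Label pool: E1..E128 minus cheek channels, extended beyond 124 if asked.
  pool <- paste0("E", seq_len(max(128, n_channels + length(cheek_channels))))
  pool <- setdiff(pool, cheek_channels)
  labels <- c(cluster_labels, setdiff(pool, cluster_labels)[seq_len(n_channels - length(cluster_labels))])

  half <- fibonacci_half_lattice(n_channels %/% 2)
  pts <- rbind(half, sweep(half, 2, c(-1, 1, 1), "*")) # right + mirrored left
  mirror_of <- c(nrow(half) + seq_len(nrow(half)), seq_len(nrow(half)))
  if (n_channels %% 2 == 1) {
    pts <- rbind(pts, c(0, 0, 1)) # midline vertex for odd counts
    mirror_of <- c(mirror_of, nrow(pts))
  }

  # Assign the right cluster to the lattice points nearest its centroid, the
  # left cluster to their mirror images, and hand out the remaining labels in
  # a deterministic sweep (by azimuth).
  taken <- rep(FALSE, n_channels)
  d <- colSums((t(pts) - .rot_dir)^2)
  d[pts[, 1] <= 0] <- Inf # right-half points only; the mirror fills LOT
  rot_idx <- order(d)[seq_len(length(ot_clusters$ROT))]
  lot_idx <- mirror_of[rot_idx]
  taken[c(rot_idx, lot_idx)] <- TRUE

  ordered_labels <- character(n_channels)
  ordered_pos <- matrix(NA_real_, n_channels, 3)
  ordered_labels[seq_along(lot_idx)] <- ot_clusters$LOT
  ordered_pos[seq_along(lot_idx), ] <- pts[lot_idx, ]
  off <- length(lot_idx)
  ordered_labels[off + seq_along(rot_idx)] <- ot_clusters$ROT
  ordered_pos[off + seq_along(rot_idx), ] <- pts[rot_idx, ]
  rest_pts <- which(!taken)
  rest_pts <- rest_pts[order(atan2(pts[rest_pts, 2], pts[rest_pts, 1]), pts[rest_pts, 3])]
  rest_labels <- setdiff(labels, unlist(ot_clusters))
  ordered_labels[(2 * off + 1):n_channels] <- rest_labels
  ordered_pos[(2 * off + 1):n_channels, ] <- pts[rest_pts, ]

  # Present channels in natural label order (E-number ascending).
  ord <- order(as.integer(sub("^E", "", ordered_labels)))
  channels <- ordered_labels[ord]
  positions <- ordered_pos[ord, , drop = FALSE]
  rownames(positions) <- channels
  colnames(positions) <- c("x", "y", "z")

  structure(
    list(channels = channels, positions = positions, clusters = ot_clusters),
    class = "eeg_montage"
  )
}

# Quasi-uniform lattice over the x > 0 half sphere: golden-ratio azimuth
# spread over (0, pi), uniform in z. Mirrored across x = 0 by the caller.
fibonacci_half_lattice <- function(m) {
  i <- seq_len(m) - 0.5
  z <- 1 - 2 * i / m
  r <- sqrt(pmax(0, 1 - z^2))
  theta <- pi * ((i * (sqrt(5) - 1) / 2) %% 1) # azimuth from +y toward +x
  cbind(r * sin(theta), r * cos(theta), z)
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> ", length(x$channels), " channels; clusters: ",
    paste(sprintf("%s (%d)", names(x$clusters), lengths(x$clusters)), collapse = ", "),
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Montage as a tidy table
#'
#' @param montage An `eeg_montage`.
#' @return Tibble with columns `label`, `x`, `y`, `z`, `cluster` (`NA` for
#'   channels outside any named cluster).
#' @export
montage_table <- function(montage) {
  stopifnot(inherits(montage, "eeg_montage"))
  cl <- rep(NA_character_, length(montage$channels))
  for (nm in names(montage$clusters)) {
    cl[montage$channels %in% montage$clusters[[nm]]] <- nm
  }
  tibble::tibble(
    label = montage$channels,
    x = montage$positions[, 1],
    y = montage$positions[, 2],
    z = montage$positions[, 3],
    cluster = cl
  )
}

#' Write / read a montage as CSV
#'
#' Plain-text interchange format: one row per channel with unit-sphere
#' coordinates and cluster membership.
#'
#' @param montage An `eeg_montage`.
#' @param path File path.
#' @return `write_montage` returns `path` invisibly; `read_montage` returns an
#'   `eeg_montage`.
#' @export
write_montage <- function(montage, path) {
  utils::write.csv(montage_table(montage), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  pos <- as.matrix(df[, c("x", "y", "z")])
  rownames(pos) <- df$label
  clusters <- split(df$label, df$cluster)
  structure(
    list(channels = df$label, positions = pos, clusters = clusters[order(names(clusters))]),
    class = "eeg_montage"
  )
}

cluster_centroid <- function(montage, cluster) {
  ch <- montage$clusters[[cluster]]
  v <- colMeans(montage$positions[ch, , drop = FALSE])
  v / sqrt(sum(v^2))
}
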