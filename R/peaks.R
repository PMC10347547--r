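# Density-peak extraction: periodic 26-neighbour local maxima above a
# threshold, refined to sub-voxel precision by separable quadratic
# interpolation; sigma <-> absolute contour conversion; periodic trilinear
# map interpolation.

shift_array <- function(a, s) {
  d <- dim(a)
  idx <- lapply(1:3, function(k) ((seq_len(d[k]) - 1 + s[k]) %% d[k]) + 1)
  a[idx[[1]], idx[[2]], idx[[3]]]
}

#' Find density peaks
#'
#' A voxel is a candidate peak iff its value exceeds the threshold and all
#' 26 periodic neighbours. Candidate positions are refined by a separable
#' quadratic fit along each axis (offset clipped to half a voxel), and
#' peaks closer than half a voxel edge are merged keeping the higher one
#' (ties broken by lexicographic grid index).
#'
#' @param map A `density_map`.
#' @param threshold Detection threshold in e/A^3; defaults to 2.08 (the
#'   analysis level for water/oxygen maps; use 0.26 for hydrogen maps).
#' @param species Species tag recorded on the peaks (default: the map's).
#' @return A `peak_list`: data frame with id, Cartesian position, refined
#'   and raw heights, grid index and species, plus the cell as an attribute.
#' @export
find_peaks <- function(map, threshold = 2.08, species = map$species) {
  if (threshold <= map$mean)
    stop("threshold must exceed the map mean (", signif(map$mean, 4), ")")
  v <- map$values
  d <- dim(v)
  is_max <- v > threshold
  for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
    if (sx == 0 && sy == 0 && sz == 0) next
    if (!any(is_max)) break
    is_max <- is_max & (v > shift_array(v, c(sx, sy, sz)))
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty_peak_list(map$cell, species))

  # quadratic refinement per axis using periodic neighbours
  n <- nrow(idx)
  offset <- matrix(0, n, 3)
  height <- v[idx]
  raw <- height
  for (ax in 1:3) {
    up <- idx; up[, ax] <- (idx[, ax] %% d[ax]) + 1
    dn <- idx; dn[, ax] <- ((idx[, ax] - 2) %% d[ax]) + 1
    fp <- v[up]; fm <- v[dn]; f0 <- raw
    den <- fm - 2 * f0 + fp
    delta <- ifelse(den < 0, 0.5 * (fm - fp) / den, 0)
    delta <- pmax(-0.5, pmin(0.5, delta))
    offset[, ax] <- delta
    height <- height + ifelse(den < 0, 0.5 * (fp - fm) * delta +
                                0.5 * den * delta^2, 0)
  }
  frac <- sweep(idx - 1 + offset, 2, d, "/")
  pos <- frac_to_cart(map$cell, frac)

  pk <- data.frame(id = seq_len(n), x = pos[, 1], y = pos[, 2], z = pos[, 3],
                   height = height, height_raw = raw,
                   i = idx[, 1] - 1L, j = idx[, 2] - 1L, k = idx[, 3] - 1L,
                   species = species, stringsAsFactors = FALSE)
  # merge peaks closer than half a voxel edge, keeping the higher
  min_edge <- min(c(map$cell$a, map$cell$b, map$cell$c) / d)
  ord <- order(-pk$height, pk$i, pk$j, pk$k)
  pk <- pk[ord, , drop = FALSE]
  keep <- rep(TRUE, n)
  if (n > 1) {
    dm <- min_image_dist(map$cell, as.matrix(pk[, c("x", "y", "z")]),
                         as.matrix(pk[, c("x", "y", "z")]))
    for (i in seq_len(n)) {
      if (!keep[i]) next
      close_j <- which(dm[i, ] < min_edge / 2)
      keep[setdiff(close_j, seq_len(i))] <- FALSE
    }
  }
  pk <- pk[keep, , drop = FALSE]
  pk <- pk[order(pk$i, pk$j, pk$k), , drop = FALSE]
  pk$id <- seq_len(nrow(pk))
  rownames(pk) <- NULL
  attr(pk, "cell") <- map$cell
  class(pk) <- c("peak_list", "data.frame")
  pk
}

empty_peak_list <- function(cell, species = "all") {
  pk <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                   z = numeric(0), height = numeric(0),
                   height_raw = numeric(0), i = integer(0), j = integer(0),
                   k = integer(0), species = character(0),
                   stringsAsFactors = FALSE)
  attr(pk, "cell") <- cell
  class(pk) <- c("peak_list", "data.frame")
  pk
}

#' Convert a sigma-relative contour level to absolute units
#'
#' `map.mean + n_sigma * map.sigma`, the identity linking sigma-contoured
#' experimental maps to absolute e/A^3 levels (e.g. a 1 sigma contour of a
#' map with zero mean and sigma 0.173 e/A^3 is 0.173 e/A^3).
#'
#' @param map A `density_map` with populated statistics.
#' @param n_sigma Contour level in sigma units.
#' @return Contour level in e/A^3.
#' @export
sigma_to_absolute <- function(map, n_sigma) map$mean + n_sigma * map$sigma

#' Interpolate a density map at arbitrary positions
#'
#' Periodic trilinear interpolation.
#'
#' @param map A `density_map`.
#' @param positions Length-3 vector or n x 3 matrix of Cartesian positions.
#' @return Interpolated values in e/A^3.
#' @export
height_at <- function(map, positions) {
  positions <- rbind(positions)
  stopifnot(all(is.finite(positions)))
  v <- map$values
  d <- dim(v)
  fr <- cart_to_frac(map$cell, positions)
  g <- sweep(fr - floor(fr), 2, d, "*")
  i0 <- floor(g)
  f <- g - i0
  out <- numeric(nrow(positions))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (if (cx) f[, 1] else 1 - f[, 1]) *
         (if (cy) f[, 2] else 1 - f[, 2]) *
         (if (cz) f[, 3] else 1 - f[, 3])
    ii <- cbind((i0[, 1] + cx) %% d[1], (i0[, 2] + cy) %% d[2],
                (i0[, 3] + cz) %% d[3]) + 1
    out <- out + w * v[ii]
  }
  unname(out)
}

#' Write a peak list as CSV
#' @param peaks A `peak_list`.
#' @param path Output path.
#' @export
write_peaks_csv <- function(peaks, path) {
  utils::write.csv(as.data.frame(peaks)[, c("id", "x", "y", "z", "height",
                                            "height_raw", "species")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
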