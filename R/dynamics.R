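# Site-occupancy and water-exchange analysis: which molecule occupies each
# solvent site in each frame, and debounced exchange events -- the fast
# dynamics that the time-averaged density alone cannot show.

#' Per-frame site occupancy
#'
#' For every site and frame, the nearest water oxygen within
#' `capture_radius` (minimum image); `NA` when the capture sphere is empty.
#' Overlapping capture spheres trigger a warning; assignment stays
#' deterministic (nearest wins).
#'
#' @param snapshots A `snapshot_set`.
#' @param sites n x 3 matrix (or length-3 vector) of site positions (A).
#' @param capture_radius Capture radius in Angstrom (default 1.2, below
#'   half a typical nearest-neighbour water spacing and above typical site
#'   jitter).
#' @return An `occupancy_series` data frame (site, frame, molecule).
#' @export
site_occupancy <- function(snapshots, sites, capture_radius = 1.2) {
  stopifnot(capture_radius > 0)
  sites <- rbind(sites)
  cell <- snapshots$cell
  if (is.null(cell)) stop("snapshot set has no unit cell")
  if (nrow(sites) > 1) {
    dd <- min_image_dist(cell, sites, sites)
    diag(dd) <- Inf
    if (any(dd < 2 * capture_radius))
      warning("capture spheres overlap; nearest-site assignment still deterministic")
  }
  o_idx <- which(snapshots$atoms$label == "O")
  nf <- n_frames(snapshots)
  out <- vector("list", nf)
  for (f in seq_len(nf)) {
    opos <- snapshots$coords[f, o_idx, , drop = FALSE]
    opos <- matrix(opos, ncol = 3)
    d <- min_image_dist(cell, sites, opos)
    nearest <- apply(d, 1, which.min)
    dist <- d[cbind(seq_len(nrow(sites)), nearest)]
    mol <- ifelse(dist <= capture_radius,
                  snapshots$molid[f, o_idx[nearest]], NA_integer_)
    out[[f]] <- data.frame(site = seq_len(nrow(sites)), frame = f - 1L,
                           molecule = as.integer(mol))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$site, res$frame), ]
  rownames(res) <- NULL
  attr(res, "capture_radius") <- capture_radius
  class(res) <- c("occupancy_series", "data.frame")
  res
}

#' Count debounced exchange events
#'
#' An exchange is a change of occupant in which both the outgoing and the
#' incoming molecule persist for at least `min_dwell` frames; shorter
#' excursions (flickers) are ignored. The event frame is the first frame of
#' the incoming occupant's run (0-based).
#'
#' @param series An `occupancy_series` (one site, or use `site` to pick one).
#' @param min_dwell Minimum dwell in frames (default 5).
#' @param site Site id when `series` covers several sites.
#' @return Data frame of events (site, frame, from, to).
#' @export
count_exchanges <- function(series, min_dwell = 5, site = NULL) {
  stopifnot(min_dwell >= 1)
  sites <- if (is.null(site)) unique(series$site) else site
  events <- list()
  for (s in sites) {
    sub <- series[series$site == s, ]
    sub <- sub[order(sub$frame), ]
    occ <- sub$molecule
    r <- rle(ifelse(is.na(occ), -1L, occ))
    start <- cumsum(c(0, r$lengths[-length(r$lengths)]))
    solid <- which(r$lengths >= min_dwell & r$values != -1L)
    if (length(solid) >= 2) {
      for (k in 2:length(solid)) {
        a <- solid[k - 1]; b <- solid[k]
        if (r$values[a] != r$values[b])
          events[[length(events) + 1]] <- data.frame(
            site = s, frame = sub$frame[start[b] + 1],
            from = r$values[a], to = r$values[b])
      }
    }
  }
  if (length(events) == 0)
    return(data.frame(site = integer(0), frame = integer(0),
                      from = integer(0), to = integer(0)))
  do.call(rbind, events)
}

#' Occupancy fraction per site
#' @param series An `occupancy_series`.
#' @return Data frame (site, n_occupied, n_frames, fraction).
#' @export
occupancy_fraction <- function(series) {
  agg <- aggregate(molecule ~ site, data = series,
                   FUN = function(m) sum(!is.na(m)), na.action = stats::na.pass)
  nf <- length(unique(series$frame))
  data.frame(site = agg$site, n_occupied = agg$molecule, n_frames = nf,
             fraction = agg$molecule / nf)
}
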