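# Agreement statistics between MD density peaks and reference water
# positions: per-water nearest-peak distance (r_MD-xtal), shell
# classification, per-shell peak-height correlation, fraction recovered,
# and region summaries.

#' Region specification
#'
#' Exactly one membership rule: a sphere (`center`, `radius`), an explicit
#' water-id list (`ids`), or residue-pair boundaries (`pairs`, a data frame
#' with columns x, y, z of pair midpoint positions, plus `radius`) standing
#' in for channel-boundary definitions.
#'
#' @param name Region name.
#' @param center,radius Sphere centre (Cartesian A) and radius (A).
#' @param ids Integer vector of water ids.
#' @param pairs Data frame of boundary-pair midpoint positions (x, y, z);
#'   membership is the union of spheres of `radius` about each midpoint.
#' @return A `region_spec`.
#' @export
region_spec <- function(name = "region", center = NULL, radius = NULL,
                        ids = NULL, pairs = NULL) {
  kinds <- c(sphere = !is.null(center), ids = !is.null(ids),
             pairs = !is.null(pairs))
  if (sum(kinds) != 1) stop("exactly one membership rule must be given")
  kind <- names(kinds)[kinds]
  if (kind %in% c("sphere", "pairs") && is.null(radius))
    stop("radius required for ", kind, " regions")
  structure(list(name = name, kind = kind, center = center, radius = radius,
                 ids = ids, pairs = pairs), class = "region_spec")
}

region_member <- function(region, cell, positions, ids = NULL) {
  if (is.null(region)) return(rep(TRUE, nrow(rbind(positions))))
  positions <- rbind(positions)
  switch(region$kind,
    sphere = as.vector(min_image_dist(cell, positions,
                                      region$center) <= region$radius),
    ids = if (is.null(ids)) stop("region by ids needs water ids")
          else ids %in% region$ids,
    pairs = {
      d <- min_image_dist(cell, positions,
                          as.matrix(region$pairs[, c("x", "y", "z")]))
      apply(d <= region$radius, 1, any)
    })
}

#' Shell classification of a peak-to-water distance
#'
#' inner: r < 0.3 A; middle: 0.3 <= r < 0.5 A; outer: 0.5 <= r < 1.0 A;
#' distant: r >= 1.0 A. Boundary values go to the upper class.
#'
#' @param r Distance(s) in Angstrom (vectorized).
#' @param boundaries Shell boundaries, default `c(0.3, 0.5, 1.0)`.
#' @return Factor with levels inner/middle/outer/distant.
#' @export
classify_shell <- function(r, boundaries = c(0.3, 0.5, 1.0)) {
  if (any(r < 0, na.rm = TRUE)) stop("distances must be non-negative")
  stopifnot(length(boundaries) == 3, all(diff(boundaries) > 0))
  cut(r, breaks = c(-Inf, boundaries, Inf), right = FALSE,
      include.lowest = TRUE,
      labels = c("inner", "middle", "outer", "distant"))
}

#' Match reference waters to density peaks
#'
#' For every reference water (in the region, if given): the minimum-image
#' distance to the nearest peak, the nearest peak's id and height, the
#' shell class, and optionally the experimental map value at the water
#' position. Nearest-peak assignment is non-exclusive: one peak may serve
#' several waters. With no peaks, r is `Inf` and the shell "distant".
#'
#' @param peaks A `peak_list`.
#' @param reference A `reference_model` with a cell (or `cell` supplied).
#' @param region Optional `region_spec` restricting the waters considered.
#' @param experimental_map Optional `density_map` supplying experimental
#'   heights at the water positions.
#' @param cell Cell override when the reference has none.
#' @param boundaries Shell boundaries passed to [classify_shell()].
#' @return A `match_report` data frame.
#' @export
match_waters <- function(peaks, reference, region = NULL,
                         experimental_map = NULL, cell = NULL,
                         boundaries = c(0.3, 0.5, 1.0)) {
  cell <- cell %||% reference$cell %||% attr(peaks, "cell")
  if (is.null(cell)) stop("no unit cell available for matching")
  w <- reference$waters
  keep <- region_member(region, cell, as.matrix(w[, c("x", "y", "z")]),
                        w$water_id)
  w <- w[keep, , drop = FALSE]
  n <- nrow(w)
  if (nrow(peaks) == 0) {
    rep_df <- data.frame(water_id = w$water_id, r = rep(Inf, n),
                         peak_id = NA_integer_,
                         shell = factor(rep("distant", n),
                                        levels = c("inner", "middle",
                                                   "outer", "distant")),
                         md_height = NA_real_, exp_height = NA_real_)
  } else {
    dm <- min_image_dist(cell, as.matrix(w[, c("x", "y", "z")]),
                         as.matrix(peaks[, c("x", "y", "z")]))
    nearest <- apply(dm, 1, which.min)
    r <- dm[cbind(seq_len(n), nearest)]
    rep_df <- data.frame(water_id = w$water_id, r = r,
                         peak_id = peaks$id[nearest],
                         shell = classify_shell(r, boundaries),
                         md_height = peaks$height[nearest],
                         exp_height = NA_real_)
  }
  if (!is.null(experimental_map) && n > 0)
    rep_df$exp_height <- height_at(experimental_map,
                                   as.matrix(w[, c("x", "y", "z")]))
  attr(rep_df, "cell") <- cell
  class(rep_df) <- c("match_report", "data.frame")
  rep_df
}

#' Per-shell Pearson correlation of MD vs experimental peak heights
#'
#' @param report A `match_report` with `exp_height` populated (or an
#'   `experimental_map` to interpolate is already folded in by
#'   [match_waters()]).
#' @return Named numeric vector of Pearson r per shell (inner, middle,
#'   outer); shells with fewer than two complete pairs are `NA`.
#' @export
shell_height_correlation <- function(report) {
  out <- c(inner = NA_real_, middle = NA_real_, outer = NA_real_)
  for (sh in names(out)) {
    rows <- report$shell == sh & is.finite(report$md_height) &
      is.finite(report$exp_height)
    if (sum(rows, na.rm = TRUE) >= 2) {
      x <- report$md_height[rows]; y <- report$exp_height[rows]
      if (stats::sd(x) > 0 && stats::sd(y) > 0)
        out[sh] <- stats::cor(x, y)
    }
  }
  out
}

#' Fraction of reference waters recovered by the MD density
#'
#' A water counts as recovered when its nearest peak lies within
#' `distance_cut` and that peak's height is at least `height_cut` -- the
#' "strong peak within 1 A" criterion.
#'
#' @param report A `match_report`.
#' @param distance_cut Distance cut in Angstrom (default 1.0).
#' @param height_cut Peak-height cut in e/A^3 (default 2.08).
#' @return List with `n_recovered`, `n_total`, `fraction`.
#' @export
fraction_recovered <- function(report, distance_cut = 1.0,
                               height_cut = 2.08) {
  if (nrow(report) == 0) stop("empty match report")
  ok <- is.finite(report$r) & report$r <= distance_cut &
    is.finite(report$md_height) & report$md_height >= height_cut
  list(n_recovered = sum(ok), n_total = nrow(report),
       fraction = sum(ok) / nrow(report))
}

#' Region summary statistics
#'
#' Mean peak height (and mean r for match reports) over the members of a
#' region; an empty region reports n = 0 with undefined means.
#'
#' @param x A `peak_list` or `match_report`.
#' @param region A `region_spec`, or NULL for all.
#' @param reference Needed to resolve water positions for a `match_report`.
#' @return List with `n`, `mean_peak_height`, and `mean_r` (match reports).
#' @export
region_stats <- function(x, region = NULL, reference = NULL) {
  cell <- attr(x, "cell")
  if (inherits(x, "peak_list")) {
    member <- region_member(region, cell, as.matrix(x[, c("x", "y", "z")]))
    h <- x$height[member]
    list(n = sum(member),
         mean_peak_height = if (sum(member)) mean(h) else NA_real_)
  } else if (inherits(x, "match_report")) {
    if (is.null(reference)) stop("match-report regions need the reference model")
    w <- reference$waters[match(x$water_id, reference$waters$water_id), ]
    member <- region_member(region, cell, as.matrix(w[, c("x", "y", "z")]),
                            w$water_id)
    list(n = sum(member),
         mean_peak_height = if (sum(member)) mean(x$md_height[member]) else NA_real_,
         mean_r = if (sum(member)) mean(x$r[member]) else NA_real_)
  } else stop("region_stats expects a peak_list or match_report")
}

#' Write a match report as CSV
#' @param report A `match_report`.
#' @param path Output path.
#' @export
write_match_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
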