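# MADI: map-based acceptor-donor identification.
#
# Oxygen and hydrogen density maps are reduced to peak lists; a directed
# hydrogen bond i -> j is inferred when the O-O distance falls in the
# hydrogen-bond window and a hydrogen peak sits within covalent range of
# the donor oxygen, close to the donor->acceptor axis. The supporting
# hydrogen peak height serves as the bond-strength score: orientational
# disorder smears hydrogen density and lowers the peak, so height is a
# monotone proxy for how well-ordered (strong) the bond is.

#' Collect MADI peaks from oxygen and hydrogen maps
#'
#' @param O_map Water-oxygen `density_map`.
#' @param H_maps A single hydrogen `density_map` or a list of them (e.g.
#'   separate H1 and H2 maps); each peak remembers which map produced it.
#' @param o_threshold Oxygen peak threshold, e/A^3 (default 2.08).
#' @param h_threshold Hydrogen peak threshold, e/A^3 (default 0.26).
#' @param external_sites Optional data frame (id, x, y, z) of protein
#'   acceptor atoms from a reference model.
#' @return A `madi_peaks` object.
#' @export
collect_peaks <- function(O_map, H_maps, o_threshold = 2.08,
                          h_threshold = 0.26, external_sites = NULL) {
  if (inherits(H_maps, "density_map")) H_maps <- list(H = H_maps)
  same_cell <- function(c1, c2)
    isTRUE(all.equal(unlist(c1[c("a", "b", "c", "alpha", "beta", "gamma")]),
                     unlist(c2[c("a", "b", "c", "alpha", "beta", "gamma")])))
  for (hm in H_maps)
    if (!same_cell(O_map$cell, hm$cell))
      stop("oxygen and hydrogen maps must share a unit cell")
  O_peaks <- find_peaks(O_map, o_threshold, species = "O")
  H_list <- lapply(seq_along(H_maps), function(i) {
    tag <- names(H_maps)[i] %||% paste0("H", i)
    if (is.null(tag) || !nzchar(tag)) tag <- paste0("H", i)
    find_peaks(H_maps[[i]], h_threshold, species = tag)
  })
  H_peaks <- do.call(rbind, lapply(H_list, as.data.frame))
  if (is.null(H_peaks)) H_peaks <- as.data.frame(empty_peak_list(O_map$cell))
  H_peaks$id <- seq_len(nrow(H_peaks))
  structure(list(O_peaks = O_peaks, H_peaks = H_peaks,
                 external_sites = external_sites, cell = O_map$cell),
            class = "madi_peaks")
}

#' @export
print.madi_peaks <- function(x, ...) {
  cat(sprintf("MADI peaks: %d oxygen, %d hydrogen, %d external sites\n",
              nrow(x$O_peaks), nrow(x$H_peaks),
              if (is.null(x$external_sites)) 0L else nrow(x$external_sites)))
  invisible(x)
}

#' Infer directed hydrogen bonds from MADI peaks
#'
#' For every ordered oxygen-site pair (i, j) whose minimum-image O-O
#' distance lies inside `OO_window`: if some hydrogen peak lies within
#' `covalent_max` of O_i and within `angle_tol` degrees of the i -> j axis
#' (measured at O_i), a directed edge i -> j is emitted, supported by the
#' highest such hydrogen peak. Evidence in both directions yields a single
#' edge flagged ambiguous (directed along the stronger evidence). External
#' sites participate as acceptors only, since the water maps contain no
#' protein hydrogens.
#'
#' @param peaks A `madi_peaks` object.
#' @param OO_window O-O distance window in Angstrom, default `c(2.4, 3.5)`.
#' @param covalent_max Maximum donor O -- H peak distance (A), default 1.2.
#' @param angle_tol Off-axis tolerance in degrees, default 30.
#' @param class_bounds Strength class bounds passed to [score_strength()].
#' @return An `hbond_network` with node and edge tables.
#' @export
assign_hbonds <- function(peaks, OO_window = c(2.4, 3.5), covalent_max = 1.2,
                          angle_tol = 30, class_bounds = c(0.5, 1.5)) {
  stopifnot(OO_window[1] > 2.0, OO_window[2] < 4.0, covalent_max > 0,
            angle_tol > 0)
  cell <- peaks$cell
  O <- as.data.frame(peaks$O_peaks)
  nO <- nrow(O)
  nodes <- data.frame(id = seq_len(nO),
                      x = O$x, y = O$y, z = O$z,
                      height = O$height, kind = rep("water_O", nO),
                      stringsAsFactors = FALSE)
  if (!is.null(peaks$external_sites) && nrow(peaks$external_sites) > 0) {
    ex <- peaks$external_sites
    nodes <- rbind(nodes, data.frame(id = nO + seq_len(nrow(ex)),
                                     x = ex$x, y = ex$y, z = ex$z,
                                     height = NA_real_, kind = "external",
                                     stringsAsFactors = FALSE))
  }
  H <- peaks$H_peaks
  edges <- empty_edge_table()
  if (nO > 0 && nrow(H) > 0 && nrow(nodes) > 1) {
    npos <- as.matrix(nodes[, c("x", "y", "z")])
    oo <- min_image_dist(cell, npos, npos)
    # hydrogen evidence: displacement vectors donor O -> H peak
    hpos <- as.matrix(H[, c("x", "y", "z")])
    mv <- min_image_vec(cell, npos[seq_len(nO), , drop = FALSE], hpos)
    oh_d <- sqrt(mv$d2)                         # nO x nH
    found <- list()
    for (i in seq_len(nO)) {
      hs <- which(oh_d[i, ] <= covalent_max)
      if (length(hs) == 0) next
      js <- which(oo[i, ] >= OO_window[1] & oo[i, ] <= OO_window[2])
      js <- setdiff(js, i)
      if (length(js) == 0) next
      oov <- min_image_vec(cell, npos[i, , drop = FALSE],
                           npos[js, , drop = FALSE])
      for (jj in seq_along(js)) {
        j <- js[jj]
        axis <- oov$vec[jj, ] / sqrt(oov$d2[1, jj])
        best <- NULL
        for (h in hs) {
          hv <- mv$vec[(i - 1) * nrow(H) + h, ]
          hn <- sqrt(sum(hv^2))
          if (hn == 0) next
          ang <- acos(pmin(1, pmax(-1, sum(hv * axis) / hn))) * 180 / pi
          if (ang <= angle_tol &&
              (is.null(best) || H$height[h] > best$height ||
               (H$height[h] == best$height && ang < best$angle)))
            best <- list(h = h, height = H$height[h], angle = ang)
        }
        if (!is.null(best))
          found[[length(found) + 1]] <- data.frame(
            donor = i, acceptor = j, OO_A = oo[i, j],
            H_peak = best$h, H_species = H$species[best$h],
            H_height_e_A3 = best$height, angle_deg = best$angle,
            stringsAsFactors = FALSE)
      }
    }
    if (length(found) > 0) {
      ed <- do.call(rbind, found)
      # collapse opposing directions into one ambiguous edge
      key <- paste(pmin(ed$donor, ed$acceptor), pmax(ed$donor, ed$acceptor))
      ed$ambiguous <- key %in% key[duplicated(key)]
      keep <- rep(TRUE, nrow(ed))
      for (k in unique(key[ed$ambiguous])) {
        rows <- which(key == k)
        ord <- rows[order(-ed$H_height_e_A3[rows], ed$donor[rows])]
        keep[ord[-1]] <- FALSE
      }
      edges <- ed[keep, , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  net <- structure(list(nodes = nodes, edges = edges, cell = cell),
                   class = "hbond_network")
  score_strength(net, class_bounds)
}

empty_edge_table <- function() {
  data.frame(donor = integer(0), acceptor = integer(0), OO_A = numeric(0),
             H_peak = integer(0), H_species = character(0),
             H_height_e_A3 = numeric(0), angle_deg = numeric(0),
             ambiguous = logical(0), stringsAsFactors = FALSE)
}

#' @export
print.hbond_network <- function(x, ...) {
  cat(sprintf("hydrogen-bond network: %d nodes, %d directed edges (%d ambiguous)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$ambiguous)))
  invisible(x)
}

#' Score hydrogen-bond strength
#'
#' Strength is the supporting hydrogen peak height in e/A^3 (a sharper,
#' better-ordered hydrogen gives a taller peak). Classes by bounds: weak
#' below the first, strong at or above the second (upper-inclusive),
#' medium between. An occupancy-normalized variant (height divided by the
#' donor oxygen peak height) is reported alongside as `strength_norm`.
#'
#' @param net An `hbond_network`.
#' @param class_bounds Numeric length-2, default `c(0.5, 1.5)` e/A^3.
#' @return The network with `strength`, `strength_norm` and `class` columns.
#' @export
score_strength <- function(net, class_bounds = c(0.5, 1.5)) {
  stopifnot(length(class_bounds) == 2, class_bounds[1] < class_bounds[2])
  ed <- net$edges
  ed$strength <- ed$H_height_e_A3
  dh <- net$nodes$height[ed$donor]
  ed$strength_norm <- ifelse(is.finite(dh) & dh > 0, ed$strength / dh,
                             NA_real_)
  ed$class <- ifelse(ed$strength < class_bounds[1], "weak",
                     ifelse(ed$strength >= class_bounds[2], "strong",
                            "medium"))
  net$edges <- ed
  net
}

#' Extract water wires (maximal directed paths)
#'
#' All maximal simple directed paths with at least `min_length` edges, in
#' deterministic order (start node, then lexicographic node sequence).
#' Nodes on directed cycles are reported separately rather than traversed.
#'
#' @param net An `hbond_network`.
#' @param min_length Minimum number of edges per wire (default 1).
#' @return List with `wires` (list of integer node-id vectors) and
#'   `cycles` (node ids involved in directed cycles, if any).
#' @export
extract_wires <- function(net, min_length = 1) {
  ed <- net$edges
  if (nrow(ed) == 0) return(list(wires = list(), cycles = integer(0)))
  nodes <- sort(unique(c(ed$donor, ed$acceptor)))
  out_adj <- split(ed$acceptor, factor(ed$donor, levels = nodes))
  in_deg <- table(factor(ed$acceptor, levels = nodes))
  g <- igraph::graph_from_data_frame(ed[, c("donor", "acceptor")],
                                     vertices = data.frame(name = nodes))
  cyc_nodes <- integer(0)
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    big <- which(comp$csize > 1)
    cyc_nodes <- nodes[comp$membership %in% big]
  }
  starts <- nodes[in_deg == 0]
  wires <- list()
  grow <- function(path) {
    nxt <- setdiff(out_adj[[as.character(path[length(path)])]], path)
    nxt <- setdiff(nxt, cyc_nodes)
    if (length(nxt) == 0) {
      if (length(path) - 1 >= min_length)
        wires[[length(wires) + 1]] <<- path
      return(invisible())
    }
    for (v in sort(nxt)) grow(c(path, v))
  }
  for (s in sort(setdiff(starts, cyc_nodes))) grow(s)
  ord <- order(vapply(wires, `[`, numeric(1), 1),
               vapply(wires, paste, character(1), collapse = ","))
  list(wires = wires[ord], cycles = cyc_nodes)
}

#' MADI hydrogen-bond network straight from a snapshot set
#'
#' Convenience wrapper for the full MADI chain: species selection (water
#' oxygen, H1, H2), mean structure factors, map synthesis, peak collection
#' and directed bond assignment. The analysis maps default to a finer
#' resolution (1.5 A) than the 2.0 A experimental-comparison map: hydrogen
#' scattering is so weak that at 2.0 A an ideal rigid water hydrogen peaks
#' at only ~0.28 e/A^3, leaving no margin over the 0.26 e/A^3 detection
#' level once positional disorder smears it; at 1.5 A ordered hydrogens
#' peak well above the level while cone- or sphere-smeared (disordered)
#' hydrogens stay far below it.
#'
#' @param snapshots A `snapshot_set` of waters.
#' @param d_min Analysis-map resolution in Angstrom (default 1.5).
#' @param o_threshold,h_threshold Peak thresholds (e/A^3).
#' @param pool_H `"split"` (default) computes separate H1/H2 maps; `"all"`
#'   one combined hydrogen map.
#' @param frames Optional frame subset.
#' @param external_sites Optional protein acceptor sites (id, x, y, z).
#' @param ... Passed to [assign_hbonds()].
#' @return An `hbond_network`.
#' @export
madi_network <- function(snapshots, d_min = 1.5, o_threshold = 2.08,
                         h_threshold = 0.26, pool_H = c("split", "all"),
                         frames = NULL, external_sites = NULL, ...) {
  pool_H <- match.arg(pool_H)
  mk <- function(sel) map_from_sf(structure_factors(
    select_species(snapshots, sel), d_min, frames = frames))
  O_map <- mk("water_O")
  H_maps <- if (pool_H == "split")
    list(H1 = mk("water_H1"), H2 = mk("water_H2"))
  else list(H = mk("water_H_all"))
  mp <- collect_peaks(O_map, H_maps, o_threshold, h_threshold,
                      external_sites = external_sites)
  assign_hbonds(mp, ...)
}

#' Score a recovered network against a ground-truth network
#'
#' Maps every water-oxygen node to the nearest ground-truth site (within
#' `match_tol`, minimum image) and counts ground-truth directed edges
#' recovered with the correct direction, ambiguous recoveries, and false
#' (non-truth) directed edges.
#'
#' @param net An `hbond_network`.
#' @param truth Per-site truth list (as from [generate_water_wire()]).
#' @param truth_network The accompanying `ground_truth_network`.
#' @param cell The `unit_cell`.
#' @param match_tol Node-to-site matching tolerance in Angstrom.
#' @return List with counts: `n_truth`, `n_recovered`, `n_ambiguous`,
#'   `n_false`, `n_edges`.
#' @export
compare_to_truth <- function(net, truth, truth_network, cell,
                             match_tol = 0.5) {
  sites <- t(vapply(truth, function(s) as.numeric(s$mean_O_position),
                    numeric(3)))
  site_ids <- vapply(truth, function(s) as.integer(s$site_id), integer(1))
  nodes <- net$nodes[net$nodes$kind == "water_O", , drop = FALSE]
  node_site <- rep(NA_integer_, nrow(net$nodes))
  if (nrow(nodes) > 0) {
    d <- min_image_dist(cell, as.matrix(nodes[, c("x", "y", "z")]), sites)
    nearest <- apply(d, 1, which.min)
    ok <- d[cbind(seq_len(nrow(nodes)), nearest)] <= match_tol
    node_site[nodes$id[ok]] <- site_ids[nearest[ok]]
  }
  ed <- net$edges
  ed_sites <- data.frame(donor = node_site[ed$donor],
                         acceptor = node_site[ed$acceptor],
                         ambiguous = ed$ambiguous)
  tkey <- paste(truth_network$edges$donor, truth_network$edges$acceptor)
  ekey <- paste(ed_sites$donor, ed_sites$acceptor)
  recovered <- ekey %in% tkey & !is.na(ed_sites$donor) & !is.na(ed_sites$acceptor)
  list(n_truth = nrow(truth_network$edges),
       n_recovered = sum(recovered & !ed_sites$ambiguous),
       n_ambiguous = sum(recovered & ed_sites$ambiguous),
       n_false = sum(!(recovered)),
       n_edges = nrow(ed))
}

#' Write a network edge list as CSV
#' @param net An `hbond_network`.
#' @param path Output path.
#' @export
write_network_csv <- function(net, path) {
  utils::write.csv(net$edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
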