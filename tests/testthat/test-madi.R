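cell <- unit_cell(16, 16, 16)

make_madi_peaks <- function(O_pos, H_pos, O_h = 5, H_h = 0.4,
                            H_species = "H1", cell. = cell) {
  O_pos <- rbind(O_pos)
  O <- data.frame(id = seq_len(nrow(O_pos)), x = O_pos[, 1], y = O_pos[, 2],
                  z = O_pos[, 3], height = rep_len(O_h, nrow(O_pos)),
                  height_raw = rep_len(O_h, nrow(O_pos)), i = 0L, j = 0L,
                  k = 0L, species = "O", stringsAsFactors = FALSE)
  attr(O, "cell") <- cell.; class(O) <- c("peak_list", "data.frame")
  if (is.null(H_pos)) {
    H <- as.data.frame(solvmap:::empty_peak_list(cell.))
  } else {
    H_pos <- rbind(H_pos)
    H <- data.frame(id = seq_len(nrow(H_pos)), x = H_pos[, 1], y = H_pos[, 2],
                    z = H_pos[, 3], height = rep_len(H_h, nrow(H_pos)),
                    height_raw = rep_len(H_h, nrow(H_pos)), i = 0L, j = 0L,
                    k = 0L, species = rep_len(H_species, nrow(H_pos)),
                    stringsAsFactors = FALSE)
  }
  structure(list(O_peaks = O, H_peaks = H, external_sites = NULL,
                 cell = cell.), class = "madi_peaks")
}

test_that("an on-axis hydrogen yields a single forward edge at zero angle", {
  mp <- make_madi_peaks(rbind(c(5, 8, 8), c(7.8, 8, 8)), c(5.96, 8, 8))
  net <- assign_hbonds(mp)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$donor, 1)
  expect_equal(net$edges$acceptor, 2)
  expect_equal(net$edges$angle_deg, 0, tolerance = 1e-9)
  expect_equal(net$edges$OO_A, 2.8, tolerance = 1e-12)
  expect_false(net$edges$ambiguous)
})

test_that("no hydrogen evidence means no edges regardless of O geometry", {
  mp <- make_madi_peaks(rbind(c(5, 8, 8), c(7.8, 8, 8)), NULL)
  net <- assign_hbonds(mp)
  expect_equal(nrow(net$edges), 0)
  expect_equal(extract_wires(net)$wires, list())
})

test_that("geometric gates reject off-window and off-axis candidates", {
  # O-O outside the window
  mp <- make_madi_peaks(rbind(c(5, 8, 8), c(9, 8, 8)), c(5.96, 8, 8))
  expect_equal(nrow(assign_hbonds(mp)$edges), 0)
  # H far from the donor
  mp <- make_madi_peaks(rbind(c(5, 8, 8), c(7.8, 8, 8)), c(6.5, 8, 8))
  expect_equal(nrow(assign_hbonds(mp)$edges), 0)
  # H 45 degrees off axis at default 30-degree tolerance
  mp <- make_madi_peaks(rbind(c(5, 8, 8), c(7.8, 8, 8)),
                        c(5, 8, 8) + 0.96 * c(cos(pi / 4), sin(pi / 4), 0))
  expect_equal(nrow(assign_hbonds(mp)$edges), 0)
  expect_equal(nrow(assign_hbonds(mp, angle_tol = 50)$edges), 1)
})

test_that("evidence in both directions collapses to one ambiguous edge", {
  O <- rbind(c(5, 8, 8), c(7.8, 8, 8))
  H <- rbind(c(5.96, 8, 8), c(6.84, 8, 8))   # one donated H from each side
  mp <- make_madi_peaks(O, H)
  net <- assign_hbonds(mp)
  expect_equal(nrow(net$edges), 1)
  expect_true(net$edges$ambiguous)
})

test_that("external sites accept but never donate", {
  mp <- make_madi_peaks(c(5, 8, 8), c(5.96, 8, 8))
  mp$external_sites <- data.frame(id = 1, x = 7.8, y = 8, z = 8)
  net <- assign_hbonds(mp)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$nodes$kind[net$edges$acceptor], "external")
  # reversing the geometry: H near the external site must not create an edge
  mp2 <- make_madi_peaks(c(7.8, 8, 8), c(5.96, 8, 8))
  mp2$external_sites <- data.frame(id = 1, x = 5, y = 8, z = 8)
  expect_equal(nrow(assign_hbonds(mp2)$edges), 0)
})

test_that("strength scoring is monotone in H height with inclusive class bounds", {
  O <- rbind(c(4, 8, 8), c(6.8, 8, 8), c(9.6, 8, 8))
  H <- rbind(c(4.96, 8, 8), c(7.76, 8, 8))
  mp <- make_madi_peaks(O, H)
  mp$H_peaks$height <- c(0.3, 0.9)
  net <- assign_hbonds(mp)
  ed <- net$edges[order(net$edges$donor), ]
  expect_equal(ed$strength, c(0.3, 0.9))
  expect_true(ed$strength[1] < ed$strength[2])
  expect_equal(ed$class, c("weak", "medium"))
  # boundary values: upper-inclusive
  mp$H_peaks$height <- c(0.5, 1.5)
  ed2 <- assign_hbonds(mp)$edges[order(ed$donor), ]
  expect_equal(sort(ed2$class), c("medium", "strong"))
})

test_that("collect_peaks separates species and enforces shared cells", {
  ens <- generate_water_wire(2, 2.8, "chain", 0, 1, seed = 1)
  sn <- ens$snapshots
  mk <- function(sel, dmin = 1.5) map_from_sf(structure_factors(
    select_species(sn, sel), dmin))
  mp <- collect_peaks(mk("water_O"), list(H1 = mk("water_H1"),
                                          H2 = mk("water_H2")))
  expect_equal(nrow(mp$O_peaks), 2)
  expect_true(all(mp$O_peaks$species == "O"))
  expect_true(any(mp$H_peaks$species == "H1"))
  other <- map_from_sf(structure_factors(
    select_species(generate_water_wire(2, 2.8, "chain", 0, 1, seed = 1,
                                       pad = 9)$snapshots, "water_H1"), 1.5))
  expect_error(collect_peaks(mk("water_O"), other), "cell")
  # empty maps produce empty peak collections
  emptyO <- solvmap:::new_density_map(sn$cell, array(0, c(12, 12, 12)) +
                                        1e-9 * array(runif(12^3), c(12, 12, 12)))
  mp0 <- collect_peaks(emptyO, emptyO, o_threshold = 1, h_threshold = 1)
  expect_equal(nrow(mp0$O_peaks), 0)
  expect_equal(nrow(assign_hbonds(mp0)$edges), 0)
})

test_that("noiseless donor chains are recovered exactly with full direction", {
  ens <- generate_water_wire(5, 2.8, "chain", 0, 1, seed = 1)
  net <- madi_network(ens$snapshots)
  sc <- compare_to_truth(net, ens$truth, ens$network, ens$snapshots$cell)
  expect_equal(sc$n_truth, 4)
  expect_equal(sc$n_recovered, 4)
  expect_equal(sc$n_ambiguous, 0)
  expect_equal(sc$n_false, 0)
  w <- extract_wires(net)
  expect_equal(length(w$wires), 1)
  expect_equal(length(w$wires[[1]]), 5)
})

test_that("rotor-mode hydrogens smear below the detection level", {
  ens <- generate_water_wire(3, 2.8, "rotor", jitter_sigma = 0.1,
                             n_frames = 800, seed = 6)
  sn <- ens$snapshots
  mH1 <- map_from_sf(structure_factors(select_species(sn, "water_H1"), 1.5))
  expect_lt(max(mH1$values), 0.26)
  net <- madi_network(sn)
  expect_gte(nrow(net$nodes), 3)     # oxygens still resolve
  expect_equal(nrow(net$edges), 0)   # no ordered hydrogen evidence
})

test_that("jittered chains keep >= 90% directed recovery with few false edges", {
  tot_truth <- 0; tot_rec <- 0; tot_false <- 0; tot_edges <- 0
  for (sd in 1:3) {
    ens <- generate_water_wire(5, 2.8, "chain", 0.15, 2000, seed = sd)
    net <- madi_network(ens$snapshots)
    sc <- compare_to_truth(net, ens$truth, ens$network, ens$snapshots$cell)
    tot_truth <- tot_truth + sc$n_truth
    tot_rec <- tot_rec + sc$n_recovered
    tot_false <- tot_false + sc$n_false
    tot_edges <- tot_edges + sc$n_edges
  }
  expect_gte(tot_rec / tot_truth, 0.9)
  expect_lte(tot_false / max(tot_edges, 1), 0.05)
})

test_that("assign_hbonds is invariant under O-peak relabeling and translation", {
  O <- rbind(c(4, 8, 8), c(6.8, 8, 8), c(9.6, 8, 8))
  H <- rbind(c(4.96, 8, 8), c(7.76, 8, 8))
  mp <- make_madi_peaks(O, H)
  net <- assign_hbonds(mp)
  key <- function(n) {
    p <- n$nodes
    sort(paste(round(p$x[n$edges$donor], 6), round(p$x[n$edges$acceptor], 6)))
  }
  # relabel (permute) O peaks
  mp2 <- make_madi_peaks(O[c(3, 1, 2), ], H)
  expect_equal(key(assign_hbonds(mp2)), key(net))
  # lattice translation
  mp3 <- make_madi_peaks(sweep(O, 2, c(16, -16, 0), "+"),
                         sweep(H, 2, c(16, -16, 0), "+"))
  net3 <- assign_hbonds(mp3)
  expect_equal(nrow(net3$edges), nrow(net$edges))
  expect_equal(net3$edges$OO_A, net$edges$OO_A, tolerance = 1e-9)
})

test_that("wire extraction enumerates maximal paths like brute force", {
  mk_net <- function(edges) {
    nodes <- data.frame(id = seq_len(max(edges)), x = 0, y = 0, z = 0,
                        height = 1, kind = "water_O")
    ed <- solvmap:::empty_edge_table()
    for (r in seq_len(nrow(edges)))
      ed[r, c("donor", "acceptor")] <- edges[r, ]
    ed$ambiguous <- FALSE
    structure(list(nodes = nodes, edges = ed, cell = cell),
              class = "hbond_network")
  }
  # linear chain: one wire; fork: two wires sharing a prefix
  lin <- extract_wires(mk_net(cbind(1:4, 2:5)))
  expect_equal(lin$wires, list(1:5))
  fork <- extract_wires(mk_net(rbind(c(1, 2), c(2, 3), c(3, 4), c(3, 5))))
  expect_equal(length(fork$wires), 2)
  expect_equal(fork$wires[[1]][1:3], c(1, 2, 3))
  expect_equal(sort(vapply(fork$wires, function(w) w[4], numeric(1))),
               c(4, 5))
  # random small DAGs against exhaustive enumeration via igraph
  brute_wires <- function(edges, min_len = 1) {
    g <- igraph::graph_from_edgelist(edges)
    vs <- as.integer(igraph::V(g))
    paths <- list()
    for (a in vs) for (b in vs) {
      if (a == b) next
      for (p in igraph::all_simple_paths(g, a, b, mode = "out"))
        paths[[length(paths) + 1]] <- as.integer(p)
    }
    adj_in <- lapply(vs, function(v)
      as.integer(igraph::neighbors(g, v, mode = "in")))
    adj_out <- lapply(vs, function(v)
      as.integer(igraph::neighbors(g, v, mode = "out")))
    maximal <- Filter(function(p) {
      head_ext <- length(setdiff(adj_in[[p[1]]], p)) > 0
      tail_ext <- length(setdiff(adj_out[[p[length(p)]]], p)) > 0
      !head_ext && !tail_ext && length(p) - 1 >= min_len
    }, paths)
    unique(maximal)
  }
  set.seed(14)
  for (rep_i in 1:8) {
    n <- sample(4:8, 1)
    # random DAG: edges only from lower to higher node id
    pairs <- t(combn(n, 2))
    pick <- pairs[runif(nrow(pairs)) < 0.35, , drop = FALSE]
    if (nrow(pick) == 0) next
    got <- extract_wires(mk_net(pick))$wires
    want <- brute_wires(pick)
    norm <- function(l) sort(vapply(l, paste, character(1), collapse = "-"))
    expect_equal(norm(got), norm(want))
  }
})

test_that("cycles are reported separately rather than traversed", {
  nodes <- data.frame(id = 1:4, x = 0, y = 0, z = 0, height = 1,
                      kind = "water_O")
  ed <- solvmap:::empty_edge_table()
  cyc <- rbind(c(1, 2), c(2, 3), c(3, 1), c(3, 4))
  for (r in 1:4) ed[r, c("donor", "acceptor")] <- cyc[r, ]
  ed$ambiguous <- FALSE
  net <- structure(list(nodes = nodes, edges = ed, cell = cell),
                   class = "hbond_network")
  w <- extract_wires(net)
  expect_setequal(w$cycles, 1:3)
})
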