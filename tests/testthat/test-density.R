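cell16 <- unit_cell(16, 16, 16)

test_that("a single oxygen gives F(000) = 8 exactly and a conserved map", {
  sn <- fixed_atoms_snapshots(cell16, "O", c(8, 8, 8))
  sf <- structure_factors(sn, 2.0)
  f000_row <- which(rowSums(abs(sf$hkl)) == 0)
  expect_identical(length(f000_row), 1L)
  expect_equal(Re(sf$F[f000_row]), 8)
  expect_equal(Im(sf$F[f000_row]), 0)
  expect_equal(sf$F000, 8)
  m <- map_from_sf(sf)
  expect_equal(sum(m$values) * voxel_volume(m), 8, tolerance = 1e-9)
})

test_that("two atoms half a cell apart extinguish F(1,0,0)", {
  sn <- fixed_atoms_snapshots(cell16, c("O", "O"),
                              rbind(c(2, 5, 9), c(10, 5, 9)))
  sf <- structure_factors(sn, 2.0)
  r <- which(sf$hkl[, 1] == 1 & sf$hkl[, 2] == 0 & sf$hkl[, 3] == 0)
  expect_lt(Mod(sf$F[r]), 1e-12)
})

test_that("unknown elements are rejected by name", {
  sn <- fixed_atoms_snapshots(cell16, "XX", c(8, 8, 8))
  expect_error(structure_factors(sn, 2.0), "XX")
})

test_that("Friedel symmetry holds and maps are real", {
  sn <- fixed_atoms_snapshots(cell16, c("O", "H", "H"),
                              rbind(c(8, 8, 8), c(8.9, 8.2, 8), c(7.8, 8.9, 8)))
  sf <- structure_factors(sn, 2.0)
  key <- paste(sf$hkl[, 1], sf$hkl[, 2], sf$hkl[, 3])
  mate <- match(paste(-sf$hkl[, 1], -sf$hkl[, 2], -sf$hkl[, 3]), key)
  expect_true(all(!is.na(mate)))
  expect_equal(sf$F, Conj(sf$F[mate]), tolerance = 1e-12)
  m <- map_from_sf(sf)
  expect_lt(m$max_imag, 1e-9 * max(abs(m$values)))
})

test_that("a DC-only structure-factor set gives a constant map", {
  sn <- fixed_atoms_snapshots(cell16, "O", c(8, 8, 8))
  sf <- structure_factors(sn, 2.0)
  keep <- rowSums(abs(sf$hkl)) == 0
  sf$hkl <- sf$hkl[keep, , drop = FALSE]
  sf$F <- sf$F[keep]
  m <- map_from_sf(sf, c(16, 16, 16))
  expect_equal(as.vector(m$values), rep(8 / cell16$volume, 16^3),
               tolerance = 1e-12)
})

test_that("species selection counts electrons and preserves frames", {
  ens <- generate_water_wire(4, 2.8, "chain", 0.1, 6, seed = 2)
  sn <- ens$snapshots
  selO <- select_species(sn, "water_O")
  expect_equal(nrow(selO$atoms), 4)
  expect_equal(n_frames(selO), 6)
  expect_equal(structure_factors(selO, 2.0)$F000, 32)
  selH <- select_species(sn, "water_H_all")
  expect_equal(structure_factors(selH, 2.0)$F000, 8)
  selm <- select_species(sn, list(molecule = 2))
  expect_equal(nrow(selm$atoms), 3)
  expect_error(select_species(sn, list(molecule = 99)), "molecule")
  expect_warning(sel0 <- select_species(
    fixed_atoms_snapshots(cell16, "O", c(8, 8, 8)), "water_H1"), "empty")
})

test_that("conservation holds for every species map", {
  ens <- generate_water_wire(3, 2.8, "chain", 0.12, 8, seed = 6)
  for (sel in c("water_all", "water_O", "water_H1", "water_H2")) {
    sf <- structure_factors(select_species(ens$snapshots, sel), 2.0)
    m <- map_from_sf(sf)
    expect_equal(sum(m$values) * voxel_volume(m), sf$F000,
                 tolerance = 1e-6 * max(sf$F000, 1))
  }
})

test_that("frame averaging commutes with map synthesis (linearity)", {
  ens <- generate_water_wire(2, 2.8, "chain", 0.2, 5, seed = 8)
  sn <- ens$snapshots
  dims <- default_grid(sn$cell, 2.0)
  mean_map <- map_from_sf(structure_factors(sn, 2.0), dims)
  avg_map <- frame_averaged_map(sn, 2.0, dims)
  expect_equal(avg_map$values, mean_map$values,
               tolerance = 1e-9)
})

test_that("per-molecule maps add up to the all-water map", {
  ens <- generate_water_wire(3, 2.8, "chain", 0.15, 10, seed = 12)
  sn <- ens$snapshots
  dims <- default_grid(sn$cell, 2.0)
  total <- map_from_sf(structure_factors(select_species(sn, "water_all"), 2.0),
                       dims)
  acc <- 0
  for (mid in 1:3) acc <- acc + per_molecule_map(sn, mid, 2.0, dims)$values
  expect_equal(acc, total$values, tolerance = 1e-6 * max(abs(total$values)))
})

test_that("per-molecule maps of the exchange fixture sit on the shared site", {
  ex <- generate_exchange_site(c(8, 8, 8), 50, 100, jitter_sigma = 0,
                               seed = 2)
  sn <- ex$snapshots
  dims <- default_grid(sn$cell, 2.0)
  for (mid in 1:2) {
    sfm <- structure_factors(select_species(sn, list(molecule = mid)), 2.0)
    expect_equal(sfm$F000, 5)      # one water, present half the frames
    m <- map_from_sf(sfm, dims)
    pk <- find_peaks(m, 0.5)
    expect_equal(nrow(pk), 1)
    expect_lt(min_image_dist(sn$cell, as.matrix(pk[, c("x", "y", "z")]),
                             c(8, 8, 8)), 0.3)
  }
})

test_that("ensemble averaging only attenuates structure-factor amplitudes", {
  one <- generate_water_wire(1, direction_mode = "chain", jitter_sigma = 0,
                             n_frames = 1, seed = 3)
  jit <- generate_water_wire(1, direction_mode = "chain", jitter_sigma = 0.25,
                             n_frames = 10, seed = 3)
  sf1 <- structure_factors(one$snapshots, 2.0)
  sfj <- structure_factors(jit$snapshots, 2.0)
  expect_true(all(Mod(sfj$F) <= Mod(sf1$F) + 1e-6 * Mod(sf1$F) + 1e-9))
})

test_that("maps are invariant under lattice translation and wrapping", {
  ens <- generate_water_wire(2, 2.8, "chain", 0, 1, seed = 1)
  sn <- ens$snapshots
  dims <- default_grid(sn$cell, 2.0)
  m1 <- map_from_sf(structure_factors(sn, 2.0), dims)
  sn2 <- sn
  sn2$coords <- sn$coords + rep(c(sn$cell$a, 0, -2 * sn$cell$c),
                                each = prod(dim(sn$coords)[1:2]))
  m2 <- map_from_sf(structure_factors(sn2, 2.0), dims)
  expect_equal(m2$values, m1$values, tolerance = 1e-9)
})

test_that("sub-Nyquist grids are rejected with the required minimum", {
  sn <- fixed_atoms_snapshots(cell16, "O", c(8, 8, 8))
  sf <- structure_factors(sn, 2.0)
  expect_error(map_from_sf(sf, c(12, 12, 12)), "Nyquist")
})

test_that("peak height decreases strictly with site jitter", {
  heights <- sapply(c(0, 0.1, 0.2, 0.4), function(sig) {
    ens <- generate_water_wire(1, direction_mode = "chain",
                               jitter_sigma = sig,
                               n_frames = if (sig == 0) 1 else 400, seed = 21)
    m <- map_from_sf(structure_factors(
      select_species(ens$snapshots, "water_O"), 2.0))
    pk <- find_peaks(m, 0.5)
    expect_equal(nrow(pk), 1)
    pk$height
  })
  expect_true(all(diff(heights) < 0))
})
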