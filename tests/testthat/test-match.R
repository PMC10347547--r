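cell <- unit_cell(15, 15, 15)

make_peaks <- function(pos, heights, cell) {
  pos <- rbind(pos)
  pk <- data.frame(id = seq_len(nrow(pos)), x = pos[, 1], y = pos[, 2],
                   z = pos[, 3], height = heights, height_raw = heights,
                   i = 0L, j = 0L, k = 0L, species = "O",
                   stringsAsFactors = FALSE)
  attr(pk, "cell") <- cell
  class(pk) <- c("peak_list", "data.frame")
  pk
}

make_ref <- function(pos, cell, ids = seq_len(nrow(rbind(pos)))) {
  pos <- rbind(pos)
  solvmap:::new_reference_model(
    data.frame(water_id = ids, label = paste0("W", ids),
               x = pos[, 1], y = pos[, 2], z = pos[, 3],
               b = 15, occupancy = 1), cell = cell)
}

test_that("coincident peaks give r = 0, inner shells and full recovery", {
  set.seed(4)
  pos <- matrix(runif(15, 2, 13), 5, 3)
  ref <- make_ref(pos, cell)
  pk <- make_peaks(pos, rep(5, 5), cell)
  rep <- match_waters(pk, ref)
  expect_equal(rep$r, rep(0, 5))
  expect_true(all(rep$shell == "inner"))
  fr <- fraction_recovered(rep)
  expect_equal(fr$fraction, 1.0)
  expect_equal(fr$n_recovered, 5)
})

test_that("matching with no peaks yields Inf distances and distant shells", {
  ref <- make_ref(matrix(runif(9, 2, 13), 3, 3), cell)
  pk <- solvmap:::empty_peak_list(cell)
  rep <- match_waters(pk, ref)
  expect_true(all(is.infinite(rep$r)))
  expect_true(all(rep$shell == "distant"))
  expect_true(all(is.na(rep$peak_id)))
  expect_equal(fraction_recovered(rep)$fraction, 0)
})

test_that("nearest distances equal an all-pairs brute-force minimum", {
  set.seed(11)
  wpos <- matrix(runif(18, 0, 15), 6, 3)
  ppos <- matrix(runif(12, 0, 15), 4, 3)
  ref <- make_ref(wpos, cell)
  pk <- make_peaks(ppos, runif(4, 3, 6), cell)
  rep <- match_waters(pk, ref)
  oracle <- brute_min_dist(cell, wpos, ppos)
  expect_equal(rep$r, apply(oracle, 1, min), tolerance = 1e-10)
  # non-exclusive assignment: relabeling peaks leaves distances unchanged
  pk2 <- pk[4:1, ]; pk2$id <- 1:4
  attr(pk2, "cell") <- cell; class(pk2) <- class(pk)
  expect_equal(match_waters(pk2, ref)$r, rep$r)
})

test_that("shell classification applies the documented boundaries", {
  expect_equal(as.character(classify_shell(c(0, 0.25, 0.3, 0.45, 0.5, 0.9,
                                             1.0, 3, Inf))),
               c("inner", "inner", "middle", "middle", "outer", "outer",
                 "distant", "distant", "distant"))
  expect_error(classify_shell(-0.1), "non-negative")
  # total and monotone in r
  r <- sort(runif(50, 0, 2))
  sh <- as.integer(classify_shell(r))
  expect_true(all(diff(sh) >= 0))
  expect_false(anyNA(sh))
})

test_that("per-shell Pearson correlation matches the direct formula", {
  md <- c(5.1, 4.2, 6.3, 3.9, 5.8)
  ex <- c(0.9, 0.7, 1.4, 0.6, 1.1)
  rep <- data.frame(water_id = 1:5, r = c(0.1, 0.2, 0.1, 0.25, 0.15),
                    peak_id = 1:5, shell = classify_shell(c(0.1, 0.2, 0.1,
                                                            0.25, 0.15)),
                    md_height = md, exp_height = ex)
  class(rep) <- c("match_report", "data.frame")
  out <- shell_height_correlation(rep)
  manual <- sum((md - mean(md)) * (ex - mean(ex))) /
    sqrt(sum((md - mean(md))^2) * sum((ex - mean(ex))^2))
  expect_equal(unname(out["inner"]), manual, tolerance = 1e-12)
  expect_true(is.na(out["middle"]))

  # identical heights give r = 1; a single pair is undefined
  rep$exp_height <- rep$md_height
  expect_equal(unname(shell_height_correlation(rep)["inner"]), 1.0)
  rep$shell <- classify_shell(c(0.1, 0.4, 0.4, 0.4, 0.4))
  rep$exp_height <- ex
  expect_true(is.na(shell_height_correlation(rep)["inner"]))
})

test_that("experimental heights are interpolated from a supplied map", {
  pos <- rbind(c(5, 5, 5), c(9, 9, 9))
  ref <- make_ref(pos, cell)
  pk <- make_peaks(pos, c(5, 4), cell)
  m <- gaussian_blob_map(cell, pos, sigma = 0.8, amp = 2, dims = c(30, 30, 30))
  rep <- match_waters(pk, ref, experimental_map = m)
  expect_equal(rep$exp_height, as.vector(height_at(m, pos)))
})

test_that("fraction_recovered counts both cuts and is monotone in them", {
  pos <- matrix(seq(2, 13, length.out = 10), 10, 3)
  ref <- make_ref(pos, cell)
  # peaks only for the first half, at 0.4 A offset
  pk <- make_peaks(pos[1:5, ] + 0.4 / sqrt(3), c(3, 3, 3, 1, 1), cell)
  rep <- match_waters(pk, ref)
  fr <- fraction_recovered(rep, distance_cut = 1.0, height_cut = 2.08)
  expect_equal(fr$n_total, 10)
  expect_equal(fr$n_recovered, 3)   # 2 of 5 matched peaks are too weak
  # monotone: non-increasing in height cut, non-decreasing in distance cut
  f_h <- sapply(c(0.5, 1, 2.08, 3.5),
                function(h) fraction_recovered(rep, 1.0, h)$fraction)
  expect_true(all(diff(f_h) <= 0))
  f_d <- sapply(c(0, 0.2, 0.5, 1, 20),
                function(d) fraction_recovered(rep, d, 0.5)$fraction)
  expect_true(all(diff(f_d) >= 0))
  expect_error(fraction_recovered(rep[0, ]), "empty")
})

test_that("region membership and statistics match brute-force filtering", {
  set.seed(21)
  pos <- matrix(runif(45, 0, 15), 15, 3)
  h <- runif(15, 2, 8)
  pk <- make_peaks(pos, h, cell)
  ctr <- c(7, 7, 7)
  reg <- region_spec("ball", center = ctr, radius = 4)
  st <- region_stats(pk, reg)
  inside <- as.vector(brute_min_dist(cell, pos, ctr) <= 4)
  expect_equal(st$n, sum(inside))
  expect_equal(st$mean_peak_height, mean(h[inside]))

  # two disjoint regions partitioning the peaks recompose the global mean
  regA <- region_spec("A", ids = 1:7)
  regB <- region_spec("B", ids = 8:15)
  ref <- make_ref(pos, cell)
  repo <- match_waters(pk, ref)
  sA <- region_stats(repo, regA, ref); sB <- region_stats(repo, regB, ref)
  expect_equal((sA$n * sA$mean_peak_height + sB$n * sB$mean_peak_height) /
                 (sA$n + sB$n), mean(repo$md_height))

  empty <- region_stats(pk, region_spec("far", center = c(0, 0, 0),
                                        radius = 1e-6))
  expect_equal(empty$n, 0)
  expect_true(is.na(empty$mean_peak_height))
  expect_error(region_spec("bad"), "exactly one")
  expect_error(region_spec("bad", center = c(1, 1, 1), ids = 1L),
               "exactly one")
})

test_that("match distances are invariant under global lattice translation", {
  set.seed(3)
  wpos <- matrix(runif(9, 0, 15), 3, 3)
  ppos <- matrix(runif(9, 0, 15), 3, 3)
  ref <- make_ref(wpos, cell)
  r1 <- match_waters(make_peaks(ppos, rep(4, 3), cell), ref)$r
  shift <- c(15, -15, 30)
  ref2 <- make_ref(sweep(wpos, 2, shift, "+"), cell)
  r2 <- match_waters(make_peaks(sweep(ppos, 2, shift, "+"), rep(4, 3), cell),
                     ref2)$r
  expect_equal(r1, r2, tolerance = 1e-10)
})
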