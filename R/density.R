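# Species-resolved mean structure factors and absolute-scale map synthesis.
#
# For every frame i and selected atom set, F_i(hkl) = sum_atoms
# f_elem(|s|) exp(2 pi i h.x_frac); the returned structure factors are the
# arithmetic mean over frames. Density is the inverse Fourier sum
# rho(x) = (1/V) sum_hkl F(hkl) exp(-2 pi i h.x) evaluated on a grid by
# FFT, which puts the map on an absolute electron/A^3 scale: the zero-order
# coefficient F(000) is the (frame-averaged) electron count of the
# selection, so the map integrates to it exactly.

new_density_map <- function(cell, values, species = "all") {
  stopifnot(length(dim(values)) == 3, all(dim(values) >= 2))
  structure(list(cell = cell, values = values, species = species,
                 mean = mean(values),
                 sigma = stats::sd(as.vector(values))),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("density map [%s]: %d x %d x %d grid, mean %.4g, sigma %.4g e/A^3\n",
              x$species, d[1], d[2], d[3], x$mean, x$sigma))
  invisible(x)
}

#' Voxel volume of a density map
#' @param map A `density_map`.
#' @return Volume of one voxel in cubic Angstrom.
#' @export
voxel_volume <- function(map) map$cell$volume / prod(dim(map$values))

#' Select an atom species from a snapshot set
#'
#' Supported selectors: `"water_all"`, `"water_O"`, `"water_H1"`,
#' `"water_H2"`, `"water_H_all"`, or `list(molecule = id)` for a single
#' molecule. Molecule selection respects per-frame occupancy (an atom
#' contributes only in frames where it carries the requested molecule id),
#' so the zero-order electron count of a part-time molecule is its
#' occupancy-weighted value.
#'
#' @param snapshots A `snapshot_set`.
#' @param selector Selector string or `list(molecule = id)`.
#' @return A `snapshot_set` restricted to the selection, with an attached
#'   per-frame presence matrix and a `species` tag.
#' @export
select_species <- function(snapshots, selector) {
  at <- snapshots$atoms
  is_water <- at$resid %in% WATER_RESIDS
  if (is.list(selector)) {
    mid <- selector$molecule
    if (is.null(mid)) stop("list selector must name a molecule")
    if (!any(snapshots$molid == mid))
      stop("unknown molecule id ", mid)
    keep <- which(apply(snapshots$molid == mid, 2, any))
    present <- snapshots$molid[, keep, drop = FALSE] == mid
    tag <- paste0("molecule_", mid)
  } else {
    keep <- switch(selector,
      water_all = which(is_water),
      water_O = which(is_water & at$label == "O"),
      water_H1 = which(is_water & at$label == "H1"),
      water_H2 = which(is_water & at$label == "H2"),
      water_H_all = which(is_water & at$label %in% c("H1", "H2")),
      stop("unknown selector '", selector, "'"))
    present <- matrix(TRUE, n_frames(snapshots), length(keep))
    tag <- selector
  }
  out <- new_snapshot_set(snapshots$cell, at[keep, , drop = FALSE],
                          snapshots$coords[, keep, , drop = FALSE],
                          snapshots$molid[, keep, drop = FALSE])
  out$present <- present
  out$species <- tag
  if (length(keep) == 0) warning("empty selection '", tag, "': maps will be zero")
  out
}

# enumerate the Friedel-unique half set of Miller indices with |s| <= 1/d_min
enumerate_hkl <- function(cell, d_min) {
  hmax <- floor(cell$a / d_min) + 1L
  kmax <- floor(cell$b / d_min) + 1L
  lmax <- floor(cell$c / d_min) + 1L
  g <- as.matrix(expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = 0:lmax))
  half <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] >= 0)
  g <- g[half, , drop = FALSE]
  svec <- g %*% cell$frac          # rows of frac are a*, b*, c*
  smag <- sqrt(rowSums(svec^2))
  sel <- smag <= 1 / d_min + 1e-12
  list(hkl = g[sel, , drop = FALSE], s = smag[sel])
}

#' Mean structure factors of a snapshot set
#'
#' @param snapshots A `snapshot_set` (optionally from [select_species()]).
#' @param d_min Resolution cutoff in Angstrom (sharp sphere |s| <= 1/d_min).
#' @param frames Optional integer vector of frame indices to average over.
#' @return A `structure_factor_set` with the full Friedel-expanded
#'   reflection list, complex mean amplitudes in electrons, and `F000`.
#' @export
structure_factors <- function(snapshots, d_min, frames = NULL) {
  if (is.null(snapshots$cell)) stop("snapshot set has no unit cell")
  stopifnot(d_min > 0)
  cell <- snapshots$cell
  if (is.null(frames)) frames <- seq_len(n_frames(snapshots))
  nf <- length(frames)
  at <- snapshots$atoms
  na <- nrow(at)
  enum <- enumerate_hkl(cell, d_min)
  hkl <- enum$hkl
  nh <- nrow(hkl)
  Fhalf <- complex(real = rep(0, nh), imaginary = rep(0, nh))
  present <- snapshots$present
  if (is.null(present)) present <- matrix(TRUE, n_frames(snapshots), na)
  zs <- if (na > 0) electron_count(at$element) else numeric(0)
  F000 <- if (na > 0) mean(rowSums(sweep(present[frames, , drop = FALSE],
                                          2, zs, "*"))) else 0

  if (na > 0 && nf > 0) {
    # flatten frames x atoms into columns; weight = presence / n_frames
    fx <- matrix(0, 3, nf * na)
    for (k in 1:3) {
      ck <- snapshots$coords[frames, , k, drop = FALSE]
      dim(ck) <- dim(ck)[1:2]
      fx[k, ] <- as.vector(t(ck))
    }
    frx <- cell$frac %*% fx                     # fractional coords, 3 x (nf*na)
    w <- as.vector(t(present[frames, , drop = FALSE])) / nf
    elem_col <- rep(at$element, times = nf)
    chunk <- max(1L, floor(4e6 / (nf * na)))
    for (lo in seq(1L, nh, by = chunk)) {
      hi <- min(lo + chunk - 1L, nh)
      H <- hkl[lo:hi, , drop = FALSE]
      phase <- 2 * pi * (H %*% frx)             # chunk x (nf*na)
      re <- cos(phase); im <- sin(phase)
      acc_re <- matrix(0, hi - lo + 1L, 1)
      acc_im <- matrix(0, hi - lo + 1L, 1)
      for (el in unique(at$element)) {
        cols <- which(elem_col == el)
        fvals <- form_factor(el, enum$s[lo:hi])
        wre <- re[, cols, drop = FALSE] %*% (w[cols])
        wim <- im[, cols, drop = FALSE] %*% (w[cols])
        acc_re <- acc_re + fvals * wre
        acc_im <- acc_im + fvals * wim
      }
      Fhalf[lo:hi] <- complex(real = acc_re, imaginary = acc_im)
    }
  }
  # Friedel expansion F(-h) = conj(F(h))
  origin <- rowSums(abs(hkl)) == 0
  hkl_full <- rbind(hkl, -hkl[!origin, , drop = FALSE])
  F_full <- c(Fhalf, Conj(Fhalf[!origin]))
  s_full <- c(enum$s, enum$s[!origin])
  structure(list(cell = cell, d_min = d_min, hkl = hkl_full, F = F_full,
                 s = s_full, F000 = F000,
                 species = snapshots$species %||% "all"),
            class = "structure_factor_set")
}

#' @export
print.structure_factor_set <- function(x, ...) {
  cat(sprintf("structure factors [%s]: %d reflections to %.2f A, F000 = %.3f e\n",
              x$species, nrow(x$hkl), x$d_min, x$F000))
  invisible(x)
}

# smallest integer >= n whose prime factors are all in {2, 3, 5}
next_fft_friendly <- function(n) {
  n <- as.integer(ceiling(n))
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

#' Default FFT grid dimensions for a resolution cutoff
#'
#' Smallest FFT-friendly (2,3,5-smooth) dimensions giving a voxel spacing
#' of at most `d_min / oversample` along each axis. The default oversample
#' of 3 leaves at least three samples per resolution element, which
#' sub-voxel peak interpolation needs.
#'
#' @param cell A `unit_cell`.
#' @param d_min Resolution cutoff (A).
#' @param oversample Samples per d_min (default 3).
#' @return Integer vector of three grid dimensions.
#' @export
default_grid <- function(cell, d_min, oversample = 3) {
  vapply(c(cell$a, cell$b, cell$c),
         function(len) next_fft_friendly(oversample * len / d_min), integer(1))
}

#' Synthesize a density map from structure factors
#'
#' Inverse Fourier synthesis on an `nx` x `ny` x `nz` grid; voxel (i,j,k)
#' (0-based) is centred at fractional (i/nx, j/ny, k/nz). The result is in
#' e/A^3 and integrates over the cell to F000.
#'
#' @param sf A `structure_factor_set`.
#' @param dims Grid dimensions; default from [default_grid()].
#' @return A `density_map`.
#' @export
map_from_sf <- function(sf, dims = NULL) {
  cell <- sf$cell
  if (is.null(dims)) dims <- default_grid(cell, sf$d_min)
  dims <- as.integer(dims)
  lens <- c(cell$a, cell$b, cell$c)
  need <- ceiling(2 * lens / sf$d_min) + 1L
  if (any(lens / dims > sf$d_min / 2 + 1e-12) ||
      any(dims <= 2 * apply(abs(sf$hkl), 2, max)))
    stop("grid below Nyquist for d_min = ", sf$d_min,
         "; need at least ", paste(need, collapse = " x "))
  Farr <- array(complex(real = 0, imaginary = 0), dims)
  idx <- cbind(sf$hkl[, 1] %% dims[1], sf$hkl[, 2] %% dims[2],
               sf$hkl[, 3] %% dims[3]) + 1L
  Farr[idx] <- sf$F
  rho_c <- stats::fft(Farr) / cell$volume
  rho <- Re(rho_c)
  attr_im <- max(abs(Im(rho_c)))
  m <- new_density_map(cell, rho, species = sf$species)
  m$max_imag <- attr_im
  m
}

#' Density map of a single molecule
#'
#' The general pipeline applied to a single-molecule selection: structure
#' factors of that molecule's atoms (occupancy-weighted if it occupies its
#' site only part of the time), then FFT synthesis.
#'
#' @param snapshots A `snapshot_set`.
#' @param molecule_id Molecule id to isolate.
#' @param d_min Resolution cutoff (A).
#' @param dims Optional grid dimensions.
#' @param frames Optional frame subset.
#' @return A `density_map`.
#' @export
per_molecule_map <- function(snapshots, molecule_id, d_min, dims = NULL,
                             frames = NULL) {
  sel <- select_species(snapshots, list(molecule = molecule_id))
  map_from_sf(structure_factors(sel, d_min, frames = frames), dims)
}

#' Average of per-frame density maps (linearity helper)
#'
#' Frame-by-frame synthesis then averaging; by linearity of the Fourier
#' transform this equals the map of frame-averaged structure factors and is
#' used as an internal consistency check.
#'
#' @inheritParams per_molecule_map
#' @return A `density_map`.
#' @export
frame_averaged_map <- function(snapshots, d_min, dims = NULL, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(snapshots))
  acc <- NULL
  for (f in frames) {
    m <- map_from_sf(structure_factors(snapshots, d_min, frames = f), dims)
    acc <- if (is.null(acc)) m$values else acc + m$values
    if (is.null(dims)) dims <- dim(m$values)
  }
  new_density_map(snapshots$cell, acc / length(frames),
                  species = snapshots$species %||% "all")
}
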