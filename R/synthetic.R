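# Synthetic crystalline water ensembles with machine-readable ground truth.
#
# Waters are rigid (TIP3P internal geometry: O-H 0.9572 A, H-O-H 104.52 deg);
# per-frame positions are site means plus isotropic Gaussian jitter, and
# hydrogen orientations follow one of three modes (fixed chain, free-rotor
# cone, or fully random per frame).  The generator returns both the
# coordinate ensemble and the ground-truth site/network description that
# downstream density, matching and hydrogen-bond analyses are tested against.

OH_BOND <- 0.9572
HOH_ANGLE <- 104.52

# deterministic 32-bit stream split for per-stage seeds
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 16807) %% 2147483647) + 1L
}

# orthonormal pair perpendicular to unit vector u
perp_basis <- function(u) {
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  w1 <- ref - sum(ref * u) * u
  w1 <- w1 / sqrt(sum(w1^2))
  w2 <- c(u[2] * w1[3] - u[3] * w1[2],
          u[3] * w1[1] - u[1] * w1[3],
          u[1] * w1[2] - u[2] * w1[1])
  list(w1 = w1, w2 = w2)
}

# uniform random rotation matrix (quaternion method)
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
}

# hydrogen offsets for a rigid water given the two O->H unit directions
h_offsets <- function(d1, d2) rbind(d1, d2) * OH_BOND

# fixed H1/H2 directions: H1 along u, H2 at the tetrahedral-like water angle
# from u, in the plane spanned by u and a deterministic perpendicular
fixed_h_dirs <- function(u) {
  pb <- perp_basis(u)
  ang <- HOH_ANGLE * pi / 180
  d2 <- cos(ang) * u + sin(ang) * pb$w1
  list(d1 = u, d2 = d2)
}

new_snapshot_set <- function(cell, atoms, coords, molid = NULL) {
  n_frames <- dim(coords)[1]; n_atoms <- dim(coords)[2]
  stopifnot(nrow(atoms) == n_atoms, dim(coords)[3] == 3)
  if (is.null(molid))
    molid <- matrix(rep(atoms$molid, each = n_frames), n_frames, n_atoms)
  structure(list(cell = cell, atoms = atoms, coords = coords, molid = molid),
            class = "snapshot_set")
}

#' @export
print.snapshot_set <- function(x, ...) {
  cat(sprintf("snapshot set: %d frames x %d atoms (%d molecules)\n",
              n_frames(x), nrow(x$atoms), length(unique(as.vector(x$molid)))))
  print(x$cell)
  invisible(x)
}

#' Number of frames in a snapshot set
#' @param snapshots A `snapshot_set`.
#' @export
n_frames <- function(snapshots) dim(snapshots$coords)[1]

#' Generate a synthetic water wire ensemble
#'
#' Places `n_sites` water oxygens on a line at the given spacing inside an
#' orthorhombic box (padding of `pad` Angstrom on every side), then samples
#' `n_frames` frames with isotropic Gaussian positional jitter and rigid
#' internal geometry.  Hydrogen orientation depends on `direction_mode`:
#'
#' * `"chain"`: H1 of each site points at the next site's mean oxygen (the
#'   last site donates nothing along the wire); H2 lies at the water angle
#'   from H1, tilted off the wire axis. This produces an ordered donor chain
#'   whose directed hydrogen bonds i -> i+1 form the ground-truth network.
#' * `"rotor"`: both hydrogens precess about the would-be donation axis
#'   (uniform cone angle per frame), smearing the hydrogen density over a
#'   cone; no directed ground-truth edges.
#' * `"random"`: a fresh uniform random orientation every frame; the
#'   null/no-network control.
#'
#' @param n_sites Number of water sites (>= 1).
#' @param spacing O-O spacing along the wire in Angstrom (must lie in the
#'   hydrogen-bond window 2.4--3.5 A for chain mode).
#' @param direction_mode One of "chain", "random", "rotor".
#' @param jitter_sigma Isotropic positional standard deviation per axis (A).
#' @param n_frames Number of frames to sample.
#' @param seed Integer seed; identical arguments and seed reproduce the
#'   ensemble exactly.
#' @param pad Box padding around the wire (A), default 8.
#' @param cell Optional `unit_cell` overriding the default box.
#' @return A list with elements `snapshots` (a `snapshot_set`), `truth`
#'   (list of per-site ground-truth descriptions) and `network` (the
#'   ground-truth directed hydrogen-bond network).
#' @export
generate_water_wire <- function(n_sites, spacing = 2.8,
                                direction_mode = c("chain", "random", "rotor"),
                                jitter_sigma = 0, n_frames = 1, seed = 1,
                                pad = 8, cell = NULL) {
  direction_mode <- match.arg(direction_mode)
  stopifnot(n_sites >= 1, n_frames >= 1, jitter_sigma >= 0)
  if (direction_mode == "chain" && n_sites > 1 &&
      (spacing < 2.4 || spacing > 3.5))
    stop("chain mode requires an O-O spacing inside the hydrogen-bond window [2.4, 3.5] A")
  span <- (n_sites - 1) * spacing
  if (is.null(cell)) {
    cell <- unit_cell(span + 2 * pad, 2 * pad, 2 * pad)
  }
  if (span >= cell$a)
    stop("wire of length ", span, " A does not fit in the cell (a = ", cell$a, " A)")

  means <- cbind(pad + (seq_len(n_sites) - 1) * spacing,
                 rep(cell$b / 2, n_sites), rep(cell$c / 2, n_sites))
  # donation axis: toward the next site; the last site points off-wire
  axes <- lapply(seq_len(n_sites), function(i) {
    if (i < n_sites) c(1, 0, 0) else c(0, 1, 0)
  })

  truth <- lapply(seq_len(n_sites), function(i) {
    dirs <- switch(direction_mode,
      chain = {
        fd <- fixed_h_dirs(axes[[i]])
        if (i < n_sites) list(fd$d1) else list()
      },
      rotor = list(axes[[i]]),
      random = list())
    list(site_id = i, mean_O_position = means[i, ],
         H_mode = switch(direction_mode, chain = "fixed", rotor = "rotor",
                         random = "rotor"),
         H_directions = dirs, jitter_sigma = jitter_sigma,
         occupying_molecule_schedule = list(list(frames = c(0, n_frames),
                                                 molecule = i)))
  })
  edges <- if (direction_mode == "chain" && n_sites > 1) {
    data.frame(donor = seq_len(n_sites - 1), acceptor = 2:n_sites,
               expected_OO_A = spacing)
  } else {
    data.frame(donor = integer(0), acceptor = integer(0),
               expected_OO_A = numeric(0))
  }
  network <- structure(list(nodes = seq_len(n_sites), edges = edges),
                       class = "ground_truth_network")

  atoms <- data.frame(
    element = rep(c("O", "H", "H"), n_sites),
    label = rep(c("O", "H1", "H2"), n_sites),
    molid = rep(seq_len(n_sites), each = 3),
    resid = "HOH", chain = "A", stringsAsFactors = FALSE)

  set.seed(derive_seed(seed, 0L))
  coords <- array(0, c(n_frames, 3 * n_sites, 3))
  # draw jitter for all frames/sites first, then orientations, so that the
  # stream layout is independent of direction mode
  jit <- array(stats::rnorm(n_frames * n_sites * 3, sd = jitter_sigma),
               c(n_frames, n_sites, 3))
  if (jitter_sigma == 0) jit[] <- 0
  for (i in seq_len(n_sites)) {
    u <- axes[[i]]
    fd <- fixed_h_dirs(u)
    pb <- perp_basis(u)
    half <- (HOH_ANGLE / 2) * pi / 180
    for (f in seq_len(n_frames)) {
      o <- means[i, ] + jit[f, i, ]
      dirs <- switch(direction_mode,
        chain = rbind(fd$d1, fd$d2),
        rotor = {
          th <- stats::runif(1, 0, 2 * pi)
          sw <- cos(th) * pb$w1 + sin(th) * pb$w2
          rbind(cos(half) * u + sin(half) * sw,
                cos(half) * u - sin(half) * sw)
        },
        random = {
          R <- random_rotation()
          rbind(as.vector(R %*% fd$d1), as.vector(R %*% fd$d2))
        })
      base <- (i - 1) * 3
      coords[f, base + 1, ] <- o
      coords[f, base + 2, ] <- o + dirs[1, ] * OH_BOND
      coords[f, base + 3, ] <- o + dirs[2, ] * OH_BOND
    }
  }
  list(snapshots = new_snapshot_set(cell, atoms, coords),
       truth = truth, network = network)
}

#' Generate a scripted water-exchange fixture
#'
#' One water site whose occupying molecule switches identity at a scripted
#' frame: molecule 1 occupies frames `[0, swap_frame)` and molecule 2 the
#' rest (0-based frame indices, matching the recorded truth schedule).
#' Both molecules sample the same spatial distribution, so density maps see
#' a single stable site while occupancy analysis sees one exchange event.
#'
#' @param site Cartesian mean oxygen position (length-3, Angstrom).
#' @param swap_frame 0-based frame index of the exchange; must satisfy
#'   `0 < swap_frame < n_frames`.
#' @param n_frames Total frames.
#' @param jitter_sigma Positional jitter per axis (A).
#' @param seed Integer seed.
#' @param cell Optional `unit_cell`; defaults to a box padding the site by 8 A.
#' @return A list with `snapshots` (a `snapshot_set`) and `truth` (the
#'   site's ground-truth description including the occupancy schedule).
#' @export
generate_exchange_site <- function(site, swap_frame, n_frames,
                                   jitter_sigma = 0.1, seed = 1, cell = NULL) {
  stopifnot(length(site) == 3, n_frames >= 2)
  if (!(swap_frame > 0 && swap_frame < n_frames))
    stop("swap_frame must lie strictly inside (0, n_frames)")
  if (is.null(cell)) cell <- unit_cell(16, 16, 16)
  atoms <- data.frame(element = c("O", "H", "H"), label = c("O", "H1", "H2"),
                      molid = 1L, resid = "HOH", chain = "A",
                      stringsAsFactors = FALSE)
  fd <- fixed_h_dirs(c(1, 0, 0))
  set.seed(derive_seed(seed, 1L))
  jit <- matrix(stats::rnorm(n_frames * 3, sd = jitter_sigma), n_frames, 3)
  if (jitter_sigma == 0) jit[] <- 0
  coords <- array(0, c(n_frames, 3, 3))
  for (f in seq_len(n_frames)) {
    o <- site + jit[f, ]
    coords[f, 1, ] <- o
    coords[f, 2, ] <- o + fd$d1 * OH_BOND
    coords[f, 3, ] <- o + fd$d2 * OH_BOND
  }
  molid <- matrix(ifelse(seq_len(n_frames) - 1 < swap_frame, 1L, 2L),
                  n_frames, 3)
  truth <- list(site_id = 1L, mean_O_position = site, H_mode = "fixed",
                H_directions = list(fd$d1), jitter_sigma = jitter_sigma,
                occupying_molecule_schedule = list(
                  list(frames = c(0, swap_frame), molecule = 1L),
                  list(frames = c(swap_frame, n_frames), molecule = 2L)))
  list(snapshots = new_snapshot_set(cell, atoms, coords, molid),
       truth = truth)
}

#' Reference model from ground-truth sites
#'
#' Exports one reference water per ground-truth site at its mean oxygen
#' position, mimicking the crystallographic-waters side of a peak-matching
#' comparison. The placeholder B-factor is the isotropic value implied by
#' the site jitter (B = 8 pi^2 sigma^2).
#'
#' @param truth List of per-site ground-truth descriptions (as produced by
#'   [generate_water_wire()]).
#' @param cell The `unit_cell` the sites live in.
#' @return A `reference_model`.
#' @export
truth_to_reference <- function(truth, cell) {
  if (length(truth) == 0) stop("empty ground truth")
  pos <- t(vapply(truth, function(s) as.numeric(s$mean_O_position), numeric(3)))
  waters <- data.frame(
    water_id = vapply(truth, function(s) as.integer(s$site_id), integer(1)),
    label = paste0("W", vapply(truth, function(s) s$site_id, numeric(1))),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    b = 8 * pi^2 * vapply(truth, function(s) s$jitter_sigma^2, numeric(1)),
    occupancy = 1, stringsAsFactors = FALSE)
  new_reference_model(waters = waters, cell = cell)
}

#' Write ground truth to JSON
#' @param truth Per-site truth list (and/or `network`).
#' @param network Optional `ground_truth_network`.
#' @param path Output file.
#' @export
write_truth_json <- function(truth, network = NULL, path) {
  jsonlite::write_json(list(sites = truth, network = unclass(network)), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
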