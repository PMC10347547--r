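#' Unit cell
#'
#' Construct a crystallographic unit cell from lengths (Angstrom) and angles
#' (degrees). The orthogonalization matrix follows the PDB convention: the
#' a axis lies along Cartesian x and b lies in the xy plane.
#'
#' @param a,b,c Cell edge lengths in Angstrom.
#' @param alpha,beta,gamma Cell angles in degrees.
#' @return An object of class `unit_cell` with the fractional-to-Cartesian
#'   matrix (`orth`), its inverse (`frac`), and the cell volume in cubic
#'   Angstrom.
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c))
  if (any(c(a, b, c) <= 0)) stop("cell lengths must be positive")
  if (any(c(alpha, beta, gamma) <= 0) || any(c(alpha, beta, gamma) >= 180))
    stop("cell angles must lie in (0, 180) degrees")
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  v2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v2 <= 0) stop("degenerate cell: angles do not define a positive volume")
  v <- sqrt(v2)
  orth <- matrix(c(
    a, b * cg, c * cb,
    0, b * sg, c * (ca - cb * cg) / sg,
    0, 0,      c * v / sg), nrow = 3, byrow = TRUE)
  structure(list(
    a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
    orth = orth, frac = solve(orth), volume = a * b * c * v),
    class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell  a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f  V=%.1f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

is_orthorhombic <- function(cell, tol = 1e-8) {
  all(abs(c(cell$alpha, cell$beta, cell$gamma) - 90) < tol)
}

#' Convert between Cartesian and fractional coordinates
#'
#' @param cell A `unit_cell`.
#' @param xyz An n x 3 matrix of coordinates.
#' @return An n x 3 matrix in the other convention.
#' @export
cart_to_frac <- function(cell, xyz) {
  xyz <- rbind(xyz)
  t(cell$frac %*% t(xyz))
}

#' @rdname cart_to_frac
#' @export
frac_to_cart <- function(cell, xyz) {
  xyz <- rbind(xyz)
  t(cell$orth %*% t(xyz))
}

#' Minimum-image pairwise distances
#'
#' Distances between two sets of Cartesian positions under the periodic
#' boundary conditions of `cell`, using the minimum-image convention.
#' For strongly non-orthogonal cells the wrapped fractional difference is
#' additionally checked against the 26 neighbouring lattice translations.
#'
#' @param cell A `unit_cell`.
#' @param x An n x 3 matrix (or length-3 vector) of Cartesian positions.
#' @param y An m x 3 matrix (or length-3 vector) of Cartesian positions.
#' @return An n x m matrix of distances in Angstrom.
#' @export
min_image_dist <- function(cell, x, y) {
  v <- min_image_vec(cell, x, y)
  sqrt(v$d2)
}

# Minimum-image displacement vectors y - x (Cartesian). Returns list with
# n*m x 3 matrix `vec` (row-major over pairs: pair (i,j) at (i-1)*m + j)
# and squared distances `d2` as an n x m matrix.
min_image_vec <- function(cell, x, y) {
  x <- rbind(x); y <- rbind(y)
  n <- nrow(x); m <- nrow(y)
  fx <- cart_to_frac(cell, x); fy <- cart_to_frac(cell, y)
  # wrapped fractional differences for all pairs
  df <- matrix(0, n * m, 3)
  for (k in 1:3) {
    d <- rep(fy[, k], times = n) - rep(fx[, k], each = m)
    df[, k] <- d - round(d)
  }
  if (is_orthorhombic(cell)) {
    vec <- frac_to_cart(cell, df)
    d2 <- rowSums(vec^2)
  } else {
    # search neighbouring images for the true minimum
    best <- rep(Inf, n * m)
    vec <- matrix(0, n * m, 3)
    shifts <- as.matrix(expand.grid(sx = -1:1, sy = -1:1, sz = -1:1))
    for (s in seq_len(nrow(shifts))) {
      cand <- frac_to_cart(cell, sweep(df, 2, shifts[s, ], "+"))
      d2c <- rowSums(cand^2)
      upd <- d2c < best
      best[upd] <- d2c[upd]
      vec[upd, ] <- cand[upd, , drop = FALSE]
    }
    d2 <- best
  }
  list(vec = vec, d2 = matrix(d2, n, m, byrow = TRUE))
}

# wrap Cartesian coordinates into the primary cell [0,1)^3 (fractional)
wrap_cart <- function(cell, xyz) {
  f <- cart_to_frac(cell, xyz)
  frac_to_cart(cell, f - floor(f))
}
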