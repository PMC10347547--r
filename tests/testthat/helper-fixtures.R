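# Shared fixture builders (everything generated in code; no data files).

# a snapshot set holding arbitrary atoms at fixed positions, one frame
fixed_atoms_snapshots <- function(cell, elements, positions,
                                  labels = elements, n_frames = 1) {
  positions <- rbind(positions)
  atoms <- data.frame(element = elements, label = labels,
                      molid = seq_along(elements), resid = "HOH",
                      chain = "A", stringsAsFactors = FALSE)
  coords <- array(0, c(n_frames, nrow(positions), 3))
  for (f in seq_len(n_frames)) coords[f, , ] <- positions
  solvmap:::new_snapshot_set(cell, atoms, coords)
}

# density map with one or more periodic Gaussian blobs (analytic fixture)
gaussian_blob_map <- function(cell, centers, sigma = 0.5, amp = 5,
                              dims = c(32, 32, 32)) {
  centers <- rbind(centers)
  vals <- array(0, dims)
  fr <- expand.grid(i = (seq_len(dims[1]) - 1) / dims[1],
                    j = (seq_len(dims[2]) - 1) / dims[2],
                    k = (seq_len(dims[3]) - 1) / dims[3])
  pos <- frac_to_cart(cell, as.matrix(fr))
  for (c_i in seq_len(nrow(centers))) {
    d2 <- min_image_dist(cell, pos, centers[c_i, ])^2
    vals <- vals + array(amp * exp(-d2 / (2 * sigma^2)), dims)
  }
  solvmap:::new_density_map(cell, vals, species = "blob")
}

# brute-force minimum-image distance via explicit 27-image search
brute_min_dist <- function(cell, x, y) {
  x <- rbind(x); y <- rbind(y)
  out <- matrix(Inf, nrow(x), nrow(y))
  sh <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  L <- t(cell$orth %*% t(sh))     # lattice translations, general cells
  for (i in seq_len(nrow(x))) for (j in seq_len(nrow(y)))
    for (s in seq_len(nrow(L)))
      out[i, j] <- min(out[i, j], sqrt(sum((y[j, ] + L[s, ] - x[i, ])^2)))
  out
}
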