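# CCP4/MRC density-map I/O (mode 2, 32-bit float), written and read with
# explicit axis-order support. No installed R package reads this container,
# so the 1024-byte header is assembled directly.

#' Write a density map as CCP4/MRC (mode 2)
#'
#' @param map A `density_map`.
#' @param path Output path.
#' @param axis_order Permutation of 1:3 giving which cell axis runs fastest,
#'   medium, slowest in the file (MAPC/MAPR/MAPS). Default `c(1, 2, 3)`.
#' @export
write_map <- function(map, path, axis_order = c(1, 2, 3)) {
  stopifnot(inherits(map, "density_map"), setequal(axis_order, 1:3))
  vals <- aperm(map$values, axis_order)
  dims <- dim(vals)
  cell <- map$cell
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(dims)                                   # NC NR NS
  wi(2L)                                     # MODE 2 = float32
  wi(c(0L, 0L, 0L))                          # NCSTART NRSTART NSSTART
  wi(dim(map$values))                        # MX MY MZ (full-cell sampling)
  wf(c(cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma))
  wi(axis_order)                             # MAPC MAPR MAPS
  wf(c(min(map$values), max(map$values), mean(map$values)))
  wi(1L)                                     # ISPG
  wi(0L)                                     # NSYMBT
  wi(rep(0L, 25))                            # EXTRA (words 26-50)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.vector(map$values)))       # RMS
  wi(1L)                                     # NLABL
  writeChar(formatC("solvmap density map", width = -800), con,
            nchars = 800, eos = NULL)
  writeBin(as.numeric(as.vector(vals)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a CCP4/MRC density map
#'
#' Values are returned in (x, y, z) axis order regardless of the stored
#' MAPC/MAPR/MAPS permutation; map statistics are recomputed from the data.
#'
#' @param path Path to a `.ccp4`/`.mrc` file.
#' @return A `density_map`.
#' @export
read_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  dims <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("unsupported MRC mode ", mode, " (only mode 2 is read)")
  ri(3)                    # starts
  mxyz <- ri(3)
  cellpar <- rf(6)
  axis_order <- ri(3)
  if (!setequal(axis_order, 1:3) || any(dims <= 0) ||
      any(!is.finite(cellpar)) || any(cellpar[1:3] <= 0))
    stop("corrupt CCP4/MRC header in ", path)
  rf(3)                    # min max mean
  ri(2)                    # ispg nsymbt
  ri(25)                   # extra
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "MAP "))
    stop("corrupt CCP4/MRC header in ", path, " (missing MAP magic)")
  readBin(con, "raw", 4)   # machine stamp
  rf(1)                    # rms
  ri(1)                    # nlabl
  readChar(con, 800, useBytes = TRUE)
  n <- prod(dims)
  vals <- rf(n)
  if (length(vals) != n) stop("truncated map data in ", path)
  arr <- array(vals, dims)
  # un-permute: stored axis k corresponds to cell axis axis_order[k]
  arr <- aperm(arr, order(axis_order))
  cell <- unit_cell(cellpar[1], cellpar[2], cellpar[3],
                    cellpar[4], cellpar[5], cellpar[6])
  new_density_map(cell, arr, species = "unknown")
}
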