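# Reference-structure and snapshot I/O.
#
# Reference structures (PDB/mmCIF) are parsed with bio3d; the CRYST1/_cell
# records, which bio3d does not expose, are scanned from the file directly.
# Snapshot sets are written as multi-model PDB by a fixed-width formatter
# (per-frame residue numbering is needed for exchange fixtures, which
# bio3d's writer cannot vary across models) and read back through bio3d.

new_reference_model <- function(waters, protein_atoms = NULL, cell = NULL,
                                space_group = "P 1") {
  stopifnot(is.data.frame(waters))
  if (nrow(waters) > 0) {
    if (anyDuplicated(waters$water_id)) stop("water ids must be unique")
    if (any(!is.finite(as.matrix(waters[, c("x", "y", "z")]))))
      stop("water positions must be finite")
    if (any(waters$occupancy <= 0 | waters$occupancy > 1))
      stop("occupancies must lie in (0, 1]")
  }
  structure(list(waters = waters, protein_atoms = protein_atoms,
                 cell = cell, space_group = space_group),
            class = "reference_model")
}

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf("reference model: %d waters, %d protein atoms, cell %s\n",
              nrow(x$waters),
              if (is.null(x$protein_atoms)) 0L else nrow(x$protein_atoms),
              if (is.null(x$cell)) "absent" else
                sprintf("%.2f x %.2f x %.2f A", x$cell$a, x$cell$b, x$cell$c)))
  invisible(x)
}

scan_cryst1 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hit <- grep("^CRYST1", lines, value = TRUE)
  if (length(hit) == 0) return(NULL)
  f <- hit[1]
  vals <- suppressWarnings(as.numeric(c(
    substr(f, 7, 15), substr(f, 16, 24), substr(f, 25, 33),
    substr(f, 34, 40), substr(f, 41, 47), substr(f, 48, 54))))
  if (any(is.na(vals))) stop("malformed CRYST1 record in ", path)
  sg <- trimws(substr(f, 56, 66))
  list(cell = unit_cell(vals[1], vals[2], vals[3], vals[4], vals[5], vals[6]),
       space_group = if (nzchar(sg)) sg else "P 1")
}

scan_cif_cell <- function(path) {
  lines <- readLines(path, warn = FALSE)
  get1 <- function(tag) {
    hit <- grep(paste0("^_cell[._]", tag), lines, value = TRUE)
    if (length(hit) == 0) return(NA_real_)
    suppressWarnings(as.numeric(strsplit(trimws(hit[1]), "[[:space:]]+")[[1]][2]))
  }
  vals <- c(get1("length_a"), get1("length_b"), get1("length_c"),
            get1("angle_alpha"), get1("angle_beta"), get1("angle_gamma"))
  if (any(is.na(vals))) return(NULL)
  list(cell = unit_cell(vals[1], vals[2], vals[3], vals[4], vals[5], vals[6]),
       space_group = "P 1")
}

WATER_RESIDS <- c("HOH", "WAT", "DOD", "H2O", "TIP", "SOL")

#' Read a reference structure (PDB or mmCIF)
#'
#' All water residues become reference waters; everything else is retained
#' as optional protein/hetero atoms. The unit cell and space group are
#' parsed from CRYST1 (or the mmCIF `_cell` items) when present; a missing
#' cell is allowed and flagged by `cell = NULL` -- map-based operations then
#' require an explicit cell.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @param keep_protein Keep non-water atoms (default TRUE).
#' @return A `reference_model`.
#' @export
read_reference <- function(path, keep_protein = TRUE) {
  is_cif <- grepl("\\.cif$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    if (is_cif) bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) stop("cannot parse '", path, "': ", conditionMessage(e)))
  at <- pdb$atom
  wat <- at[at$resid %in% WATER_RESIDS &
              toupper(trimws(at$elesy)) %in% c("O", ""), , drop = FALSE]
  # waters modelled O-only in references; if hydrogens present keep O rows
  if (nrow(wat) == 0)
    wat <- at[at$resid %in% WATER_RESIDS & at$elety == "O", , drop = FALSE]
  waters <- data.frame(
    water_id = seq_len(nrow(wat)),
    label = paste0("W", wat$resno),
    x = wat$x, y = wat$y, z = wat$z,
    b = ifelse(is.na(wat$b), 0, wat$b),
    occupancy = ifelse(is.na(wat$o), 1, wat$o),
    stringsAsFactors = FALSE)
  prot <- NULL
  if (keep_protein) {
    pa <- at[!(at$resid %in% WATER_RESIDS), , drop = FALSE]
    if (nrow(pa) > 0)
      prot <- data.frame(resid = pa$resid, resno = pa$resno, chain = pa$chain,
                         atom = pa$elety, element = toupper(trimws(pa$elesy)),
                         x = pa$x, y = pa$y, z = pa$z,
                         stringsAsFactors = FALSE)
  }
  cr <- if (is_cif) scan_cif_cell(path) else scan_cryst1(path)
  new_reference_model(waters = waters, protein_atoms = prot,
                      cell = cr$cell, space_group = cr$space_group %||% "P 1")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pdb_atom_line <- function(serial, name, resid, chain, resno, xyz, occ, b, elem) {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000, nm, resid, chain, resno %% 10000,
          xyz[1], xyz[2], xyz[3], occ, b, elem)
}

cryst1_line <- function(cell, space_group = "P 1") {
  sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
          cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma,
          space_group, 1L)
}

#' Write a reference model as PDB
#' @param ref A `reference_model`.
#' @param path Output path.
#' @export
write_reference <- function(ref, path) {
  out <- character(0)
  if (!is.null(ref$cell)) out <- cryst1_line(ref$cell, ref$space_group)
  w <- ref$waters
  for (i in seq_len(nrow(w)))
    out <- c(out, pdb_atom_line(i, "O", "HOH", "A", w$water_id[i],
                                c(w$x[i], w$y[i], w$z[i]),
                                w$occupancy[i], w$b[i], "O"))
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}

#' Write a snapshot set as multi-model PDB
#'
#' One MODEL/ENDMDL block per frame, residue name HOH, atom names O/H1/H2,
#' residue number = occupying molecule id (which may vary across frames for
#' exchange fixtures). A CRYST1 record carries the cell.
#'
#' @param snapshots A `snapshot_set`.
#' @param path Output path.
#' @export
write_snapshots <- function(snapshots, path) {
  at <- snapshots$atoms
  nf <- n_frames(snapshots)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(cryst1_line(snapshots$cell), con)
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    lines <- vapply(seq_len(nrow(at)), function(i) {
      pdb_atom_line(i, at$label[i], at$resid[i], at$chain[i],
                    snapshots$molid[f, i], snapshots$coords[f, i, ],
                    1, 0, at$element[i])
    }, character(1))
    writeLines(c(lines, "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a snapshot set from a multi-model PDB
#'
#' Frames are taken in file order; molecule ids come from (chain, residue
#' number), per model. All models must contain the same atom list.
#'
#' @param path Path to a multi-model PDB file.
#' @param water_only Drop non-water atoms (default TRUE).
#' @return A `snapshot_set`.
#' @export
read_snapshots <- function(path, water_only = TRUE) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e)
                    stop("cannot parse '", path, "': ", conditionMessage(e)))
  at <- pdb$atom
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  if (nf < 1 || nrow(at) == 0) stop("no models found in ", path)
  keep <- if (water_only) which(at$resid %in% WATER_RESIDS) else seq_len(nrow(at))
  if (length(keep) == 0) stop("no water atoms found in ", path)
  at <- at[keep, , drop = FALSE]
  na <- nrow(at)
  coords <- array(0, c(nf, na, 3))
  for (k in 1:3)
    coords[, , k] <- xyz[, 3 * (keep - 1) + k, drop = FALSE]
  elem <- toupper(trimws(at$elesy))
  elem[!nzchar(elem)] <- substr(trimws(at$elety[!nzchar(elem)]), 1, 1)
  chain <- ifelse(is.na(at$chain), "A", at$chain)
  molid_static <- as.integer(factor(paste(chain, at$resno)))
  atoms <- data.frame(element = elem, label = trimws(at$elety),
                      molid = molid_static, resid = at$resid, chain = chain,
                      stringsAsFactors = FALSE)
  molid <- read_model_resno(path, keep, nf, na, chain)
  if (is.null(molid))
    molid <- matrix(rep(molid_static, each = nf), nf, na)
  cr <- scan_cryst1(path)
  cell <- cr$cell
  if (is.null(cell)) warning("no CRYST1 record in ", path,
                             "; cell must be supplied before map operations")
  new_snapshot_set(cell %||% NULL, atoms, coords, molid)
}

# per-model residue numbers (only needed when they differ across models);
# returns NULL when numbering is constant
read_model_resno <- function(path, keep, nf, na, chain) {
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM|HETATM)", lines)
  resno <- suppressWarnings(as.integer(substr(lines[is_atom], 23, 26)))
  per_model <- length(resno) / nf
  if (per_model != round(per_model)) stop("models differ in atom count in ", path)
  m <- matrix(resno, nrow = nf, byrow = TRUE)[, keep, drop = FALSE]
  if (all(sweep(m, 2, m[1, ], "==") == TRUE)) return(NULL)
  key <- sweep(m, 2, paste0(chain, " "), function(a, b) paste0(b, a))
  matrix(as.integer(factor(key)), nf, na)
}
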