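#' Write frames as a labelled multi-frame XYZ file
#'
#' Plain-text trajectory exchange format: for each frame an atom-count
#' line, a comment line `frame <i> box <Lx> <Ly> <Lz>`, then one row per
#' atom `species x y z molecule_id`. Coordinates are written with full
#' double precision so a read round-trip reproduces the frame set.
#'
#' @param frames A `frame_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_frames_xyz()]
#' @export
write_frames_xyz <- function(frames, path) {
  stopifnot(inherits(frames, "frame_set"))
  con <- file(path, "w")
  on.exit(close(con))
  n <- length(frames$species)
  for (f in seq_along(frames$frames)) {
    xyz <- frames$frames[[f]]
    writeLines(as.character(n), con)
    writeLines(sprintf("frame %d box %.15g %.15g %.15g", f,
                       frames$box[1], frames$box[2], frames$box[3]), con)
    writeLines(sprintf("%s %.15g %.15g %.15g %d", frames$species,
                       xyz[, 1], xyz[, 2], xyz[, 3], frames$molecule), con)
  }
  invisible(path)
}

#' Read a labelled multi-frame XYZ file
#'
#' Inverse of [write_frames_xyz()]. A plain 4-column XYZ (no molecule id)
#' is accepted: each atom then counts as its own molecule, except that all
#' atoms labelled `solute` form one molecule.
#'
#' @param path Path to the file.
#' @param selections Optional named selections to attach.
#' @return A `frame_set`.
#' @export
read_frames_xyz <- function(path, selections = list()) {
  lines <- readLines(path)
  pos <- 1L
  frames <- list()
  species <- NULL
  molecule <- NULL
  box <- NULL
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n))
      stop(sprintf("'%s': expected atom count at line %d", path, pos),
           call. = FALSE)
    hdr <- strsplit(trimws(lines[pos + 1L]), "\\s+")[[1]]
    bpos <- which(hdr == "box")
    if (length(bpos) == 1L && length(hdr) >= bpos + 3L)
      box <- as.numeric(hdr[bpos + 1:3])
    rows <- lines[pos + 2L + seq_len(n) - 1L]
    tok <- strsplit(trimws(rows), "\\s+")
    nf <- lengths(tok)
    if (any(nf < 4L))
      stop(sprintf("'%s': malformed atom row at line %d", path,
                   pos + 1L + which(nf < 4L)[1]), call. = FALSE)
    sp <- vapply(tok, `[[`, character(1), 1L)
    xyz <- t(vapply(tok, function(x) as.numeric(x[2:4]), numeric(3)))
    mol <- if (all(nf >= 5L))
      as.integer(vapply(tok, `[[`, character(1), 5L))
    else {
      m <- seq_len(n)
      m[sp == "solute"] <- if (any(sp == "solute")) m[sp == "solute"][1] else m
      m
    }
    if (is.null(species)) {
      species <- sp
      molecule <- mol
    } else if (!identical(species, sp)) {
      stop(sprintf("'%s': inconsistent species labels across frames", path),
           call. = FALSE)
    }
    frames[[length(frames) + 1L]] <- xyz
    pos <- pos + 2L + n
  }
  if (is.null(box))
    stop(sprintf("'%s': no box record found in comment lines", path),
         call. = FALSE)
  frame_set(frames, species = species, molecule = molecule, box = box,
            selections = selections)
}

#' Read a multi-model PDB as a frame set
#'
#' Thin wrapper over `bio3d::read.pdb(multi = TRUE)` that maps residue
#' names to species labels and assigns molecule ids from the residue
#' numbering. Requires the `bio3d` package.
#'
#' @param path Path to a multi-model PDB file.
#' @param species_map Named character vector mapping residue names to
#'   species labels (e.g. `c(CHO = "cation", CL = "anion", WAT = "water",
#'   PRO = "solute")`); unmapped residues become `"other"`.
#' @param box Periodic edge lengths (Angstrom); PDB CRYST1 records are not
#'   consulted, so the box must be supplied.
#' @param selections Optional named selections to attach.
#' @return A `frame_set`.
#' @export
read_frames_pdb <- function(path, species_map, box, selections = list()) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("read_frames_pdb requires the bio3d package", call. = FALSE)
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  resid <- pdb$atom$resid
  species <- unname(species_map[resid])
  species[is.na(species)] <- "other"
  molecule <- as.integer(factor(paste(pdb$atom$chain, pdb$atom$resno)))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  frames <- lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, ], ncol = 3, byrow = TRUE))
  frame_set(frames, species = species, molecule = molecule, box = box,
            selections = selections)
}
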