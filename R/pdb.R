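# van der Waals radii (A) assigned to parsed atoms, by element
.vdw_table <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
.vdw_default <- 1.70

#' Look up van der Waals radii by element symbol
#'
#' Unknown elements fall back to 1.70 A (carbon).
#' @param element character vector of element symbols.
#' @return numeric vector of radii, A.
#' @export
vdw_radius <- function(element) {
  r <- .vdw_table[toupper(trimws(element))]
  r[is.na(r)] <- .vdw_default
  unname(r)
}

#' Construct a structure frame
#'
#' One trajectory frame or crystal structure: a table of atoms with
#' coordinates and van der Waals radii.
#'
#' @param atoms data.frame with columns `eleno` (serial), `elety` (atom
#'   name), `resid` (residue name), `resno` (residue number), `chain`,
#'   `x`, `y`, `z` (A), `vdw` (A) and `elesy` (element symbol).
#' @param frame_index integer frame number.
#' @param time optional time stamp, ps.
#' @return object of class `structure_frame`.
#' @export
structure_frame <- function(atoms, frame_index = 1L, time = NA_real_) {
  need <- c("eleno", "elety", "resid", "resno", "chain",
            "x", "y", "z", "vdw", "elesy")
  stopifnot(is.data.frame(atoms), all(need %in% names(atoms)))
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates", call. = FALSE)
  }
  if (any(atoms$vdw <= 0)) stop("vdW radii must be > 0", call. = FALSE)
  structure(list(atoms = atoms, frame_index = as.integer(frame_index),
                 time = time),
            class = "structure_frame")
}

#' @export
print.structure_frame <- function(x, ...) {
  cat(sprintf("<structure_frame #%d> %d atoms, %d residues\n",
              x$frame_index, nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno)))))
  invisible(x)
}

#' Coordinates of a frame as a matrix
#' @param frame a [structure_frame()].
#' @param idx optional row indices.
#' @return n x 3 numeric matrix.
#' @export
frame_coords <- function(frame, idx = NULL) {
  a <- frame$atoms
  if (!is.null(idx)) a <- a[idx, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

#' Select atoms of a frame
#'
#' Simple conjunctive selection on atom name, residue name, residue number
#' and chain. NULL criteria match everything.
#'
#' @param frame a [structure_frame()].
#' @param elety,resid,resno,chain vectors of admissible values, or NULL.
#' @return integer vector of matching atom row indices.
#' @export
select_atoms <- function(frame, elety = NULL, resid = NULL, resno = NULL,
                         chain = NULL) {
  a <- frame$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(elety)) keep <- keep & a$elety %in% elety
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  which(keep)
}

#' Read a (multi-model) PDB file into structure frames
#'
#' Parses ATOM/HETATM records per the PDB v3.3 fixed-width layout (via
#' bio3d), splitting MODEL/ENDMDL blocks into separate frames. Alternate
#' locations are filtered to blank or 'A'. Van der Waals radii are assigned
#' from a bundled element table (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20,
#' P 1.80 A); the element symbol is taken from columns 77-78 when present,
#' else inferred from the atom name.
#'
#' @param path path to a PDB file.
#' @return list of [structure_frame()] objects, one per MODEL.
#' @export
read_pdb <- function(path) {
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) {
      stop("failed to parse PDB file '", path, "': ", conditionMessage(e),
           call. = FALSE)
    })
  at <- pdb$atom
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  elesy <- at$elesy
  blank <- is.na(elesy) | trimws(elesy) == ""
  elesy[blank] <- substr(gsub("[^A-Za-z].*$", "", at$elety[blank]), 1, 1)
  nmod <- nrow(pdb$xyz)
  lapply(seq_len(nmod), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    atoms <- data.frame(
      eleno = at$eleno, elety = at$elety, resid = at$resid,
      resno = at$resno,
      chain = ifelse(is.na(at$chain), "", at$chain),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      vdw = vdw_radius(elesy), elesy = toupper(trimws(elesy)),
      stringsAsFactors = FALSE)
    structure_frame(atoms[keep, , drop = FALSE], frame_index = m)
  })
}

#' Write structure frames as a multi-model PDB file
#'
#' @param frames list of [structure_frame()] (identical atom tables are not
#'   required, but typical trajectories share one).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_frames_pdb <- function(frames, path) {
  if (inherits(frames, "structure_frame")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(frames)) {
    a <- frames[[m]]$atoms
    writeLines(sprintf("MODEL     %4d", m), con)
    # PDB v3.3 ATOM record; atom names of <4 chars start in column 14
    nm <- ifelse(nchar(a$elety) < 4, sprintf(" %-3s", a$elety),
                 sprintf("%-4s", a$elety))
    writeLines(sprintf(
      "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$eleno, nm, a$resid, substr(paste0(a$chain, " "), 1, 1), a$resno,
      a$x, a$y, a$z, 1.0, 0.0, a$elesy), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
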