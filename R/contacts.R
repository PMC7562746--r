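#' Distance-and-angle contact detection
#'
#' Finds hydrogen-bond-style contacts between a metabolite and selected
#' pore-lining residues using the trajectory-viewer criterion: donor and
#' acceptor heavy atoms (N or O) within `dist_cutoff`, and — when the frame
#' contains hydrogens — a donor-hydrogen-acceptor angle deviating from
#' linearity (180 degrees) by at most `angle_cutoff`. A hydrogen counts as
#' bound to a donor when it lies within 1.25 A of it; either partner may
#' act as the donor. Frames without any hydrogens (heavy-atom-only probes
#' such as O2/CO2) are scored on distance alone and flagged
#' `distance_only`.
#'
#' @param frame a [structure_frame()].
#' @param metabolite selection list for the metabolite (passed to
#'   [select_atoms()]), e.g. `list(resid = "BCT")`.
#' @param residues named list of residue selections, e.g.
#'   `list(Arg11 = list(resid = "ARG", resno = 11), ...)`.
#' @param dist_cutoff donor-acceptor heavy-atom distance cutoff, A
#'   (default 3.5).
#' @param angle_cutoff allowed deviation from linearity at the hydrogen,
#'   degrees (default 30).
#' @param per_chain report one record per (residue, chain) instead of
#'   pooling chains (default FALSE).
#' @return data.frame with columns `frame_index`, `residue` (and `chain`
#'   if `per_chain`), `n_contacts`, `contact` (`n_contacts >= 1`) and
#'   `distance_only`.
#' @export
detect_contacts <- function(frame, metabolite, residues,
                            dist_cutoff = 3.5, angle_cutoff = 30,
                            per_chain = FALSE) {
  stopifnot(inherits(frame, "structure_frame"), length(residues) >= 1)
  a <- frame$atoms
  met_idx <- do.call(select_atoms, c(list(frame), metabolite))
  if (!length(met_idx)) stop("empty metabolite selection", call. = FALSE)
  h_idx <- which(a$elesy == "H")
  have_h <- length(h_idx) > 0
  xyz <- frame_coords(frame)

  met_heavy <- met_idx[a$elesy[met_idx] != "H"]
  met_polar <- met_heavy[a$elesy[met_heavy] %in% c("N", "O")]

  hydrogens_of <- function(i) {
    if (!have_h) return(integer())
    d2 <- rowSums(sweep(xyz[h_idx, , drop = FALSE], 2, xyz[i, ])^2)
    h_idx[d2 <= 1.25^2]
  }
  angle_ok <- function(donor, hyd, acceptor) {
    v1 <- xyz[donor, ] - xyz[hyd, ]
    v2 <- xyz[acceptor, ] - xyz[hyd, ]
    cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    (180 - ang) <= angle_cutoff
  }
  pair_contact <- function(i, j) {
    # i, j heavy atoms across the interface; TRUE if the pair qualifies
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d > dist_cutoff) return(FALSE)
    if (!have_h) return(TRUE)
    for (dir in list(c(i, j), c(j, i))) {
      if (!a$elesy[dir[1]] %in% c("N", "O")) next
      for (h in hydrogens_of(dir[1])) {
        if (angle_ok(dir[1], h, dir[2])) return(TRUE)
      }
    }
    FALSE
  }

  rows <- list()
  for (lab in names(residues)) {
    res_idx <- do.call(select_atoms, c(list(frame), residues[[lab]]))
    res_idx <- setdiff(res_idx, met_idx)
    res_polar <- res_idx[a$elesy[res_idx] %in% c("N", "O")]
    chains <- if (per_chain) unique(a$chain[res_idx]) else ""
    for (ch in chains) {
      ri <- if (per_chain) res_polar[a$chain[res_polar] == ch] else res_polar
      n <- 0L
      for (i in ri) {
        cand <- if (have_h) met_polar else met_heavy
        for (j in cand) if (pair_contact(i, j)) n <- n + 1L
      }
      rec <- data.frame(frame_index = frame$frame_index, residue = lab,
                        n_contacts = n, contact = n >= 1L,
                        distance_only = !have_h,
                        stringsAsFactors = FALSE)
      if (per_chain) rec$chain <- ch
      rows[[length(rows) + 1]] <- rec
    }
  }
  do.call(rbind, rows)
}

#' Contact tables for a whole trajectory
#'
#' @param frames list of [structure_frame()].
#' @param ... passed to [detect_contacts()].
#' @return row-bound data.frame of per-frame contact records, with a
#'   `frame` column aliasing `frame_index`.
#' @export
contact_series <- function(frames, ...) {
  out <- do.call(rbind, lapply(frames, detect_contacts, ...))
  out$frame <- out$frame_index
  out
}
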