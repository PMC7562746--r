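#' Specification for a synthetic hexameric pore ensemble
#'
#' Describes a breathing six-fold-symmetric pore with three stacked residue
#' rings (Arg11 on the convex side, Ser39 at the constriction, Lys36 on the
#' concave side — the three pore-lining residues of a BMC-H hexamer) and a
#' single-atom metabolite probe. In a fraction of frames the metabolite
#' sits within hydrogen-bonding distance of a designated residue and all
#' ring radii are dilated by `contact_dilation / 2`, shifting the
#' constriction diameter by `contact_dilation` — a planted, recoverable
#' contact-coupled pore-opening effect.
#'
#' @param n_frames number of frames (default 2500, the number of
#'   equidistant trajectory frames analyzed in the reference workflow).
#' @param ring_radius_mean mean radius of the constriction (Ser39) ring, A
#'   (default 3.0; flanking rings sit 1.5 A wider). Must exceed `atom_vdw`.
#' @param breathing_sd per-frame Gaussian SD of the common ring radius, A
#'   (default 0.5, giving constriction diameters fluctuating over a few A).
#' @param atom_vdw van der Waals radius assigned to ring atoms, A (default
#'   1.52, matching the oxygen of a serine hydroxyl).
#' @param contact_dilation diameter shift when the metabolite is bound, A.
#' @param contact_fraction fraction of frames with a planted contact.
#' @param contact_residue which residue ring receives the contact
#'   (default "LYS", residue 36).
#' @param seed RNG seed.
#' @return object of class `pore_ensemble_spec`.
#' @export
pore_ensemble_spec <- function(n_frames = 2500, ring_radius_mean = 3.0,
                               breathing_sd = 0.5, atom_vdw = 1.52,
                               contact_dilation = 0,
                               contact_fraction = 0,
                               contact_residue = "LYS", seed = 1L) {
  stopifnot(n_frames >= 1, ring_radius_mean > atom_vdw,
            breathing_sd >= 0, contact_fraction >= 0, contact_fraction <= 1,
            contact_residue %in% c("ARG", "SER", "LYS"))
  structure(list(n_frames = as.integer(n_frames),
                 ring_radius_mean = ring_radius_mean,
                 breathing_sd = breathing_sd, atom_vdw = atom_vdw,
                 contact_dilation = contact_dilation,
                 contact_fraction = contact_fraction,
                 contact_residue = contact_residue,
                 seed = as.integer(seed)),
            class = "pore_ensemble_spec")
}

# ring layout: resid, resno, atom name, element, z offset, radial offset
.ring_layout <- data.frame(
  resid = c("ARG", "SER", "LYS"),
  resno = c(11L, 39L, 36L),
  elety = c("NH1", "OG", "NZ"),
  elesy = c("N", "O", "N"),
  zoff  = c(-3, 0, 3),
  roff  = c(1.5, 0, 1.5),
  stringsAsFactors = FALSE)

#' Generate a synthetic breathing-pore ensemble with planted contacts
#'
#' @param spec a [pore_ensemble_spec()].
#' @param build_frames build atomic coordinate frames (default TRUE). With
#'   FALSE only the ground-truth contact table and diameters are returned
#'   — enough for statistical calibration studies at a fraction of the
#'   cost.
#' @return list with elements `frames` (list of [structure_frame()], NULL
#'   when `build_frames = FALSE`), `contacts` (ground-truth contact table:
#'   frame, residue, n_contacts, contact) and `diameters` (data.frame
#'   frame, diameter with the true per-frame constriction diameter
#'   `2 * (ring_radius - atom_vdw)`).
#' @export
generate_pore_ensemble <- function(spec, build_frames = TRUE) {
  stopifnot(inherits(spec, "pore_ensemble_spec"))
  set.seed(spec$seed)
  n <- spec$n_frames
  radius <- stats::rnorm(n, spec$ring_radius_mean, spec$breathing_sd)
  # keep the pore physically open
  radius <- pmax(radius, spec$atom_vdw + 0.3)
  n_contact <- round(spec$contact_fraction * n)
  contact <- rep(FALSE, n)
  if (n_contact > 0) contact[sample.int(n, n_contact)] <- TRUE
  radius <- radius + ifelse(contact, spec$contact_dilation / 2, 0)

  ang <- (0:5) * pi / 3
  chains <- LETTERS[1:6]
  planted <- .ring_layout[.ring_layout$resid == spec$contact_residue, ]

  frames <- if (!build_frames) NULL else lapply(seq_len(n), function(f) {
    rows <- lapply(seq_len(nrow(.ring_layout)), function(i) {
      ri <- radius[f] + .ring_layout$roff[i]
      data.frame(
        eleno = 0L, elety = .ring_layout$elety[i],
        resid = .ring_layout$resid[i], resno = .ring_layout$resno[i],
        chain = chains,
        x = ri * cos(ang), y = ri * sin(ang),
        z = rep(.ring_layout$zoff[i], 6),
        vdw = spec$atom_vdw, elesy = .ring_layout$elesy[i],
        stringsAsFactors = FALSE)
    })
    atoms <- do.call(rbind, rows)
    # metabolite probe: bound 3.0 A above the chain-A planted-ring atom in
    # contact frames, parked on the axis well away from all rings otherwise
    met_xyz <- if (contact[f]) {
      c((radius[f] + planted$roff) * cos(ang[1]),
        (radius[f] + planted$roff) * sin(ang[1]),
        planted$zoff + 3.0)
    } else {
      c(0, 0, 9)
    }
    atoms <- rbind(atoms, data.frame(
      eleno = 0L, elety = "O1", resid = "BCT", resno = 1L, chain = "X",
      x = met_xyz[1], y = met_xyz[2], z = met_xyz[3],
      vdw = vdw_radius("O"), elesy = "O", stringsAsFactors = FALSE))
    atoms$eleno <- seq_len(nrow(atoms))
    structure_frame(atoms, frame_index = f)
  })

  contacts <- do.call(rbind, lapply(c("ARG", "SER", "LYS"), function(r) {
    nc <- if (r == spec$contact_residue) as.integer(contact) else 0L
    data.frame(frame = seq_len(n), residue = r, n_contacts = nc,
               contact = nc >= 1L, stringsAsFactors = FALSE)
  }))
  diam <- data.frame(frame = seq_len(n),
                     diameter = 2 * (radius - spec$atom_vdw))
  list(frames = frames, contacts = contacts, diameters = diam, spec = spec)
}

#' Write a pore ensemble to disk
#'
#' Frames go to a multi-model PDB, the ground-truth contact table to a
#' companion CSV.
#'
#' @param ensemble output of [generate_pore_ensemble()].
#' @param pdb_path,contacts_path output paths.
#' @return invisibly, a list of the two paths.
#' @export
write_pore_ensemble <- function(ensemble, pdb_path, contacts_path) {
  write_frames_pdb(ensemble$frames, pdb_path)
  utils::write.csv(ensemble$contacts, contacts_path, row.names = FALSE)
  invisible(list(pdb = pdb_path, contacts = contacts_path))
}
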