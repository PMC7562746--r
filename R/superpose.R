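#' Least-squares rigid superposition (Kabsch)
#'
#' Optimal rotation/translation of `mobile` onto `reference` over a matched
#' atom selection (default alpha carbons), by the Kabsch algorithm with
#' the determinant correction that excludes improper rotations. Returns
#' the transform and the post-fit RMSD; the transform maps a mobile
#' coordinate row-vector x as `x %*% t(rotation) + translation`.
#'
#' @param mobile,reference [structure_frame()] objects.
#' @param elety,resid,resno,chain selection criteria applied to both frames
#'   (see [select_atoms()]); the selections must pair up one-to-one.
#' @return list with `rotation` (3x3), `translation` (length 3), `rmsd`
#'   (A) and `transformed` (the whole mobile frame after fitting).
#' @export
superpose <- function(mobile, reference, elety = "CA", resid = NULL,
                      resno = NULL, chain = NULL) {
  im <- select_atoms(mobile, elety, resid, resno, chain)
  ir <- select_atoms(reference, elety, resid, resno, chain)
  if (length(im) != length(ir)) {
    stop(sprintf("selection count mismatch: %d mobile vs %d reference",
                 length(im), length(ir)), call. = FALSE)
  }
  if (length(im) < 3) stop("need at least 3 paired atoms", call. = FALSE)
  P <- frame_coords(mobile, im)
  Q <- frame_coords(reference, ir)
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  if (min(svd(P0)$d) < 1e-9 * max(svd(P0)$d)) {
    stop("degenerate (collinear) selection geometry", call. = FALSE)
  }
  H <- crossprod(P0, Q0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.vector(cq - R %*% cp)
  fit <- sweep(P %*% t(R), 2, tr, "+")
  rmsd <- sqrt(mean(rowSums((fit - Q)^2)))
  all_xyz <- sweep(frame_coords(mobile) %*% t(R), 2, tr, "+")
  out <- mobile
  out$atoms$x <- all_xyz[, 1]
  out$atoms$y <- all_xyz[, 2]
  out$atoms$z <- all_xyz[, 3]
  list(rotation = R, translation = tr, rmsd = rmsd, transformed = out)
}

#' Superpose every frame of a trajectory onto a reference
#'
#' @param frames list of [structure_frame()].
#' @param reference reference frame (default the first frame).
#' @inheritParams superpose
#' @return list with `frames` (fitted frames) and `rmsd` (per-frame RMSD).
#' @export
superpose_trajectory <- function(frames, reference = frames[[1]],
                                 elety = "CA", resid = NULL, resno = NULL,
                                 chain = NULL) {
  fits <- lapply(frames, superpose, reference = reference, elety = elety,
                 resid = resid, resno = resno, chain = chain)
  list(frames = lapply(fits, `[[`, "transformed"),
       rmsd = vapply(fits, `[[`, numeric(1), "rmsd"))
}

#' Per-residue root-mean-square fluctuation
#'
#' RMSF of selected atoms about their time-averaged positions,
#' `sqrt(mean(|r - <r>|^2))`, over the retained part of a pre-superposed
#' trajectory, aggregated per residue (mean over the residue's selected
#' atoms). A leading fraction of frames can be discarded as equilibration
#' (e.g. 0.25 to analyze the last 150 ns of a 200 ns run). Residues are
#' keyed by chain and residue number, so per-chain profiles come out
#' directly; `pooled = TRUE` additionally averages equivalent residues
#' across chains.
#'
#' @param frames list of pre-superposed [structure_frame()] sharing one
#'   atom table layout.
#' @param elety,resid,resno,chain atom selection (default alpha carbons).
#' @param discard_fraction fraction of initial frames to drop (default 0).
#' @param pooled average across chains by residue number (default FALSE).
#' @return data.frame with columns `chain` (absent when pooled), `resno`,
#'   `resid` and `rmsf` (A).
#' @export
rmsf <- function(frames, elety = "CA", resid = NULL, resno = NULL,
                 chain = NULL, discard_fraction = 0, pooled = FALSE) {
  stopifnot(discard_fraction >= 0, discard_fraction < 1)
  drop_n <- floor(length(frames) * discard_fraction)
  frames <- frames[(drop_n + 1):length(frames)]
  if (length(frames) < 2) stop("need at least 2 retained frames",
                               call. = FALSE)
  idx <- select_atoms(frames[[1]], elety, resid, resno, chain)
  if (!length(idx)) stop("empty atom selection", call. = FALSE)
  coords <- vapply(frames, frame_coords, frame_coords(frames[[1]], idx),
                   idx = idx)                       # natoms x 3 x nframes
  mean_xyz <- apply(coords, c(1, 2), mean)
  dev2 <- sweep(coords, c(1, 2), mean_xyz)^2
  atom_rmsf <- sqrt(apply(dev2, 1, mean) * 3)       # mean over xyz & frames
  a <- frames[[1]]$atoms[idx, ]
  key <- if (pooled) list(resno = a$resno) else
    list(chain = a$chain, resno = a$resno)
  agg <- stats::aggregate(atom_rmsf, by = key, FUN = mean)
  names(agg)[ncol(agg)] <- "rmsf"
  agg$resid <- a$resid[match(agg$resno, a$resno)]
  agg[order(agg$resno), c(setdiff(names(agg), c("rmsf", "resid")),
                          "resid", "rmsf")]
}
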