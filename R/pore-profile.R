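#' Inscribed-sphere pore radius profile
#'
#' For each slice along the pore axis z, finds the center (x, y) that
#' maximizes the largest sphere radius not overlapping any van der Waals
#' sphere, `r(x, y, z) = min_i(|p_i - (x, y, z)| - vdw_i)`, over atoms
#' within a slab around the slice — the construction used by channel
#' profiling tools such as HOLE. The frame must already be superposed so
#' the pore axis is the z axis (center of mass at the origin). The search
#' is multi-start local optimization (Nelder-Mead) from an
#' `n_starts x n_starts` grid over ±2 A around the axis.
#'
#' @param frame a [structure_frame()].
#' @param z_range axial range profiled, A (default c(-10, 10)).
#' @param z_step slice spacing, A (default 0.5).
#' @param n_starts number of local refinements launched from the best
#'   mutually separated cells of a dense (0.25 A) coarse scan of the
#'   search box (default 5).
#' @param slab_halfwidth half-width of the atom-inclusion slab per slice, A
#'   (default 6).
#' @param escape_radius radius cap beyond which the pore is considered
#'   open, A (default 10).
#' @param atoms_idx optional atom row indices to profile against (e.g. a
#'   protein-only selection that excludes a ligand).
#' @param search_halfwidth radius of the disc around the axis within
#'   which the sphere center may wander, A (default 3). Bounding the
#'   search keeps the center on the pore axis region instead of slipping
#'   around the outside of the protein.
#' @return object of class `pore_profile`: data.frame with columns `z`,
#'   `radius` (A, NA where no atoms fall in the slab), `cx`, `cy`.
#' @export
pore_profile <- function(frame, z_range = c(-10, 10), z_step = 0.5,
                         n_starts = 5, slab_halfwidth = 6,
                         escape_radius = 10, atoms_idx = NULL,
                         search_halfwidth = 3) {
  stopifnot(inherits(frame, "structure_frame"))
  xyz <- frame_coords(frame, atoms_idx)
  vdw <- if (is.null(atoms_idx)) frame$atoms$vdw else
    frame$atoms$vdw[atoms_idx]
  zs <- seq(z_range[1], z_range[2], by = z_step)
  g1 <- seq(-search_halfwidth, search_halfwidth, by = 0.25)
  coarse <- as.matrix(expand.grid(x = g1, y = g1))
  coarse <- coarse[rowSums(coarse^2) <= search_halfwidth^2 + 1e-9, ]
  res <- lapply(zs, function(z0) {
    slab <- abs(xyz[, 3] - z0) <= slab_halfwidth
    if (!any(slab)) {
      return(data.frame(z = z0, radius = NA_real_, cx = NA_real_,
                        cy = NA_real_))
    }
    P <- xyz[slab, , drop = FALSE]
    vv <- vdw[slab]
    dz2 <- (P[, 3] - z0)^2
    obj <- function(xy) {
      r <- min(sqrt((P[, 1] - xy[1])^2 + (P[, 2] - xy[2])^2 + dz2) - vv)
      # soft wall keeps the center inside a disc around the pore axis
      excess <- max(sqrt(sum(xy^2)) - search_halfwidth, 0)
      r - 100 * excess^2
    }
    # dense vectorized coarse scan, then local refinement from the best
    # mutually separated cells (covers distinct basins of the non-smooth
    # min-of-cones objective)
    dx <- outer(coarse[, 1], P[, 1], "-")
    dy <- outer(coarse[, 2], P[, 2], "-")
    rs <- sqrt(dx^2 + dy^2 + rep(dz2, each = nrow(coarse)))
    v0 <- apply(sweep(rs, 2, vv), 1, min)
    ord <- order(v0, decreasing = TRUE)
    picks <- integer()
    for (s in ord) {
      if (length(picks) >= n_starts) break
      if (!length(picks) ||
          min((coarse[picks, 1] - coarse[s, 1])^2 +
                (coarse[picks, 2] - coarse[s, 2])^2) > 0.5^2) {
        picks <- c(picks, s)
      }
    }
    best <- c(NA_real_, NA_real_, -Inf)
    for (s in picks) {
      o <- stats::optim(coarse[s, ], obj,
                        control = list(fnscale = -1, reltol = 1e-10,
                                       maxit = 400))
      if (o$value > best[3]) best <- c(o$par, o$value)
    }
    data.frame(z = z0, radius = min(max(best[3], 0), escape_radius),
               cx = best[1], cy = best[2])
  })
  structure(do.call(rbind, res), class = c("pore_profile", "data.frame"))
}

#' Minimum constriction of a pore profile
#'
#' The narrowest slice of the profile, reported as a diameter. Ties are
#' broken toward the slice closest to z = 0 (the pore midplane).
#'
#' @param profile a [pore_profile()].
#' @return list with `z` (A) and `diameter` (A).
#' @export
min_constriction <- function(profile) {
  ok <- is.finite(profile$radius)
  if (!any(ok)) stop("profile has no defined slices", call. = FALSE)
  p <- profile[ok, ]
  rmin <- min(p$radius)
  cand <- p[p$radius <= rmin + 1e-9, ]
  hit <- cand[which.min(abs(cand$z)), ]
  list(z = hit$z, diameter = 2 * hit$radius)
}

#' Per-frame constriction diameters of a trajectory
#'
#' Convenience wrapper: [pore_profile()] + [min_constriction()] for every
#' frame, against an optional protein-only atom selection.
#'
#' @param frames list of [structure_frame()].
#' @param ... passed to [pore_profile()].
#' @return data.frame with columns `frame`, `z_min`, `diameter`.
#' @export
constriction_series <- function(frames, ...) {
  rows <- lapply(seq_along(frames), function(i) {
    mc <- min_constriction(pore_profile(frames[[i]], ...))
    data.frame(frame = frames[[i]]$frame_index %||% i, z_min = mc$z,
               diameter = mc$diameter)
  })
  do.call(rbind, rows)
}

#' Area of a (near-)planar hexagon in 3D
#'
#' Used to track the pore-entrance surface defined by the six Ser39 alpha
#' carbons of a hexamer: fits the least-squares plane through the six
#' points, orders the vertices by polar angle about their centroid in that
#' plane, and sums the 3D areas of the fan triangles (for a convex hexagon
#' every triangulation, including the Delaunay one, gives the same area).
#'
#' @param points 6x3 numeric matrix of vertex coordinates, or a
#'   [structure_frame()] combined with a selection.
#' @param ... when `points` is a frame: selection arguments passed to
#'   [select_atoms()] (e.g. `elety = "CA"`, `resno = 39`).
#' @return area in A^2.
#' @export
hexagon_area <- function(points, ...) {
  if (inherits(points, "structure_frame")) {
    idx <- select_atoms(points, ...)
    points <- frame_coords(points, idx)
  }
  points <- as.matrix(points)
  if (nrow(points) != 6 || ncol(points) != 3) {
    stop("hexagon_area requires exactly 6 points in 3D", call. = FALSE)
  }
  ctr <- colMeans(points)
  X <- sweep(points, 2, ctr)
  sv <- svd(X)
  if (sv$d[2] < 1e-9 * sv$d[1]) {
    stop("points are collinear; no hexagon defined", call. = FALSE)
  }
  uv <- X %*% sv$v[, 1:2]                 # in-plane coordinates
  ord <- order(atan2(uv[, 2], uv[, 1]))
  V <- X[ord, ]
  area <- 0
  for (i in seq_len(6)) {
    a <- V[i, ]
    b <- V[if (i == 6) 1 else i + 1, ]
    cr <- c(a[2] * b[3] - a[3] * b[2],
            a[3] * b[1] - a[1] * b[3],
            a[1] * b[2] - a[2] * b[1])
    area <- area + 0.5 * sqrt(sum(cr^2))
  }
  area
}
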