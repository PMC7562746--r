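#' Binned free-energy profile
#'
#' Container for 1D or 2D free-energy estimates. `G` is NA in unoccupied
#' bins (the empty-bin policy is "masked, never infinite"). 1D profiles
#' carry per-bin standard errors once block splitting has been applied.
#'
#' @param bin_centers numeric vector of z bin centers (1D).
#' @param G free energy per bin, kcal/mol.
#' @param stderr per-bin standard error, kcal/mol (NA when not estimated).
#' @param n_eff pooled sample count per bin.
#' @param anchor text describing the zero convention.
#' @param T temperature, K.
#' @param b_centers radial bin centers; when non-NULL, `G` and `n_eff` are
#'   matrices (z rows, b columns) and the profile is 2D.
#' @return object of class `free_energy_profile`.
#' @export
free_energy_profile <- function(bin_centers, G, stderr = NULL, n_eff = NULL,
                                anchor = "", T = 303.15, b_centers = NULL) {
  dim_ <- if (is.null(b_centers)) 1L else 2L
  if (is.null(stderr)) {
    stderr <- if (dim_ == 1L) rep(NA_real_, length(G)) else NULL
  }
  structure(list(bin_centers = bin_centers, G = G, stderr = stderr,
                 n_eff = n_eff, anchor = anchor, T = T,
                 b_centers = b_centers, dim = dim_),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  occ <- sum(is.finite(x$G))
  cat(sprintf("<free_energy_profile> %dD, %d/%d occupied bins, anchor: %s\n",
              x$dim, occ, length(x$G), x$anchor))
  if (occ) {
    cat(sprintf("  G range [%.3f, %.3f] kcal/mol\n",
                min(x$G, na.rm = TRUE), max(x$G, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
as.data.frame.free_energy_profile <- function(x, ...) {
  if (x$dim == 1L) {
    data.frame(z = x$bin_centers, G = x$G, stderr = x$stderr,
               n_eff = if (is.null(x$n_eff)) NA else x$n_eff)
  } else {
    data.frame(z = rep(x$bin_centers, times = length(x$b_centers)),
               b = rep(x$b_centers, each = length(x$bin_centers)),
               G = as.vector(x$G))
  }
}

#' Write a free-energy profile to CSV
#'
#' 1D profiles are written as (z, G, stderr, n_eff); 2D surfaces as
#' long-format (z, b, G).
#'
#' @param profile a [free_energy_profile()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' Root-mean-square pooled standard error of a profile
#'
#' Scalar summary used to compare estimators at the resolution the data
#' supports (e.g. WHAM vs DHAM discrepancy in units of pooled error).
#'
#' @param profile a 1D [free_energy_profile()] with block standard errors.
#' @return pooled standard error, kcal/mol.
#' @export
pooled_stderr <- function(profile) {
  s <- profile$stderr
  sqrt(mean(s[is.finite(s)]^2))
}

# default histogram grid: 0.5 A bins centered on the window grid
#' Default bin edges matching the umbrella window grid
#' @param z_min,z_max,step grid parameters (defaults -26, 26, 0.5 A).
#' @return numeric vector of bin edges.
#' @export
default_bin_edges <- function(z_min = -26, z_max = 26, step = 0.5) {
  seq(z_min - step / 2, z_max + step / 2, by = step)
}

# anchoring helper: shift G so the mean over bulk bins is zero; falls back
# to the mean of all occupied bins when no bulk bin is occupied (toy data)
anchor_profile <- function(G, centers, bulk = c(24, 25)) {
  occ <- is.finite(G)
  in_bulk <- occ & abs(centers) >= bulk[1] & abs(centers) <= bulk[2]
  if (any(in_bulk)) {
    list(G = G - mean(G[in_bulk]),
         anchor = sprintf("mean over bins with |z| in [%g, %g] A = 0",
                          bulk[1], bulk[2]))
  } else {
    list(G = G - mean(G[occ]),
         anchor = "mean over occupied bins = 0 (no bulk bins occupied)")
  }
}
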