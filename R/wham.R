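# Shared WHAM core: solves the self-consistent equations
#   p_j  = M_j / sum_k N_k exp((f_k - w_kj) / kBT)
#   f_k  = -kBT log sum_j p_j exp(-w_kj / kBT)
# on the z-marginal histograms. Returns the window free energies and the
# per-z-bin denominator, from which 1D probabilities (and, because the bias
# depends on z only, 2D probabilities) follow directly.
wham_core <- function(counts, w, kBT, tol, max_iter) {
  K <- nrow(counts); J <- ncol(counts)
  N <- rowSums(counts)
  M <- colSums(counts)
  occ <- M > 0
  A <- exp(-w / kBT)                      # K x J Boltzmann bias factors
  f <- numeric(K)                          # window free energies, kcal/mol
  for (it in seq_len(max_iter)) {
    g <- exp(f / kBT)
    denom <- as.vector(crossprod(A, N * g))
    p <- ifelse(occ, M / denom, 0)
    Z <- as.vector(A %*% p)
    f_new <- -kBT * log(Z)
    f_new <- f_new - mean(f_new)           # fix the gauge
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol * kBT) {
      g <- exp(f / kBT)
      denom <- as.vector(crossprod(A, N * g))
      return(list(f = f, denom = denom, occ = occ, M = M, iter = it))
    }
  }
  stop(sprintf(
    "WHAM did not converge in %d iterations (residual %.3g kBT > tol %.3g)",
    max_iter, delta / kBT, tol), call. = FALSE)
}

# histogram window samples on bin edges; drops out-of-range samples
bin_counts <- function(values, edges) {
  J <- length(edges) - 1
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  tabulate(idx[idx >= 1 & idx <= J], nbins = J)
}

check_window_overlap <- function(counts, centers_z0) {
  ord <- order(centers_z0)
  occ <- counts[ord, , drop = FALSE] > 0
  for (i in seq_len(nrow(occ) - 1)) {
    if (!any(occ[i, ] & occ[i + 1, ])) {
      stop(sprintf(
        "no mutually occupied bin between windows at z0 = %.2f and %.2f A",
        centers_z0[ord[i]], centers_z0[ord[i + 1]]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

window_bias_matrix <- function(windows, centers) {
  t(vapply(windows, function(wd) {
    bias_energy(wd$bias, wd$restraint, centers, b = 0)
  }, numeric(length(centers))))
}

check_uniform_T <- function(windows) {
  Ts <- vapply(windows, `[[`, numeric(1), "T")
  if (diff(range(Ts)) > 1e-9) {
    stop("windows must share one temperature", call. = FALSE)
  }
  Ts[1]
}

#' 1D weighted histogram analysis method (WHAM)
#'
#' Combines biased umbrella-window histograms of the axial coordinate z
#' into an unbiased free-energy profile by iterating the standard WHAM
#' self-consistent equations until the window free energies change by less
#' than `tol * kBT`. The profile is anchored so the mean free energy over
#' the bulk-solvent bins (|z| in 24-25 A) is zero.
#'
#' @param windows list of `umbrella_window_data`.
#' @param bin_edges histogram bin edges, A (default 0.5 A bins over
#'   \[-26, 26\] matching the window grid).
#' @param tol convergence tolerance on window free energies, units of kBT
#'   (default 1e-7).
#' @param max_iter iteration cap (default 1e5).
#' @return a [free_energy_profile()] (stderr NA; see
#'   [split_block_errors()]).
#' @references Kumar et al. (1992) J Comput Chem 13:1011 (WHAM).
#' @export
wham_1d <- function(windows, bin_edges = default_bin_edges(),
                    tol = 1e-7, max_iter = 1e5) {
  stopifnot(length(windows) >= 1)
  T <- check_uniform_T(windows)
  kBT <- thermal_energy(T)
  centers <- (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2
  counts <- t(vapply(windows, function(wd) bin_counts(wd$samples$z, bin_edges),
                     numeric(length(centers))))
  if (any(rowSums(counts) == 0)) {
    stop("a window has no samples inside the bin range", call. = FALSE)
  }
  z0s <- vapply(windows, function(wd) {
    if (is.null(wd$bias)) NA_real_ else wd$bias$z0
  }, numeric(1))
  if (length(windows) > 1 && !anyNA(z0s)) check_window_overlap(counts, z0s)
  w <- window_bias_matrix(windows, centers)
  sol <- wham_core(counts, w, kBT, tol, max_iter)
  p <- ifelse(sol$occ, sol$M / sol$denom, NA_real_)
  G <- -kBT * log(p)
  anc <- anchor_profile(G, centers)
  free_energy_profile(centers, anc$G, n_eff = sol$M, anchor = anc$anchor,
                      T = T)
}

#' 2D weighted histogram analysis method
#'
#' Extends [wham_1d()] to the (z, b) plane. Because the umbrella bias acts
#' on z only (the radial restraint is flat inside the cylinder), the window
#' free energies solve the same 1D self-consistent equations on the
#' z-marginal histograms; the 2D bin probabilities then follow from the
#' converged denominators. With `jacobian_correct = TRUE` the reported
#' surface is `G(z, b) = -kBT log(p / b_center)`: the linear growth of the
#' distance-from-axis volume element is divided out, so a free particle
#' shows a flat surface in b.
#'
#' @inheritParams wham_1d
#' @param z_edges,b_edges bin edges in z and b, A.
#' @param jacobian_correct divide out the radial measure (default TRUE).
#' @return a 2D [free_energy_profile()] (G is a z-by-b matrix).
#' @export
wham_2d <- function(windows, z_edges = default_bin_edges(),
                    b_edges = seq(0, 15, by = 1), tol = 1e-7,
                    max_iter = 1e5, jacobian_correct = TRUE) {
  stopifnot(length(windows) >= 1)
  T <- check_uniform_T(windows)
  kBT <- thermal_energy(T)
  zc <- (z_edges[-1] + z_edges[-length(z_edges)]) / 2
  bc <- (b_edges[-1] + b_edges[-length(b_edges)]) / 2
  Jz <- length(zc); Jb <- length(bc)
  counts_z <- t(vapply(windows, function(wd) bin_counts(wd$samples$z, z_edges),
                       numeric(Jz)))
  z0s <- vapply(windows, function(wd) {
    if (is.null(wd$bias)) NA_real_ else wd$bias$z0
  }, numeric(1))
  if (length(windows) > 1 && !anyNA(z0s)) check_window_overlap(counts_z, z0s)
  w <- window_bias_matrix(windows, zc)
  sol <- wham_core(counts_z, w, kBT, tol, max_iter)
  # pooled 2D histogram
  M2 <- matrix(0, Jz, Jb)
  for (wd in windows) {
    iz <- findInterval(wd$samples$z, z_edges, rightmost.closed = TRUE)
    ib <- findInterval(wd$samples$b, b_edges, rightmost.closed = TRUE)
    ok <- iz >= 1 & iz <= Jz & ib >= 1 & ib <= Jb
    M2 <- M2 + unclass(table(factor(iz[ok], levels = seq_len(Jz)),
                             factor(ib[ok], levels = seq_len(Jb))))
  }
  p2 <- sweep(M2, 1, sol$denom, "/")
  p2[M2 == 0] <- NA_real_
  if (jacobian_correct) p2 <- sweep(p2, 2, bc, "/")
  G <- -kBT * log(p2)
  occ <- is.finite(G)
  zmat <- matrix(zc, Jz, Jb)
  bulk <- occ & abs(zmat) >= 24 & abs(zmat) <= 25
  if (any(bulk)) {
    G <- G - mean(G[bulk])
    anchor <- "mean over cells with |z| in [24, 25] A = 0"
  } else {
    G <- G - mean(G[occ])
    anchor <- "mean over occupied cells = 0 (no bulk cells occupied)"
  }
  free_energy_profile(zc, G, n_eff = M2, anchor = anchor, T = T,
                      b_centers = bc)
}
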