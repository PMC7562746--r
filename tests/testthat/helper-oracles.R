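# Independent oracles, deliberately written as naive loops so they share no
# code path with the package implementations they check.

# Brute-force solver of the WHAM self-consistent equations, scalar loops,
# fixed-point iterated to near machine precision. Returns anchored G per
# bin (mean over occupied bins = 0), NA in unoccupied bins.
oracle_wham_1d <- function(windows, bin_edges, kBT, n_iter = 2e4) {
  J <- length(bin_edges) - 1
  K <- length(windows)
  centers <- numeric(J)
  for (j in 1:J) centers[j] <- (bin_edges[j] + bin_edges[j + 1]) / 2
  counts <- matrix(0, K, J)
  for (k in 1:K) {
    zz <- windows[[k]]$samples$z
    for (v in zz) {
      for (j in 1:J) {
        if (v >= bin_edges[j] && (v < bin_edges[j + 1] ||
            (j == J && v <= bin_edges[j + 1]))) {
          counts[k, j] <- counts[k, j] + 1
          break
        }
      }
    }
  }
  w <- matrix(0, K, J)
  for (k in 1:K) {
    b <- windows[[k]]$bias
    if (!is.null(b)) {
      for (j in 1:J) w[k, j] <- 0.5 * b$k * (centers[j] - b$z0)^2
    }
  }
  N <- rowSums(counts)
  M <- colSums(counts)
  f <- rep(0, K)
  p <- rep(0, J)
  for (it in 1:n_iter) {
    for (j in 1:J) {
      den <- 0
      for (k in 1:K) den <- den + N[k] * exp((f[k] - w[k, j]) / kBT)
      p[j] <- if (M[j] > 0) M[j] / den else 0
    }
    fn <- numeric(K)
    for (k in 1:K) {
      s <- 0
      for (j in 1:J) s <- s + p[j] * exp(-w[k, j] / kBT)
      fn[k] <- -kBT * log(s)
    }
    fn <- fn - mean(fn)
    if (max(abs(fn - f)) < 1e-13) { f <- fn; break }
    f <- fn
  }
  G <- ifelse(M > 0, -kBT * log(p), NA_real_)
  G - mean(G[is.finite(G)])
}

# Dense xy-grid search for the maximal inscribed-sphere radius at one
# z-slice (step 0.02 A over a disc of radius 3 A about the axis).
oracle_pore_radius <- function(frame, z0, halfwidth = 3, step = 0.02,
                               atoms_idx = NULL) {
  a <- frame$atoms
  if (!is.null(atoms_idx)) a <- a[atoms_idx, , drop = FALSE]
  g <- seq(-halfwidth, halfwidth, by = step)
  best <- -Inf
  px <- a$x; py <- a$y; dz2 <- (a$z - z0)^2; vv <- a$vdw
  for (x in g) {
    gy <- g[x^2 + g^2 <= halfwidth^2 + 1e-12]
    if (!length(gy)) next
    dx2dz2 <- (px - x)^2 + dz2
    dy2 <- outer(py, gy, function(p, y) (p - y)^2)  # natoms x ny
    d <- sqrt(dy2 + dx2dz2)        # vector recycles down columns
    r <- apply(d - vv, 2, min)     # vv recycles down columns too
    best <- max(best, max(r))
  }
  best
}

# toy 3-window dataset for oracle-equivalence checks
make_toy_windows <- function(seed = 1, n = 200) {
  set.seed(seed)
  restr <- cylinder_restraint()
  lapply(c(-1, 0, 1), function(z0) {
    z <- stats::rnorm(n, z0, 0.6)
    umbrella_window_data(harmonic_bias(z0, k = 2), restr, T = 303.15,
                         data.frame(time = seq_len(n) * 0.1, z = z,
                                    b = rep(1, n)),
                         sample_interval = 0.1)
  })
}

# residue selections used by contact analyses of the synthetic hexamer
hexamer_residues <- function() {
  list(ARG = list(resid = "ARG", resno = 11),
       SER = list(resid = "SER", resno = 39),
       LYS = list(resid = "LYS", resno = 36))
}
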