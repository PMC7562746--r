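# breadth-first reachability over a boolean adjacency matrix
bfs_reach <- function(adj, start = 1L) {
  n <- nrow(adj)
  seen <- logical(n)
  seen[start] <- TRUE
  frontier <- start
  while (length(frontier)) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  seen
}

#' 1D dynamic histogram analysis method (DHAM)
#'
#' Markov-model unbiasing of umbrella-window trajectories: per-window
#' transition counts between z bins at a fixed lag are combined into a
#' single unbiased transition matrix using symmetric square-root bias
#' factors `exp(-(w(bin_j) - w(bin_i)) / (2 kBT))`, and the free energy is
#' read off the stationary distribution, `G = -kBT log(pi)`, anchored as in
#' [wham_1d()]. Unvisited bins are removed from the chain and reported as
#' NA (masked).
#'
#' @inheritParams wham_1d
#' @param lag transition lag in sample counts (default 1).
#' @return a [free_energy_profile()].
#' @references Rosta & Hummer (2015) J Chem Theory Comput 11:276 (DHAM).
#' @export
dham_1d <- function(windows, bin_edges = default_bin_edges(), lag = 1L) {
  stopifnot(length(windows) >= 1, lag >= 1)
  T <- check_uniform_T(windows)
  kBT <- thermal_energy(T)
  ints <- vapply(windows, `[[`, numeric(1), "sample_interval")
  if (diff(range(ints)) > 1e-9) {
    stop("windows must share one sampling interval", call. = FALSE)
  }
  centers <- (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2
  J <- length(centers)
  w <- window_bias_matrix(windows, centers)

  num <- matrix(0, J, J)     # pooled transition counts
  den <- matrix(0, J, J)     # ML denominator
  for (k in seq_along(windows)) {
    zz <- windows[[k]]$samples$z
    s <- findInterval(zz, bin_edges, rightmost.closed = TRUE)
    s[s < 1 | s > J] <- NA
    from <- s[seq_len(length(s) - lag)]
    to <- s[seq_len(length(s) - lag) + lag]
    ok <- !is.na(from) & !is.na(to)
    if (!any(ok)) next
    C_k <- matrix(tabulate((to[ok] - 1) * J + from[ok], nbins = J * J), J, J)
    num <- num + C_k
    N_i <- rowSums(C_k)
    # den_ij = sum_k N^k_i exp(+w_ki / 2kBT) exp(-w_kj / 2kBT);
    # exponentials only evaluated where the window has transitions
    a <- numeric(J)
    vis <- N_i > 0
    a[vis] <- N_i[vis] * exp(w[k, vis] / (2 * kBT))
    den <- den + outer(a, exp(-w[k, ] / (2 * kBT)))
  }
  visited <- rowSums(num) + colSums(num) > 0
  if (!any(visited)) stop("no transitions observed", call. = FALSE)
  V <- which(visited)
  Mv <- matrix(0, length(V), length(V))
  nz <- num[V, V, drop = FALSE] > 0
  Mv[nz] <- (num[V, V, drop = FALSE] / den[V, V, drop = FALSE])[nz]
  # connectivity of the visited chain (strong, via the count graph)
  fwd <- bfs_reach(nz | diag(TRUE, length(V)))
  bwd <- bfs_reach(t(nz) | diag(TRUE, length(V)))
  if (!all(fwd & bwd)) {
    stop("disconnected bin graph: the visited bins do not form a single ",
         "communicating Markov chain (check window overlap or lag)",
         call. = FALSE)
  }
  Mv <- Mv / rowSums(Mv)
  ev <- eigen(t(Mv))
  i1 <- which.min(abs(ev$values - 1))
  pi_v <- abs(Re(ev$vectors[, i1]))
  pi_v <- pi_v / sum(pi_v)
  G <- rep(NA_real_, J)
  G[V] <- -kBT * log(pi_v)
  n_eff <- rowSums(num)
  anc <- anchor_profile(G, centers)
  free_energy_profile(centers, anc$G, n_eff = n_eff, anchor = anc$anchor,
                      T = T)
}
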