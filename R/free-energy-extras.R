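#' Block-splitting error estimation for free-energy profiles
#'
#' Divides each window's trajectory into `n_blocks` contiguous equal-length
#' segments, runs the estimator independently on each segment-dataset, and
#' reports the per-bin mean and standard error of the mean across blocks —
#' the standard convergence diagnostic of splitting each umbrella window
#' into equal-length sub-trajectories (default 5).
#'
#' @param windows list of `umbrella_window_data`.
#' @param n_blocks number of segments (>= 2, default 5).
#' @param estimator profile estimator applied per block (default
#'   [wham_1d()]).
#' @param ... passed to the estimator (e.g. `bin_edges`, `tol`).
#' @return a [free_energy_profile()] with `G` the across-block mean and
#'   `stderr` the standard error; bins not occupied in every block are NA.
#' @export
split_block_errors <- function(windows, n_blocks = 5, estimator = wham_1d,
                               ...) {
  stopifnot(n_blocks >= 2)
  n_min <- min(vapply(windows, function(w) nrow(w$samples), integer(1)))
  if (n_min < n_blocks) {
    stop("each window needs at least n_blocks samples", call. = FALSE)
  }
  profiles <- lapply(seq_len(n_blocks), function(b) {
    sub <- lapply(windows, function(wd) {
      n <- nrow(wd$samples)
      cut <- floor(n / n_blocks)
      idx <- ((b - 1) * cut + 1):(b * cut)
      umbrella_window_data(wd$bias, wd$restraint, wd$T,
                           wd$samples[idx, , drop = FALSE],
                           wd$sample_interval, wd$meta)
    })
    estimator(sub, ...)
  })
  Gmat <- vapply(profiles, `[[`, profiles[[1]]$G, "G")
  G <- rowMeans(Gmat)
  stderr <- apply(Gmat, 1, stats::sd) / sqrt(n_blocks)
  n_eff <- Reduce(`+`, lapply(profiles, function(p) {
    ifelse(is.na(p$n_eff), 0, p$n_eff)
  }))
  free_energy_profile(profiles[[1]]$bin_centers, G, stderr = stderr,
                      n_eff = n_eff,
                      anchor = paste0(profiles[[1]]$anchor,
                                      sprintf(" (mean of %d blocks)",
                                              n_blocks)),
                      T = profiles[[1]]$T)
}

#' Free energy from unbiased trajectory densities
#'
#' Pools unbiased trajectories (e.g. free ions confined to the restraint
#' cylinder), histograms the axial coordinate and converts density to free
#' energy, `G = -kBT log(density)`, anchored to bulk. The density is
#' normalized over the pooled sample, so duplicating a trajectory does not
#' change the profile. Empty bins are reported as NA.
#'
#' @param trajectories list of data.frames with a `z` column (A), or a
#'   single data.frame.
#' @param bin_edges histogram bin edges, A.
#' @param T temperature, K.
#' @return a [free_energy_profile()].
#' @export
density_free_energy <- function(trajectories,
                                bin_edges = default_bin_edges(),
                                T = 303.15) {
  if (is.data.frame(trajectories)) trajectories <- list(trajectories)
  stopifnot(length(trajectories) >= 1)
  z <- unlist(lapply(trajectories, `[[`, "z"))
  counts <- bin_counts(z, bin_edges)
  if (sum(counts) == 0) {
    stop("no samples fall inside the bin range", call. = FALSE)
  }
  widths <- diff(bin_edges)
  dens <- counts / (sum(counts) * widths)
  kBT <- thermal_energy(T)
  G <- ifelse(counts > 0, -kBT * log(dens), NA_real_)
  centers <- (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2
  anc <- anchor_profile(G, centers)
  free_energy_profile(centers, anc$G, n_eff = counts, anchor = anc$anchor,
                      T = T)
}

#' Autocorrelation function and integrated autocorrelation time
#'
#' Mean-removed normalized autocorrelation of a scalar series (e.g. the
#' pore surface area along a trajectory), with the integrated
#' autocorrelation time computed by the initial-positive-sequence rule:
#' `tau = interval * (1 + 2 * sum(acf(k)))`, summing successive lags until
#' the first negative ACF value.
#'
#' @param series numeric vector (>= 10 finite values, nonzero variance).
#' @param max_lag maximum lag to evaluate (default `min(n - 1, 5000)`).
#' @param interval sampling interval (ps) used to scale lags and tau.
#' @return list with `lags` (ps), `acf` (dimensionless, acf\[1\] = 1 at lag
#'   0) and `tau` (ps), of class `acf_result`.
#' @export
autocorrelation <- function(series, max_lag = NULL, interval = 1) {
  series <- as.numeric(series)
  if (length(series) < 10) stop("need at least 10 samples", call. = FALSE)
  if (!all(is.finite(series))) stop("series must be finite", call. = FALSE)
  if (stats::var(series) == 0) {
    stop("zero-variance series has no autocorrelation time", call. = FALSE)
  }
  if (is.null(max_lag)) max_lag <- min(length(series) - 1, 5000)
  rho <- as.vector(stats::acf(series, lag.max = max_lag, plot = FALSE,
                              demean = TRUE)$acf)
  neg <- which(rho[-1] < 0)
  m <- if (length(neg)) neg[1] - 1 else max_lag
  tau <- interval * (1 + 2 * sum(rho[1 + seq_len(m)]))
  tau <- max(tau, interval)        # floor at one sampling interval
  structure(list(lags = interval * (0:max_lag), acf = rho, tau = tau),
            class = "acf_result")
}

#' @export
print.acf_result <- function(x, ...) {
  cat(sprintf("<acf_result> %d lags, tau = %.4g\n", length(x$lags), x$tau))
  invisible(x)
}

#' Locate minima, maxima and barriers of a 1D profile
#'
#' Finds interior local extrema of a free-energy profile after optional
#' 3-bin moving-average smoothing. Each maximum is reported both relative
#' to the profile's anchor (bulk solvent) and as a barrier height relative
#' to the lower of its two adjacent minima.
#'
#' @param profile a 1D [free_energy_profile()].
#' @param smooth apply 3-bin smoothing before extremum detection (default
#'   TRUE).
#' @param min_prominence drop adjacent extremum pairs closer in G than
#'   this (kcal/mol, default 0 = keep everything); useful to read planted
#'   features off a noisy reconstruction.
#' @return data.frame with columns `z`, `G`, `type` ("minimum"/"maximum")
#'   and `barrier` (kcal/mol; NA for minima). May have zero rows.
#' @export
profile_features <- function(profile, smooth = TRUE, min_prominence = 0) {
  stopifnot(inherits(profile, "free_energy_profile"), profile$dim == 1L)
  z <- profile$bin_centers
  G <- profile$G
  keep <- is.finite(G)
  z <- z[keep]; G0 <- G[keep]
  empty <- data.frame(z = numeric(), G = numeric(), type = character(),
                      barrier = numeric())
  if (length(G0) < 3) return(empty)
  G <- G0
  if (smooth && length(G) >= 3) {
    sm <- as.vector(stats::filter(G, rep(1 / 3, 3)))
    G[!is.na(sm)] <- sm[!is.na(sm)]
  }
  d <- diff(G)
  s <- sign(d)
  s[s == 0] <- 1e-12   # treat flats as ascending so plateaus give one hit
  turn <- which(diff(sign(s)) != 0) + 1
  if (!length(turn)) return(empty)
  # prune alternating extrema whose G-gap to a neighbor is below the
  # prominence threshold (removes noise wiggles pairwise)
  if (min_prominence > 0) {
    repeat {
      if (length(turn) < 2) break
      gaps <- abs(diff(G[turn]))
      worst <- which.min(gaps)
      if (gaps[worst] >= min_prominence) break
      turn <- turn[-c(worst, worst + 1)]
    }
    if (!length(turn)) return(empty)
  }
  rows <- lapply(turn, function(i) {
    is_max <- G[i] > G[i - 1]
    barrier <- NA_real_
    if (is_max) {
      left_min <- min(G0[seq_len(i - 1)])
      right_min <- min(G0[i:length(G0)])
      barrier <- G0[i] - min(left_min, right_min)
    }
    data.frame(z = z[i], G = G0[i],
               type = if (is_max) "maximum" else "minimum",
               barrier = barrier)
  })
  do.call(rbind, rows)
}
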