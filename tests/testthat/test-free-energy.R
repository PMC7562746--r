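kBT303 <- 1.987204e-3 * 303.15

test_that("WHAM matches an independent brute-force solver on a toy dataset", {
  windows <- make_toy_windows(seed = 2, n = 200)
  edges <- seq(-3, 3, by = 0.5)
  got <- wham_1d(windows, edges, tol = 1e-12)
  G <- got$G - mean(got$G[is.finite(got$G)])   # same gauge as the oracle
  want <- oracle_wham_1d(windows, edges, kBT303)
  expect_equal(which(is.finite(G)), which(is.finite(want)))
  expect_lt(max(abs(G - want), na.rm = TRUE), 1e-8)
})

test_that("single unbiased window degenerates to the direct histogram", {
  set.seed(4)
  restr <- cylinder_restraint()
  z <- runif(4000, -5, 5)
  w <- umbrella_window_data(NULL, restr, 303.15,
                            data.frame(time = seq_along(z), z = z, b = 1),
                            sample_interval = 1)
  edges <- seq(-5, 5, by = 1)
  got <- wham_1d(list(w), edges)
  ref <- density_free_energy(data.frame(z = z), edges)
  expect_lt(max(abs(got$G - ref$G), na.rm = TRUE), 1e-8)
  # flat within sampling error
  expect_lt(diff(range(got$G, na.rm = TRUE)), 0.2)
})

test_that("non-overlapping windows raise a gap error naming the gap", {
  restr <- cylinder_restraint()
  mk <- function(z0) {
    set.seed(1)
    z <- rnorm(100, z0, 0.1)
    umbrella_window_data(harmonic_bias(z0, 5), restr, 303.15,
                         data.frame(time = 1:100, z = z, b = 1),
                         sample_interval = 1)
  }
  expect_error(wham_1d(list(mk(-5), mk(5)), seq(-6, 6, 0.5)),
               "z0 = -5.00 and 5.00")
})

test_that("WHAM anchoring zeroes the bulk bins", {
  ds <- generate_us_dataset(pmf_fixture("barrier_1"),
                            place_windows(), n_steps = 2000, seed = 21)
  p <- wham_1d(ds)
  ctr <- p$bin_centers
  bulk <- abs(ctr) >= 24 & abs(ctr) <= 25 & is.finite(p$G)
  expect_gt(sum(bulk), 0)
  expect_lt(abs(mean(p$G[bulk])), 1e-6)
})

test_that("2D WHAM is consistent with 1D after marginalization", {
  ds <- generate_us_dataset(pmf_fixture("barrier_3.5"), place_windows(),
                            n_steps = 8000, seed = 31)
  p1 <- wham_1d(ds)
  p2 <- wham_2d(ds, b_edges = seq(0, 15, 3), jacobian_correct = FALSE)
  # marginalize the 2D probabilities back onto z
  kBT <- thermal_energy(303.15)
  pz <- rowSums(exp(-p2$G / kBT), na.rm = TRUE)
  Gm <- -kBT * log(pz)
  occ <- is.finite(p1$G) & is.finite(Gm) & pz > 0
  dev <- (Gm - p1$G)[occ]
  dev <- dev - mean(dev)             # common shift is gauge
  expect_lt(max(abs(dev)), 0.15)
})

test_that("radial Jacobian correction flattens a free radial coordinate", {
  # longer, faster-diffusing runs so the radial coordinate equilibrates
  ds <- generate_us_dataset(pmf_fixture("flat"),
                            place_windows(-4, 4, 1), n_steps = 3e4,
                            dt = 0.01, D = 1, seed = 41)
  p_on <- wham_2d(ds, z_edges = seq(-4.5, 4.5, 1), b_edges = seq(0, 15, 3),
                  jacobian_correct = TRUE)
  p_off <- wham_2d(ds, z_edges = seq(-4.5, 4.5, 1), b_edges = seq(0, 15, 3),
                   jacobian_correct = FALSE)
  Gb_on <- colMeans(p_on$G, na.rm = TRUE)
  Gb_off <- colMeans(p_off$G, na.rm = TRUE)
  expect_lt(diff(range(Gb_on)), 0.35)
  # without the correction G falls like -kBT log b
  kBT <- thermal_energy(303.15)
  pred <- -kBT * log(p_off$b_centers)
  dev <- (Gb_off - pred) - mean(Gb_off - pred)
  expect_lt(max(abs(dev)), 0.35)
  expect_lt(Gb_off[5], Gb_off[1])
})

test_that("DHAM recovers a symmetric two-state chain exactly", {
  # series engineered to give transition counts [[9,1],[1,9]], no bias
  restr <- cylinder_restraint()
  z <- c(rep(0.25, 10), rep(0.75, 10), 0.25)
  w <- umbrella_window_data(NULL, restr, 303.15,
                            data.frame(time = seq_along(z), z = z, b = 1),
                            sample_interval = 1)
  p <- dham_1d(list(w), bin_edges = c(0, 0.5, 1))
  expect_equal(p$G[1], p$G[2], tolerance = 1e-12)
})

test_that("DHAM masks unvisited bins and flags disconnected chains", {
  restr <- cylinder_restraint()
  z <- c(rep(0.25, 6), rep(0.75, 6), 0.25)
  w <- umbrella_window_data(NULL, restr, 303.15,
                            data.frame(time = seq_along(z), z = z, b = 1),
                            sample_interval = 1)
  p <- dham_1d(list(w), bin_edges = c(0, 0.5, 1, 1.5, 2))
  expect_true(all(is.na(p$G[3:4])))
  # two windows confined to non-communicating bins
  mkw <- function(val) umbrella_window_data(
    NULL, restr, 303.15,
    data.frame(time = 1:6, z = rep(val, 6), b = 1), sample_interval = 1)
  expect_error(dham_1d(list(mkw(0.25), mkw(1.75)),
                       bin_edges = c(0, 0.5, 1, 1.5, 2)),
               "disconnected")
})

test_that("DHAM agrees with WHAM on synthetic umbrella data", {
  ds <- generate_us_dataset(pmf_fixture("barrier_1"), place_windows(),
                            n_steps = 5000, seed = 51)
  pw <- wham_1d(ds)
  pd <- dham_1d(ds)
  pe <- split_block_errors(ds, 5)
  lim <- 3 * pooled_stderr(pe)
  expect_lt(max(abs(pw$G - pd$G), na.rm = TRUE), lim)
})

test_that("block splitting yields positive errors that shrink with sampling", {
  ds <- generate_us_dataset(pmf_fixture("barrier_1"), place_windows(),
                            n_steps = 4000, seed = 61)
  pe <- split_block_errors(ds, 5)
  interior <- abs(pe$bin_centers) < 20 & is.finite(pe$G)
  expect_true(all(pe$stderr[interior] > 0))

  # duplicated samples in every block give zero error
  restr <- cylinder_restraint()
  set.seed(62)
  blk <- rnorm(50, 0, 0.4)
  z <- rep(blk, 5)
  w <- umbrella_window_data(harmonic_bias(0, 5), restr, 303.15,
                            data.frame(time = seq_along(z), z = z, b = 1),
                            sample_interval = 1)
  p0 <- split_block_errors(list(w), 5, bin_edges = seq(-2, 2, 0.5))
  expect_lt(max(p0$stderr, na.rm = TRUE), 1e-12)

  # quadrupling the samples shrinks the pooled error roughly as 1/sqrt(n)
  ds4 <- generate_us_dataset(pmf_fixture("barrier_1"), place_windows(),
                             n_steps = 16000, seed = 61)
  pe4 <- split_block_errors(ds4, 5)
  ratio <- pooled_stderr(pe) / pooled_stderr(pe4)
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.7)

  expect_error(split_block_errors(list(umbrella_window_data(
    harmonic_bias(0, 5), restr, 303.15,
    data.frame(time = 1:3, z = rnorm(3), b = 1), 1)), 5), "n_blocks")
})

test_that("density-based free energy recovers planted barriers and is
           invariant to trajectory duplication", {
  edges <- default_bin_edges()
  ctr <- (edges[-1] + edges[-length(edges)]) / 2
  kBT <- thermal_energy(303.15)
  # inverse-CDF sampling from the Boltzmann density of a 3.5 kcal barrier
  m <- pmf_fixture("barrier_3.5")
  zg <- seq(-26, 26, by = 0.005)
  dens <- exp(-evaluate_pmf(m, zg) / kBT)
  cdf <- cumsum(dens) / sum(dens)
  set.seed(71)
  z <- approx(cdf, zg, xout = runif(2e6), rule = 2)$y
  prof <- density_free_energy(data.frame(z = z), edges)
  peak_bin <- which.min(abs(ctr - (-6)))
  stderr_peak <- kBT / sqrt(prof$n_eff[peak_bin])
  expect_lt(abs(max(prof$G, na.rm = TRUE) - 3.5), 3 * stderr_peak)

  # duplication invariance
  tr <- data.frame(z = z[1:5000])
  p1 <- density_free_energy(tr, edges)
  p2 <- density_free_energy(list(tr, tr), edges)
  expect_equal(p1$G, p2$G)

  # uniform samples spanning the full bin support give a flat profile
  set.seed(72)
  pu <- density_free_energy(data.frame(z = runif(2e5, -26.25, 26.25)), edges)
  expect_lt(diff(range(pu$G, na.rm = TRUE)), 0.2)
  expect_error(density_free_energy(data.frame(z = 100), edges), "no samples")
})

test_that("integrated autocorrelation time follows closed forms", {
  set.seed(81)
  # white noise: tau equals the sampling interval
  x <- rnorm(1e5)
  ac <- autocorrelation(x, max_lag = 200, interval = 2)
  expect_lt(abs(ac$tau - 2) / 2, 0.2)
  expect_equal(ac$acf[1], 1)

  # AR(1): tau = (1 + phi) / (1 - phi) * interval
  phi <- 0.9
  y <- as.numeric(arima.sim(list(ar = phi), 2e5))
  ac2 <- autocorrelation(y, max_lag = 2000)
  expect_lt(abs(ac2$tau - 19) / 19, 0.25)
  expect_gt(ac2$tau, 0)

  # an umbrella window decorrelates much faster than its own length
  w <- simulate_window(simulation_spec(
    pmf_fixture("three_well"), harmonic_bias(-5, 5), n_steps = 1e4,
    seed = 82))
  acw <- autocorrelation(w$samples$z, max_lag = 2000,
                         interval = w$sample_interval)
  expect_lt(acw$tau, nrow(w$samples) * w$sample_interval / 10)

  expect_error(autocorrelation(rep(1, 100)), "variance")
  expect_error(autocorrelation(rnorm(5)), "10 samples")
  # near-degenerate spike series: tau reported at the floor
  spike <- c(rep(0, 99), 1, rep(0, 100))
  expect_gte(autocorrelation(spike)$tau, 1)
})

test_that("profile features locate extrema and barrier heights", {
  zs <- seq(-26, 26, 0.5)
  mk_prof <- function(model) {
    free_energy_profile(zs, evaluate_pmf(model, zs))
  }
  f <- profile_features(mk_prof(pmf_fixture("barrier_3.8")), smooth = FALSE)
  m <- f[f$type == "maximum", ]
  expect_equal(nrow(m), 1)
  expect_equal(m$z, -6)
  expect_equal(m$barrier, 3.8, tolerance = 1e-3)

  # monotone profile: no interior extrema
  mono <- free_energy_profile(zs, 0.1 * zs)
  expect_equal(nrow(profile_features(mono)), 0)

  # three-well landscape: the three planted minima in order
  f3 <- profile_features(mk_prof(pmf_fixture("three_well")),
                         smooth = FALSE, min_prominence = 0.5)
  mins <- f3[f3$type == "minimum", ]
  expect_equal(nrow(mins), 3)
  expect_equal(mins$z, c(-12, -5, 6), tolerance = 0.6)
})
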