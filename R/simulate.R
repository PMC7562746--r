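#' Simulation specification for one Brownian-dynamics run
#'
#' Bundles everything needed to propagate one particle: the ground-truth
#' PMF, an optional umbrella bias, the cylindrical restraint, and the
#' integrator settings. The integrator is overdamped Langevin
#' (Euler-Maruyama): full molecular dynamics is deliberately replaced by a
#' stochastic model that reproduces the statistics of the collective
#' variables (z, b), which is all the downstream estimators see.
#'
#' @param model a [pmf_model()].
#' @param bias a [harmonic_bias()] or NULL for an unbiased particle.
#' @param restraint a [cylinder_restraint()].
#' @param n_steps number of integration steps (default 1e4).
#' @param dt time step, ps (default 0.05).
#' @param D diffusion coefficient, A^2/ps (default 0.2).
#' @param T temperature, K (default 303.15).
#' @param seed integer RNG seed (required; runs are deterministic given it).
#' @param sample_stride keep every `sample_stride`-th step (default 1).
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(model, bias = NULL,
                            restraint = cylinder_restraint(),
                            n_steps = 1e4, dt = 0.05, D = 0.2, T = 303.15,
                            seed = 1L, sample_stride = 1L) {
  stopifnot(inherits(model, "pmf_model"),
            is.null(bias) || inherits(bias, "harmonic_bias"),
            inherits(restraint, "cylinder_restraint"),
            dt > 0, D > 0, T > 0, n_steps >= sample_stride,
            sample_stride >= 1)
  structure(list(model = model, bias = bias, restraint = restraint,
                 n_steps = as.integer(n_steps), dt = dt, D = D, T = T,
                 seed = as.integer(seed),
                 sample_stride = as.integer(sample_stride)),
            class = "simulation_spec")
}

# run the compiled stepper for one spec from a given start point
run_chain <- function(spec, z_init, b_init) {
  m <- spec$model
  r <- spec$restraint
  xy <- .bd_chain(z_init, b_init,
                  spec$n_steps, spec$sample_stride, spec$dt, spec$D,
                  thermal_energy(spec$T),
                  m$heights, m$centers, m$widths, m$radial_k,
                  !is.null(spec$bias),
                  if (is.null(spec$bias)) 0 else spec$bias$k,
                  if (is.null(spec$bias)) 0 else spec$bias$z0,
                  r$z_min, r$z_max, r$b_max, r$wall_k,
                  TRUE, 0.05)
  dt_s <- spec$dt * spec$sample_stride
  data.frame(time = dt_s * seq_len(nrow(xy)), z = xy[, 1], b = xy[, 2])
}

#' Simulate one umbrella window
#'
#' Propagates a particle under `U_pmf + U_bias + U_restraint` by overdamped
#' Langevin dynamics, starting at the bias center with the radial
#' coordinate drawn uniformly in `[0, b_max/2]`. The radial coordinate is a
#' distance from the pore axis: it carries the entropic Jacobian drift
#' `(D/b) dt` and reflects at b = 0, so its unbiased density grows linearly
#' in b up to the cylinder wall.
#'
#' @param spec a [simulation_spec()] with a non-NULL bias.
#' @return an `umbrella_window_data` object: list with elements `bias`,
#'   `restraint`, `T`, `samples` (data.frame time/z/b, ps and A),
#'   `sample_interval` (ps) and `meta`.
#' @export
simulate_window <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (is.null(spec$bias)) {
    stop("simulate_window requires a bias; use simulate_free_ions for ",
         "unbiased particles", call. = FALSE)
  }
  set.seed(spec$seed)
  b0 <- stats::runif(1, 0, spec$restraint$b_max / 2)
  samples <- run_chain(spec, spec$bias$z0, b0)
  umbrella_window_data(spec$bias, spec$restraint, spec$T, samples,
                       sample_interval = spec$dt * spec$sample_stride,
                       meta = list(seed = spec$seed, dt = spec$dt,
                                   D = spec$D, model = spec$model$name))
}

#' Construct an umbrella window dataset
#'
#' @param bias,restraint,T bias, restraint and temperature of the window.
#' @param samples data.frame with columns time (ps, strictly increasing),
#'   z and b (A); at least two rows.
#' @param sample_interval sampling interval, ps.
#' @param meta optional metadata list.
#' @return object of class `umbrella_window_data`.
#' @export
umbrella_window_data <- function(bias, restraint, T, samples,
                                 sample_interval, meta = list()) {
  stopifnot(is.data.frame(samples),
            all(c("time", "z", "b") %in% names(samples)),
            nrow(samples) >= 2,
            all(diff(samples$time) > 0))
  structure(list(bias = bias, restraint = restraint, T = T,
                 samples = samples, sample_interval = sample_interval,
                 meta = meta),
            class = "umbrella_window_data")
}

#' @export
print.umbrella_window_data <- function(x, ...) {
  cat(sprintf(
    "<umbrella_window_data> z0 = %.2f A, k = %.2f kcal/mol/A^2, %d samples @ %.3g ps\n",
    x$bias$z0, x$bias$k, nrow(x$samples), x$sample_interval))
  invisible(x)
}

#' Generate a full umbrella-sampling dataset
#'
#' One simulated window per bias in `windows`. Window i (1-based) is seeded
#' with `seed + i`, so the whole dataset is reproducible from the master
#' seed and individual windows can be regenerated in isolation.
#'
#' @param model ground-truth [pmf_model()].
#' @param windows list of [harmonic_bias()], e.g. from [place_windows()].
#' @param restraint a [cylinder_restraint()].
#' @param n_steps,dt,D,T,sample_stride integrator settings shared by all
#'   windows (see [simulation_spec()]).
#' @param seed master seed.
#' @return list of `umbrella_window_data`, in window order.
#' @export
generate_us_dataset <- function(model, windows = place_windows(),
                                restraint = cylinder_restraint(),
                                n_steps = 1e4, dt = 0.05, D = 0.2,
                                T = 303.15, sample_stride = 1L, seed = 1L) {
  if (length(windows) == 0) stop("empty window list", call. = FALSE)
  lapply(seq_along(windows), function(i) {
    simulate_window(simulation_spec(
      model, bias = windows[[i]], restraint = restraint,
      n_steps = n_steps, dt = dt, D = D, T = T,
      seed = seed + i, sample_stride = sample_stride))
  })
}

#' Simulate unbiased ions in the restraint cylinder
#'
#' Each ion is an independent overdamped-Langevin walker under
#' `U_pmf + U_restraint` only (no umbrella bias), mirroring the treatment
#' of free K+/Cl- ions whose trajectories are interpreted as independent
#' simulations. Ion i is seeded with `seed + i`; initial z is uniform in
#' the cylinder, initial b drawn from the linear radial density.
#'
#' @param model ground-truth [pmf_model()].
#' @param restraint a [cylinder_restraint()].
#' @param n_ions number of independent ions (>= 1).
#' @param n_steps,dt,D,T,sample_stride integrator settings.
#' @param seed master seed.
#' @return list of data.frames (time, z, b), one per ion.
#' @export
simulate_free_ions <- function(model, restraint = cylinder_restraint(),
                               n_ions = 7, n_steps = 1e4, dt = 0.05,
                               D = 0.2, T = 303.15, sample_stride = 1L,
                               seed = 1L) {
  stopifnot(n_ions >= 1)
  lapply(seq_len(n_ions), function(i) {
    spec <- simulation_spec(model, bias = NULL, restraint = restraint,
                            n_steps = n_steps, dt = dt, D = D, T = T,
                            seed = seed + i, sample_stride = sample_stride)
    set.seed(spec$seed)
    z0 <- stats::runif(1, restraint$z_min, restraint$z_max)
    b0 <- restraint$b_max * sqrt(stats::runif(1))
    run_chain(spec, z0, b0)
  })
}

#' Write an umbrella window to a columnar text file
#'
#' Header lines of the form `# key=value` (z0, k, T, dt, stride, seed)
#' followed by whitespace-separated columns time, z, b — the layout of a
#' collective-variable trajectory file printed during biased sampling.
#'
#' @param window an `umbrella_window_data`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_window <- function(window, path) {
  stopifnot(inherits(window, "umbrella_window_data"))
  hdr <- c(sprintf("# z0=%.10g", window$bias$z0),
           sprintf("# k=%.10g", window$bias$k),
           sprintf("# T=%.10g", window$T),
           sprintf("# dt=%.10g", window$meta$dt %||% window$sample_interval),
           sprintf("# stride=%d",
                   as.integer(round(window$sample_interval /
                                    (window$meta$dt %||% window$sample_interval)))),
           sprintf("# seed=%d", as.integer(window$meta$seed %||% NA)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(window$samples, con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an umbrella window from a columnar text file
#'
#' @param path file written by [write_window()].
#' @param restraint restraint to attach (not stored in the file).
#' @return an `umbrella_window_data`.
#' @export
read_window <- function(path, restraint = cylinder_restraint()) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^#\\s*", "", hdr), "="))
  vals <- stats::setNames(as.numeric(kv[, 2]), kv[, 1])
  samples <- utils::read.table(text = lines[!grepl("^#", lines)],
                               col.names = c("time", "z", "b"))
  umbrella_window_data(
    harmonic_bias(vals[["z0"]], vals[["k"]]), restraint, vals[["T"]],
    samples,
    sample_interval = vals[["dt"]] * vals[["stride"]],
    meta = list(seed = vals[["seed"]], dt = vals[["dt"]]))
}
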