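#' Boltzmann constant in kcal mol^-1 K^-1
#'
#' @format A length-one numeric, 1.987204e-3 kcal mol^-1 K^-1.
#' @export
kB_kcal <- 1.987204e-3

#' Thermal energy kB*T
#'
#' @param T temperature in Kelvin (default 303.15 K, the simulation
#'   temperature used throughout the package).
#' @return kB*T in kcal mol^-1.
#' @examples
#' thermal_energy(303.15)
#' @export
thermal_energy <- function(T = 303.15) {
  if (!is.numeric(T) || any(T <= 0)) {
    stop("temperature must be positive (Kelvin)", call. = FALSE)
  }
  kB_kcal * T
}

#' Analytic potential of mean force model
#'
#' A ground-truth free-energy surface used by the synthetic data generator
#' and as the recovery target for the estimators. The axial part is a sum of
#' Gaussian wells/barriers in the pore-axis coordinate z; an optional
#' harmonic term in the radial coordinate b makes the model two-dimensional.
#' Heights are signed: positive terms are barriers, negative terms wells.
#' All models decay to 0 in bulk solvent (|z| >= 24 A) by construction, so
#' free-energy differences read off the model are automatically relative to
#' bulk.
#'
#' @param name model name (free text).
#' @param heights,centers,widths numeric vectors of equal length: Gaussian
#'   amplitudes (kcal/mol), centers (A) and standard-deviation widths (A).
#'   Centers must lie within ±13 A and widths in (0, 2.5] A so the model is
#'   numerically zero in bulk.
#' @param radial_k optional radial stiffness (kcal mol^-1 A^-2); a positive
#'   value makes the model 2D with U += 0.5 * radial_k * b^2.
#' @return An object of class `pmf_model`.
#' @seealso [pmf_fixture()] for the shipped fixtures, [evaluate_pmf()].
#' @export
pmf_model <- function(name, heights = numeric(), centers = numeric(),
                      widths = numeric(), radial_k = 0) {
  stopifnot(length(heights) == length(centers),
            length(heights) == length(widths))
  if (length(widths) && (any(widths <= 0) || any(widths > 2.5))) {
    stop("Gaussian widths must be in (0, 2.5] A for bulk anchoring",
         call. = FALSE)
  }
  if (length(centers) && any(abs(centers) > 13)) {
    stop("Gaussian centers must lie within |z| <= 13 A for bulk anchoring",
         call. = FALSE)
  }
  if (radial_k < 0) stop("radial_k must be >= 0", call. = FALSE)
  structure(
    list(name = as.character(name),
         heights = as.numeric(heights),
         centers = as.numeric(centers),
         widths = as.numeric(widths),
         radial_k = as.numeric(radial_k),
         dimensionality = if (radial_k > 0) 2L else 1L),
    class = "pmf_model")
}

#' @export
print.pmf_model <- function(x, ...) {
  cat(sprintf("<pmf_model '%s'> %dD, %d Gaussian term(s)",
              x$name, x$dimensionality, length(x$heights)))
  if (length(x$heights)) {
    cat(":\n")
    print(data.frame(height = x$heights, center = x$centers,
                     width = x$widths))
  } else cat(" (flat)\n")
  if (x$radial_k > 0) cat(sprintf("radial stiffness %.3g kcal/mol/A^2\n",
                                  x$radial_k))
  invisible(x)
}

#' Evaluate a PMF model
#'
#' @param model a [pmf_model()].
#' @param z axial coordinate(s), A; must lie in [-28, 28].
#' @param b radial coordinate(s), A; ignored for 1D models.
#' @return energy in kcal/mol (vectorized over `z`).
#' @export
evaluate_pmf <- function(model, z, b = NULL) {
  stopifnot(inherits(model, "pmf_model"))
  if (any(!is.finite(z)) || any(abs(z) > 28)) {
    stop("z outside the cylinder domain [-28, 28] A", call. = FALSE)
  }
  u <- rep(0, length(z))
  for (i in seq_along(model$heights)) {
    u <- u + model$heights[i] *
      exp(-0.5 * ((z - model$centers[i]) / model$widths[i])^2)
  }
  if (model$dimensionality == 2L && !is.null(b)) {
    u <- u + 0.5 * model$radial_k * b^2
  }
  u
}

#' Shipped ground-truth PMF fixtures
#'
#' A small library of analytic free-energy landscapes used as recovery
#' targets. `"three_well"` qualitatively echoes the landscape a metabolite
#' sees crossing a hexameric shell-protein pore: minima near the arginine
#' (z ~ -12 A) and lysine (z ~ +6 A) rings flanking a serine-ring barrier
#' region (z ~ -5 A). Barrier fixtures `"barrier_*"` place one Gaussian
#' barrier of the stated height (kcal/mol) near the constriction.
#'
#' @param name one of `"flat"`, `"barrier_1"`, `"barrier_3.5"`,
#'   `"barrier_3.8"`, `"barrier_7.6"`, `"double_well"`, `"three_well"`,
#'   `"repulsive"`.
#' @param radial_k optional radial stiffness to promote any fixture to 2D.
#' @return a [pmf_model()].
#' @export
pmf_fixture <- function(name = c("flat", "barrier_1", "barrier_3.5",
                                 "barrier_3.8", "barrier_7.6", "double_well",
                                 "three_well", "repulsive"),
                        radial_k = 0) {
  name <- match.arg(name)
  f <- switch(name,
    flat        = list(h = numeric(), c = numeric(), w = numeric()),
    barrier_1   = list(h = 1.0, c = -6, w = 2.0),
    "barrier_3.5" = list(h = 3.5, c = -6, w = 2.0),
    "barrier_3.8" = list(h = 3.8, c = -6, w = 2.0),
    "barrier_7.6" = list(h = 7.6, c = -4, w = 2.0),
    double_well = list(h = c(-3.0, -3.0), c = c(-5, 5), w = c(1.5, 1.5)),
    three_well  = list(h = c(-2.0, 1.8, -2.5, 1.2, -2.0),
                       c = c(-12, -8.5, -5, 0.5, 6),
                       w = c(1.5, 1.0, 1.5, 1.0, 1.5)),
    repulsive   = list(h = 4.0, c = 0, w = 2.5))
  pmf_model(name, heights = f$h, centers = f$c, widths = f$w,
            radial_k = radial_k)
}

#' Harmonic umbrella bias
#'
#' Umbrella potential 0.5 * k * (z - z0)^2 applied to the axial coordinate.
#' The one-half prefactor convention is used consistently by the simulator
#' and all estimators.
#'
#' @param z0 window center, A.
#' @param k force constant, kcal mol^-1 A^-2 (default 5.0).
#' @return object of class `harmonic_bias`.
#' @export
harmonic_bias <- function(z0, k = 5.0) {
  if (!is.numeric(k) || k <= 0) stop("k must be > 0", call. = FALSE)
  structure(list(z0 = as.numeric(z0), k = as.numeric(k)),
            class = "harmonic_bias")
}

#' Cylindrical flat-bottom restraint
#'
#' Confines a particle to the interior of a cylinder along the pore axis:
#' zero energy strictly inside `[z_min, z_max]` and `b <= b_max`, harmonic
#' walls (`0.5 * wall_k * excess^2`) beyond.
#'
#' @param z_min,z_max axial bounds, A (defaults -28, +28).
#' @param b_max maximal radial distance from the axis, A (default 15).
#' @param wall_k wall stiffness, kcal mol^-1 A^-2 (default 10).
#' @return object of class `cylinder_restraint`.
#' @export
cylinder_restraint <- function(z_min = -28, z_max = 28, b_max = 15,
                               wall_k = 10) {
  stopifnot(z_min < z_max, b_max > 0, wall_k >= 0)
  structure(list(z_min = z_min, z_max = z_max, b_max = b_max,
                 wall_k = wall_k),
            class = "cylinder_restraint")
}

#' Bias-plus-restraint energy
#'
#' Total external potential acting on the particle beyond the PMF: the
#' harmonic umbrella term (if `bias` is non-NULL; unbiased ions carry the
#' restraint only) plus the flat-bottom cylinder walls.
#'
#' @param bias a [harmonic_bias()] or NULL for unbiased particles.
#' @param restraint a [cylinder_restraint()].
#' @param z,b coordinates, A (vectorized).
#' @return energy in kcal/mol.
#' @export
bias_energy <- function(bias, restraint, z, b = 0) {
  stopifnot(inherits(restraint, "cylinder_restraint"))
  e <- rep(0, length.out = max(length(z), length(b)))
  if (!is.null(bias)) {
    stopifnot(inherits(bias, "harmonic_bias"))
    e <- e + 0.5 * bias$k * (z - bias$z0)^2
  }
  e <- e + 0.5 * restraint$wall_k * pmax(z - restraint$z_max, 0)^2
  e <- e + 0.5 * restraint$wall_k * pmax(restraint$z_min - z, 0)^2
  e <- e + 0.5 * restraint$wall_k * pmax(b - restraint$b_max, 0)^2
  e
}

#' Place umbrella windows on an inclusive grid
#'
#' Builds the ordered list of harmonic biases for an umbrella-sampling run.
#' The default grid is the study design used for the CcmK2 pore: 105
#' windows from -26 to +26 A at 0.5 A spacing with k = 5 kcal mol^-1 A^-2.
#'
#' @param z_min,z_max grid endpoints, A (inclusive).
#' @param step window spacing, A; `(z_max - z_min) / step` must be an
#'   integer to within 1e-9.
#' @param k force constant shared by all windows.
#' @return list of [harmonic_bias()] objects with strictly increasing
#'   centers.
#' @examples
#' length(place_windows())  # 105
#' @export
place_windows <- function(z_min = -26, z_max = 26, step = 0.5, k = 5.0) {
  stopifnot(step > 0, z_max >= z_min)
  n_span <- (z_max - z_min) / step
  if (abs(n_span - round(n_span)) > 1e-9) {
    stop("window range is not commensurate with the step size",
         call. = FALSE)
  }
  centers <- z_min + step * seq(0, round(n_span))
  lapply(centers, harmonic_bias, k = k)
}

#' Window centers of a bias list
#' @param windows list of [harmonic_bias()].
#' @return numeric vector of centers, A.
#' @export
window_centers <- function(windows) {
  vapply(windows, function(w) w$z0, numeric(1))
}

#' Serialize a PMF model or window grid to YAML
#'
#' @param x a `pmf_model` or list of `harmonic_bias`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_pmf_yaml <- function(x, path) {
  if (inherits(x, "pmf_model")) {
    obj <- list(type = "pmf_model", name = x$name, heights = x$heights,
                centers = x$centers, widths = x$widths,
                radial_k = x$radial_k)
  } else {
    obj <- list(type = "window_grid",
                z0 = window_centers(x),
                k = vapply(x, function(w) w$k, numeric(1)))
  }
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a PMF model or window grid from YAML
#' @param path file written by [write_pmf_yaml()].
#' @return a `pmf_model` or list of `harmonic_bias`.
#' @export
read_pmf_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  if (identical(obj$type, "pmf_model")) {
    pmf_model(obj$name, heights = unlist(obj$heights),
              centers = unlist(obj$centers), widths = unlist(obj$widths),
              radial_k = obj$radial_k %||% 0)
  } else if (identical(obj$type, "window_grid")) {
    mapply(harmonic_bias, z0 = unlist(obj$z0), k = unlist(obj$k),
           SIMPLIFY = FALSE)
  } else {
    stop("unrecognized YAML object type: ", obj$type, call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
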