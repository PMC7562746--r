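#' Two-sided Wilcoxon rank-sum test
#'
#' Rank-sum statistic with midranks for ties. In `"exact"` mode the
#' two-sided p-value is computed by full enumeration of the
#' `choose(n_x + n_y, n_x)` group assignments (feasible for small
#' samples; handles ties exactly via midranks). In `"normal"` mode the
#' tie-corrected normal approximation with continuity correction is used
#' (delegated to [stats::wilcox.test()]). `"auto"` picks exact enumeration
#' when `n_x + n_y <= 12` and there are no ties, else the approximation.
#'
#' @param x,y numeric samples (both nonempty).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return list with `statistic` (rank sum of `x`, midranks), `p.value`
#'   (two-sided) and `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  ties <- anyDuplicated(c(x, y)) > 0
  if (mode == "auto") {
    mode <- if (nx + ny <= 12 && !ties) "exact" else "normal"
  }
  if (mode == "exact") {
    if (nx + ny > 20) {
      stop("exact enumeration limited to n_x + n_y <= 20", call. = FALSE)
    }
    combos <- utils::combn(nx + ny, nx)
    Ws <- colSums(matrix(r[combos], nrow = nx))
    mu <- nx * (nx + ny + 1) / 2
    p <- mean(abs(Ws - mu) >= abs(W - mu) - 1e-9)
    list(statistic = W, p.value = p, method = "exact enumeration")
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    p <- wt$p.value
    if (is.nan(p)) p <- 1       # zero-variance rank configuration
    list(statistic = W, p.value = p,
         method = "normal approximation (tie-corrected, continuity)")
  }
}

#' Contact-conditioned pore-diameter comparison
#'
#' The statistical step of the pore-dilation analysis: per-frame minimum
#' constriction diameters are split into "contact" and "no contact"
#' categories by the contact table of each residue, and the two categories
#' are compared with a two-sided Wilcoxon rank-sum test. Pairs in which one
#' category is empty (e.g. a metabolite that never touches a residue) are
#' flagged `insufficient` and get no p-value.
#'
#' @param diameters data.frame with columns `frame` and `diameter` (A),
#'   e.g. from [constriction_series()] (rename `frame`) or generator truth.
#' @param contacts data.frame with columns `frame`, `residue`, `contact`
#'   (logical), e.g. from [contact_series()] or generator truth.
#' @param metabolite label recorded in the output (default "metabolite").
#' @param alpha significance level used for the `significant` flag
#'   (default 0.01).
#' @param mode p-value mode passed to [wilcoxon_rank_sum()].
#' @return data.frame with one row per residue: `metabolite`, `residue`,
#'   `n_contact`, `n_nocontact`, `median_contact`, `median_nocontact`,
#'   `p`, `significant`, `insufficient`.
#' @export
compare_conditioned <- function(diameters, contacts,
                                metabolite = "metabolite", alpha = 0.01,
                                mode = "auto") {
  stopifnot(all(c("frame", "diameter") %in% names(diameters)),
            all(c("frame", "residue", "contact") %in% names(contacts)))
  if (!all(contacts$frame %in% diameters$frame)) {
    stop("contact table refers to frames absent from the diameter series",
         call. = FALSE)
  }
  rows <- lapply(split(contacts, contacts$residue), function(ct) {
    d <- diameters$diameter[match(ct$frame, diameters$frame)]
    dc <- d[ct$contact]
    dn <- d[!ct$contact]
    insufficient <- length(dc) == 0 || length(dn) == 0
    p <- NA_real_
    if (!insufficient) p <- wilcoxon_rank_sum(dc, dn, mode = mode)$p.value
    data.frame(metabolite = metabolite, residue = ct$residue[1],
               n_contact = length(dc), n_nocontact = length(dn),
               median_contact = if (length(dc)) stats::median(dc) else NA_real_,
               median_nocontact = if (length(dn)) stats::median(dn) else NA_real_,
               p = p,
               significant = !insufficient && p < alpha,
               insufficient = insufficient,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Violin-plot summary statistics
#'
#' Numeric backbone of a violin plot: median, quartiles and a Gaussian
#' kernel density (Silverman's rule-of-thumb bandwidth) on a regular grid,
#' normalized to integrate to 1.
#'
#' @param values numeric vector (>= 5 values).
#' @param n_grid grid size for the density curve (default 512).
#' @return list with `median`, `q1`, `q3`, `grid`, `density` and
#'   `degenerate` (TRUE for (near-)constant input, where no density curve
#'   is defined and a spike is flagged instead).
#' @export
violin_summary <- function(values, n_grid = 512) {
  values <- as.numeric(values)
  if (length(values) < 5) stop("need at least 5 values", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
  if (stats::sd(values) < 1e-12) {
    return(list(median = q[2], q1 = q[1], q3 = q[3], grid = values[1],
                density = Inf, degenerate = TRUE))
  }
  d <- stats::density(values, bw = "nrd0", n = n_grid)
  area <- sum(d$y) * diff(d$x[1:2])
  list(median = q[2], q1 = q[1], q3 = q[3], grid = d$x,
       density = d$y / area, degenerate = FALSE)
}

#' Arrhenius/Kramers rate ratio from barrier heights
#'
#' Ratio of transition rates over two activation free energies assuming a
#' shared (constant) pre-exponential factor:
#' `ratio = exp(-(dG_a - dG_b) / (kB T))`. Setting `dG_b = 0` reproduces
#' the comparison of a barrier-crossing species against a barrierless
#' reference (e.g. O2 or CO2 against bicarbonate).
#'
#' @param dG_a,dG_b activation free energies, kcal/mol.
#' @param T temperature, K (default 303.15).
#' @param labels optional character pair naming numerator and denominator.
#' @return object of class `rate_ratio_result`: list with `numerator`,
#'   `denominator`, `ddG` (kcal/mol), `T` and `ratio`.
#' @export
rate_ratio <- function(dG_a, dG_b = 0, T = 303.15,
                       labels = c("a", "b")) {
  ddG <- dG_a - dG_b
  structure(list(numerator = labels[1], denominator = labels[2],
                 ddG = ddG, T = T,
                 ratio = exp(-ddG / thermal_energy(T))),
            class = "rate_ratio_result")
}

#' @export
print.rate_ratio_result <- function(x, ...) {
  cat(sprintf("<rate_ratio> k_%s / k_%s = %.4g  (ddG = %.3f kcal/mol, T = %.2f K)\n",
              x$numerator, x$denominator, x$ratio, x$ddG, x$T))
  invisible(x)
}
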