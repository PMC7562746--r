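---
title: "Methods: free-energy, geometry and statistics of shell-protein pore permeability"
author: "poreperm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: free-energy, geometry and statistics of shell-protein pore permeability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poreperm)
```

## Scope and model

Bacterial microcompartment (BMC) shells are built from hexameric proteins
such as the carboxysome protein CcmK2, whose central pore at the six-fold
axis is the presumed route for metabolites (HCO3-, 3-PGA, O2, CO2) and
ions. `poreperm` packages the computational analyses used to characterize
such selective permeability:

1. **Free-energy reconstruction** along the pore axis from umbrella-sampling
   (US) windows — WHAM in 1D, WHAM on the (z, b) plane in 2D, and a
   Markov-model route (DHAM) — with block-splitting error bars,
   autocorrelation diagnostics, and extremum/barrier readout.
2. **Pore geometry** — PDB reading, Kabsch superposition, RMSD/RMSF,
   inscribed-sphere constriction profiles, pore-entrance hexagon areas,
   and distance/angle contact detection.
3. **Statistics and kinetics** — Wilcoxon rank-sum comparison of
   contact-conditioned pore diameters, violin summaries, and
   constant-prefactor Arrhenius/Kramers rate ratios.
4. A **synthetic data generator** that produces every input with known
   ground truth, so the whole pipeline is testable without any molecular
   dynamics engine or structure downloads.

Energies are kcal/mol, lengths Å, times ps throughout;
`kB = 1.987204e-3` kcal/mol/K and the default temperature is 303.15 K
(`thermal_energy(303.15)` ≈ 0.6025 kcal/mol).

## The reaction coordinates and the umbrella design

The axial coordinate `z` is the projection of the permeant's center of
mass on the pore axis, with the origin at the hexamer's center of mass and
positive `z` on the concave face; `b` is the distance from that axis. The
default window design is the study layout for the CcmK2 pore: 105 windows
on an inclusive grid from −26 to +26 Å at 0.5 Å spacing
(`place_windows()`), harmonic bias `0.5 k (z − z0)^2` with
`k = 5 kcal/mol/Å²`, and a flat-bottom cylinder (|z| ≤ 28 Å, b ≤ 15 Å,
wall stiffness 10 kcal/mol/Å²). The half-`k` prefactor is a convention
choice; simulator and estimators share it, which is all that correctness
requires. Ions are simulated without umbrella bias, restrained to the same
cylinder, and treated as independent trajectories.

## The synthetic generator: what it emulates and what it does not

There are no public trajectories for this system, so the generator stands
in for the MD engine. It propagates the collective variables directly by
overdamped Langevin (Euler–Maruyama) dynamics on an analytic ground-truth
potential of mean force:

```
x <- x + (D / kBT) * F(x) * dt + sqrt(2 D dt) * xi
```

with `D = 0.2 Å²/ps` and `dt = 0.05 ps` by default and `1e4` samples per
window — a reduced scale chosen so that a full 105-window dataset
simulates in well under a minute on one CPU while window autocorrelation
times (≈ 0.6 ps for the harmonic windows) stay far below the window
length, mirroring the property that matters for US convergence. `D` and
`dt` are generator-only knobs with no physical counterpart in the original
workflow.

The radial coordinate is a distance from an axis, not a Cartesian
coordinate: it receives the entropic Jacobian drift `(D / b) dt` (floored
at b = 0.05 Å in the denominator) and reflects at b = 0, so its unbiased
stationary density grows linearly in b up to the wall. Window `i`
(1-based) of a dataset is seeded `seed + i`, making datasets reproducible
from one master seed while windows remain individually regenerable. R's
RNG drives the compiled stepper, so `set.seed` gives bit-identical output
across platforms.

Ground-truth PMFs (`pmf_fixture()`) are sums of Gaussians in `z` (widths
≤ 2.5 Å, centers within ±13 Å, so every fixture is < 1e-3 kcal/mol at
|z| = 25 — anchored to bulk by construction) plus an optional radial
harmonic. `three_well` echoes the qualitative landscape of a metabolite
crossing the pore — minima near the arginine (z ≈ −12) and lysine
(z ≈ +6) rings around a serine-region barrier (z ≈ −5) — without claiming
to equal any published profile. Barrier fixtures of 1, 3.5, 3.8 and
7.6 kcal/mol cover the magnitudes relevant for O2/CO2 barriers and the
K+ maximum.

What the generator does **not** emulate: explicit water and ions, force
fields, pressure/temperature coupling, SHAKE, PME, or steered-MD seeding
of windows (windows start at their bias centers analytically). Passing
tests therefore demonstrate correctness of the estimators and analysis
chain on data whose statistics match the collective-variable level of the
real problem — they say nothing about force-field accuracy or MD sampling
adequacy on a real shell protein.

The breathing-pore generator (`generate_pore_ensemble()`) emulates the
structure-side data: three stacked six-fold rings of pore-lining
pseudo-residues (Arg11, Ser39, Lys36; the Ser39 ring is the constriction,
1.5 Å narrower than its neighbors), a common per-frame ring radius drawn
from N(mean, sd), and a single-atom metabolite probe. In a chosen fraction
of frames the probe sits 3.0 Å from a designated residue atom and all ring
radii dilate by half the configured diameter shift — a planted,
recoverable contact-coupled pore opening. The default 2500 frames match
the number of equidistant trajectory frames analyzed in the reference
workflow; defaults `ring_radius_mean = 3 Å`, `breathing_sd = 0.5 Å`,
`atom_vdw = 1.52 Å` give constriction diameters fluctuating over roughly
1–6 Å. Frames carry no hydrogens, so contact detection on them exercises
the documented distance-only fallback.

## Free-energy estimators

**WHAM (1D).** `wham_1d()` iterates the standard self-consistent
equations on 0.5 Å histograms (the bin grid matches the window spacing;
the histogram binning itself is a package choice) until window free
energies move by less than `tol = 1e-7 kBT` (cap `1e5` iterations) —
tighter than the statistical error at any shipped scale. Profiles are
anchored so that the mean free energy over bulk bins, |z| between 24 and
25 Å, is zero; the bulk anchor is stated as z = ±25 Å in the reference
analysis without a width, and a 1 Å shoulder keeps the anchor insensitive
to single-bin noise. When no bulk bin is occupied (toy data) the anchor
falls back to the mean over occupied bins and says so in the profile's
`anchor` field. Unoccupied bins are NA, never ±Inf; window pairs without a
mutually occupied bin raise a gap error naming the gap.

**WHAM (2D).** Because the umbrella bias acts on z only, the window free
energies solve the same equations on the z-marginals; the 2D cell
probabilities then follow from the converged denominators. With
`jacobian_correct = TRUE` (default) the reported surface is
`−kBT log(p / b)`: the linear volume element of the distance-from-axis
coordinate is divided out, so a non-interacting particle shows a flat
surface in b. Whether the original 2D surfaces included this measure term
is not documented; both variants are exposed through the flag.

**DHAM.** `dham_1d()` counts per-window bin-to-bin transitions at a fixed
lag (default one sampling interval), combines them with symmetric
square-root bias factors `exp(−(w_j − w_i)/(2 kBT))` — the standard
Markov unbiasing construction — row-normalizes, and reads
`G = −kBT log π` off the stationary eigenvector. Unvisited bins are
removed from the chain and masked; a non-communicating visited set raises
a connectivity error rather than returning a meaningless eigenvector.

**Errors.** `split_block_errors()` divides each window into 5 contiguous
equal segments (the convergence diagnostic used in the reference
analysis), re-estimates each segment-dataset independently, and reports
the per-bin mean and standard error across blocks. `pooled_stderr()`
summarizes a profile's error as the root-mean-square of its per-bin
standard errors; estimator comparisons (WHAM vs DHAM, recovery vs truth)
are expressed in multiples of it.

**Unbiased densities.** `density_free_energy()` pools trajectories,
histograms z and returns `−kBT log(density)` — the free-ion route. The
density is normalized per pooled sample, so duplicating a trajectory
changes nothing.

**Autocorrelation.** `autocorrelation()` uses the mean-removed normalized
ACF and the initial-positive-sequence rule,
`tau = interval (1 + 2 Σ acf(k))` summed to the first negative ACF value,
floored at one sampling interval. The estimator choice is a package
decision (the reference analysis does not state its estimator); the AR(1)
closed form `(1 + φ)/(1 − φ)` validates it in tests.

**Feature readout.** `profile_features()` locates interior extrema after
optional 3-bin smoothing and reports each maximum both relative to bulk
and as a barrier over the lower adjacent minimum. `min_prominence` prunes
noise wiggles pairwise; the pipeline default of 0.5 kcal/mol is roughly
2× the pooled block error at default sampling.

## Pore geometry

**Constriction profiling.** At each z-slice, `pore_profile()` maximizes
the inscribed-sphere radius `min_i(|p_i − c| − vdw_i)` over sphere centers
`c = (x, y, z0)`, using atoms within a ±6 Å slab, a dense 0.25 Å coarse
scan of a 3 Å-radius disc around the axis followed by Nelder–Mead
refinement from the best mutually separated cells, a 10 Å escape cap, and
a soft wall that confines the center to the disc (otherwise the optimum
slips around the outside of a thin ring model — real channel profilers
constrain the center track the same way). The original tool's simulated
annealing is replaced by this deterministic multi-start search; accuracy
is defined against a brute-force 0.02 Å grid oracle (agreement within
0.05 Å on randomized ring fixtures, typically < 0.02 Å).
`min_constriction()` reports the narrowest slice as a diameter, ties
broken toward z = 0. Van der Waals radii come from a fixed element table
(C 1.70, N 1.55, O 1.52, S 1.80, H 1.20, P 1.80 Å); published constriction
values depend on the radius set of the tool that produced them, so
cross-tool comparisons should state it.

**Superposition and flexibility.** `superpose()` is the closed-form
Kabsch fit with the determinant correction; `rmsf()` computes per-atom
fluctuations about the time-averaged structure on a pre-superposed
trajectory, aggregates per residue, supports discarding a leading
equilibration fraction (e.g. 0.25 to analyze the last three quarters of a
run), and reports per chain or pooled across chains.

**Hexagon area.** The pore-entrance surface spanned by the six Ser39
alpha carbons is summarized by fitting the least-squares plane, ordering
vertices by polar angle, and summing fan-triangle areas — for a convex
hexagon every triangulation (Delaunay included) gives the same area.

**Contacts.** `detect_contacts()` scores donor/acceptor heavy-atom pairs
(N/O) within 3.5 Å; when the frame contains hydrogens, a
donor–hydrogen–acceptor deviation from linearity ≤ 30° is also required
(hydrogens are assigned to the donor within 1.25 Å; either partner may
donate). Heavy-atom-only frames — e.g. O2/CO2 probes, for which a
conventional donor does not exist — are scored on distance alone and
flagged `distance_only`; how the original analysis handled the angle for
those species is not documented, so the fallback is explicit rather than
silent.

## Statistics and kinetics

`wilcoxon_rank_sum()` reports the midrank rank-sum statistic with
two-sided p-values: exact by full enumeration when `n_x + n_y ≤ 12`
without ties (`auto`), else the tie-corrected normal approximation with
continuity correction. Two-sidedness and the tie policy are package
decisions — the reference analysis names the test but not its options —
justified by the non-directional comparison of diameter distributions. No
multiple-testing correction is applied by default (raw p-values per
residue/metabolite pair are reported, as in the reference); apply
`p.adjust` downstream if desired. `compare_conditioned()` splits
per-frame constriction diameters by each residue's contact indicator and
flags pairs with an empty category as `insufficient` instead of testing
them — small metabolites rarely touch the pore residues, and those rows
carry no p-value.

`rate_ratio()` evaluates `exp(−ΔΔG‡ / kBT)`, the rate ratio under a
constant Arrhenius/Kramers prefactor. Barrier inputs come from
`profile_features()` rather than being recomputed internally, because a
barrier is only defined relative to a stated reference (bulk or a
preceding minimum) and that choice belongs to the caller. No prefactor
estimation from diffusion profiles is attempted.

## Numerical choices and degenerate inputs

* Euler–Maruyama has O(dt) discretization bias: a harmonic window at the
  defaults carries ≈ 4% excess variance (`θ dt / 2` with
  `θ = D k / kBT`). This is far below block errors at default scale;
  stationarity tests that resolve 1e5 samples use `dt = 0.01` where the
  residual bias is below the χ² resolution.
* A single-step displacement > 5 Å aborts with advice to reduce `dt`.
* WHAM's gauge freedom is fixed by zero-mean window free energies during
  iteration and bulk anchoring afterwards; anchored bins average to zero
  within 1e-6 by construction.
* Constant series have no autocorrelation time (error); a near-degenerate
  spike series returns the floor `tau = interval`.
* `violin_summary()` flags (near-)constant input as a degenerate spike
  instead of inventing a bandwidth.
* Collinear point sets are rejected by both `superpose()` and
  `hexagon_area()`.

## Problem sizes used by the shipped tests

The test-suite and the acceptance script run the full 105-window design
at 1e4 samples per window (the generator default; four barrier fixtures),
2500-frame pore ensembles with full contact detection and per-frame
constriction measurement, and a 100-replicate null calibration of the
conditioned comparison at 2500 frames per replicate. These sizes were
chosen so the complete pipeline stays within a desktop-minutes budget
while leaving planted effects 3σ-recoverable; they are package defaults,
not physical claims.

## Known limitations

* The generator's PMFs are analytic stand-ins; no electrostatics, no
  force field, no explicit solvent. Quantitative published free-energy
  values for real metabolites are not reproduction targets at this scale.
* 2D estimation is WHAM-based; a 2D transition-matrix (DHAM) model is out
  of scope.
* The radial Jacobian drift floor (0.05 Å) slightly distorts the radial
  density within one step-length of the axis.
* `read_pdb()` handles ATOM/HETATM, MODEL/ENDMDL and altloc blank/'A'
  (via bio3d); exotic PDB features (insertion codes in selections,
  SEGID-based chains) are untested territory.
* Published constriction diameters depend on the producing tool's radius
  set; agreement closer than ~0.2 Å should not be over-interpreted.
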