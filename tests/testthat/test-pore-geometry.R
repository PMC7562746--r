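make_pdb_text <- function() {
  c("MODEL        1",
    "ATOM      1  N   LYS A  36       5.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  LYS A  36       4.000   1.000   0.500  1.00  0.00           C",
    "ATOM      3  OG ASER A  39       2.000   2.000   0.000  1.00  0.00           O",
    "ATOM      4  OG BSER A  39       2.100   2.000   0.000  1.00  0.00           O",
    "ATOM      5  CA  SER A  39       1.500   2.500   0.250  1.00  0.00           C",
    "ATOM      6  S   CYS B  10      -1.000  -2.000   1.000  1.00  0.00           S",
    "ENDMDL")
}

test_that("PDB reading honors models, altloc policy and the vdW table", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(make_pdb_text(), path)
  fr <- read_pdb(path)
  expect_length(fr, 1)
  a <- fr[[1]]$atoms
  expect_equal(nrow(a), 5)                  # altloc B dropped
  expect_false(any(a$eleno == 4))
  expect_equal(a$x[a$eleno == 1], 5.0)
  expect_equal(a$vdw[a$eleno == 1], 1.55)   # N
  expect_equal(a$vdw[a$eleno == 2], 1.70)   # C
  expect_equal(a$vdw[a$eleno == 6], 1.80)   # S

  # three models -> three frames
  writeLines(rep(make_pdb_text(), 3), path)
  expect_length(read_pdb(path), 3)
})

test_that("multi-model PDB writing round-trips through the reader", {
  en <- generate_pore_ensemble(pore_ensemble_spec(n_frames = 3, seed = 9))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_frames_pdb(en$frames, path)
  back <- read_pdb(path)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_equal(frame_coords(back[[i]]), frame_coords(en$frames[[i]]),
                 tolerance = 1e-3, ignore_attr = TRUE)
    expect_equal(back[[i]]$atoms$resno, en$frames[[i]]$atoms$resno)
  }
})

test_that("Kabsch superposition recovers rigid transforms", {
  en <- generate_pore_ensemble(pore_ensemble_spec(n_frames = 1, seed = 10))
  f <- en$frames[[1]]
  expect_lt(superpose(f, f, elety = NULL)$rmsd, 1e-12)

  set.seed(11)
  th <- runif(3, 0, 2 * pi)
  Rz <- matrix(c(cos(th[1]), -sin(th[1]), 0, sin(th[1]), cos(th[1]), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[2]), -sin(th[2]),
                 0, sin(th[2]), cos(th[2])), 3, 3, byrow = TRUE)
  R <- Rz %*% Rx
  g <- f
  xyz <- sweep(frame_coords(f) %*% t(R), 2, c(3, -1, 2), "+")
  g$atoms[, c("x", "y", "z")] <- xyz
  s <- superpose(g, f, elety = NULL)
  expect_lt(s$rmsd, 1e-6)
  expect_equal(frame_coords(s$transformed), frame_coords(f),
               tolerance = 1e-6, ignore_attr = TRUE)

  # rmsd invariant when the same rigid motion hits both structures
  h <- f
  h$atoms$x <- h$atoms$x + rnorm(nrow(h$atoms), 0, 0.3)
  r0 <- superpose(h, f, elety = NULL)$rmsd
  move <- function(fr) {
    fr$atoms[, c("x", "y", "z")] <-
      sweep(frame_coords(fr) %*% t(R), 2, c(-2, 5, 1), "+")
    fr
  }
  r1 <- superpose(move(h), move(f), elety = NULL)$rmsd
  expect_lt(abs(r1 - r0), 1e-9)
})

test_that("superposition RMSD matches the bio3d reference fit", {
  set.seed(12)
  P <- matrix(rnorm(30), 10, 3)
  Q <- P + matrix(rnorm(30, 0, 0.4), 10, 3)
  mk <- function(m) structure_frame(data.frame(
    eleno = 1:10, elety = "CA", resid = "GLY", resno = 1:10, chain = "A",
    x = m[, 1], y = m[, 2], z = m[, 3], vdw = 1.7, elesy = "C"))
  ours <- superpose(mk(P), mk(Q))$rmsd
  ref <- bio3d::rmsd(as.vector(t(Q)), as.vector(t(P)), fit = TRUE)
  expect_equal(ours, ref, tolerance = 2e-3)   # reference rounds to 1e-3
})

test_that("superposition rejects mismatched or degenerate selections", {
  mk <- function(n) structure_frame(data.frame(
    eleno = 1:n, elety = "CA", resid = "GLY", resno = 1:n, chain = "A",
    x = seq_len(n), y = 0, z = 0, vdw = 1.7, elesy = "C"))
  expect_error(superpose(mk(4), mk(5)), "mismatch")
  expect_error(superpose(mk(5), mk(5)), "collinear|degenerate")
})

test_that("RMSF reflects per-atom fluctuation about the mean", {
  base <- structure_frame(data.frame(
    eleno = 1:4, elety = "CA", resid = "GLY", resno = 1:4, chain = "A",
    x = c(0, 3, 6, 9), y = c(0, 1, 0, 1), z = c(0, 0, 1, 1),
    vdw = 1.7, elesy = "C"))
  frames <- rep(list(base), 10)
  r0 <- rmsf(frames)
  expect_true(all(r0$rmsf == 0))

  # one atom oscillating +/-1 A along x about its mean
  frames2 <- lapply(1:10, function(i) {
    f <- base
    f$atoms$x[2] <- 3 + if (i %% 2 == 0) 1 else -1
    f
  })
  r2 <- rmsf(frames2)
  expect_equal(r2$rmsf[r2$resno == 2], 1.0)
  expect_equal(r2$rmsf[r2$resno == 1], 0.0)

  # isotropic Gaussian noise: RMSF ~ sigma * sqrt(3)
  set.seed(13)
  sig <- 0.25
  frames3 <- lapply(1:600, function(i) {
    f <- base
    f$atoms[, c("x", "y", "z")] <- frame_coords(f) +
      matrix(rnorm(12, 0, sig), 4, 3)
    f
  })
  r3 <- rmsf(frames3)
  expect_lt(max(abs(r3$rmsf - sig * sqrt(3)) / (sig * sqrt(3))), 0.1)

  # discard_fraction drops the leading frames
  frames4 <- c(lapply(1:5, function(i) {
    f <- base; f$atoms$x <- f$atoms$x + 50; f
  }), rep(list(base), 15))
  r4 <- rmsf(frames4, discard_fraction = 0.25)
  expect_true(all(r4$rmsf == 0))
  expect_error(rmsf(frames[1:2], elety = "ZZ"), "empty")
})

test_that("pore profiles match ring geometry and a brute-force oracle", {
  sp <- pore_ensemble_spec(n_frames = 1, ring_radius_mean = 5,
                           breathing_sd = 0, atom_vdw = 1.7, seed = 14)
  f <- generate_pore_ensemble(sp)$frames[[1]]
  ring <- select_atoms(f, resno = 39)
  pp <- pore_profile(f, z_range = c(0, 0), atoms_idx = ring)
  expect_equal(pp$radius, 3.3, tolerance = 1e-6)

  # one atom moved inward: off-axis center, agrees with dense grid search
  g <- f
  k <- ring[1]
  g$atoms$x[k] <- 4; g$atoms$y[k] <- 0
  pg <- pore_profile(g, z_range = c(0, 0), atoms_idx = ring)
  expect_gt(pg$radius, 2.3)
  expect_gt(abs(pg$cx) + abs(pg$cy), 0.05)
  oracle <- oracle_pore_radius(g, 0, atoms_idx = ring)
  expect_lt(abs(pg$radius - oracle), 0.05)

  # stacked rings: constriction sits at the narrow ring
  sp2 <- pore_ensemble_spec(n_frames = 1, ring_radius_mean = 3,
                            breathing_sd = 0, seed = 15)
  f2 <- generate_pore_ensemble(sp2)$frames[[1]]
  prot <- select_atoms(f2, resid = c("ARG", "SER", "LYS"))
  mc <- min_constriction(pore_profile(f2, z_range = c(-4, 4),
                                      atoms_idx = prot))
  expect_equal(mc$z, 0)          # the Ser ring is 1.5 A narrower
  expect_equal(mc$diameter, 2 * (3 - 1.52), tolerance = 1e-3)
})

test_that("minimum constriction breaks ties toward z = 0", {
  pp <- structure(data.frame(z = c(-2, -1, 0.5, 1), radius = 2,
                             cx = 0, cy = 0),
                  class = c("pore_profile", "data.frame"))
  mc <- min_constriction(pp)
  expect_equal(mc$z, 0.5)
  expect_equal(mc$diameter, 4)
  bad <- structure(data.frame(z = 1, radius = NA_real_, cx = NA, cy = NA),
                   class = c("pore_profile", "data.frame"))
  expect_error(min_constriction(bad), "no defined")
})

test_that("per-frame constriction diameters track the planted truth", {
  en <- generate_pore_ensemble(pore_ensemble_spec(
    n_frames = 40, contact_dilation = 1, contact_fraction = 0.5,
    seed = 16))
  prot <- select_atoms(en$frames[[1]], resid = c("ARG", "SER", "LYS"))
  cs <- constriction_series(en$frames, z_range = c(-2, 2),
                            atoms_idx = prot)
  expect_lt(max(abs(cs$diameter - en$diameters$diameter)), 0.05)
  expect_gt(cor(cs$diameter, en$diameters$diameter), 0.99)
})

test_that("hexagon area matches closed forms and is invariant to isometry", {
  hexa <- function(a) cbind(a * cos(0:5 * pi / 3), a * sin(0:5 * pi / 3), 0)
  expect_equal(hexagon_area(hexa(1)), 3 * sqrt(3) / 2, tolerance = 1e-9)
  expect_equal(hexagon_area(hexa(2)), 10.392, tolerance = 1e-3)

  set.seed(17)
  pts <- hexa(1.7) + matrix(rnorm(18, 0, 0.05), 6, 3)
  a0 <- hexagon_area(pts)
  expect_equal(hexagon_area(pts[sample(6), ]), a0, tolerance = 1e-9)
  th <- pi / 6
  Rx <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)),
               3, 3, byrow = TRUE)
  expect_equal(hexagon_area(sweep(pts %*% t(Rx), 2, c(5, -2, 1), "+")),
               a0, tolerance = 1e-9)

  expect_error(hexagon_area(pts[1:5, ]), "6 points")
  line <- cbind(1:6, 2 * (1:6), 0)
  expect_error(hexagon_area(line), "collinear")
})

test_that("contact detection applies the distance and angle criteria", {
  mk_frame <- function(acc_x, h_pos = c(1, 0, 0)) {
    structure_frame(data.frame(
      eleno = 1:3, elety = c("NZ", "HZ1", "O1"),
      resid = c("LYS", "LYS", "BCT"), resno = c(36, 36, 1),
      chain = c("A", "A", "X"),
      x = c(0, h_pos[1], acc_x), y = c(0, h_pos[2], 0),
      z = c(0, h_pos[3], 0),
      vdw = c(1.55, 1.2, 1.52), elesy = c("N", "H", "O")))
  }
  res <- list(LYS = list(resid = "LYS", resno = 36))
  met <- list(resid = "BCT")
  # far apart: no contact
  expect_false(detect_contacts(mk_frame(10), met, res)$contact)
  # 2.8 A, deviation ~0 degrees: contact
  ct <- detect_contacts(mk_frame(2.8), met, res)
  expect_true(ct$contact)
  expect_false(ct$distance_only)
  # 3.0 A but hydrogen off-axis by ~60 degrees: no contact
  h_off <- c(cos(pi / 3), sin(pi / 3), 0)
  expect_false(detect_contacts(mk_frame(3.0, h_off), met, res)$contact)
  # heavy-atom-only frame: distance decides, flagged
  f_noh <- mk_frame(3.0)
  f_noh$atoms <- f_noh$atoms[-2, ]
  ct2 <- detect_contacts(f_noh, met, res)
  expect_true(ct2$contact)
  expect_true(ct2$distance_only)
})

test_that("contact counts respect six-fold symmetry per chain", {
  en <- generate_pore_ensemble(pore_ensemble_spec(
    n_frames = 1, breathing_sd = 0, contact_fraction = 0, seed = 18))
  f <- en$frames[[1]]
  # metabolite on the axis: all six chains equivalent
  ct <- detect_contacts(f, list(resid = "BCT"), hexamer_residues(),
                        per_chain = TRUE)
  for (r in unique(ct$residue)) {
    expect_equal(length(unique(ct$n_contacts[ct$residue == r])), 1)
  }
})
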