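# Geometry primitives: superposition, RMSD/RMSF, dihedrals, distances,
# axial rotation.

rot_z <- function(deg) {
  th <- deg * pi / 180
  rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
}

test_that("kabsch_superpose recovers exact rigid motions", {
  set.seed(11)
  A <- matrix(rnorm(18), 6, 3)
  tf <- kabsch_superpose(A, A)
  expect_equal(tf$rmsd, 0, tolerance = 1e-12)
  expect_equal(tf$rotation, diag(3), tolerance = 1e-9)

  B <- A %*% t(rot_z(90)) + matrix(rep(c(1, 2, 3), each = 6), 6, 3)
  tf <- kabsch_superpose(A, B)
  expect_equal(tf$rmsd, 0, tolerance = 1e-10)
  expect_equal(apply_transform(A, tf), B, tolerance = 1e-9)
  expect_equal(det(tf$rotation), 1, tolerance = 1e-9)

  expect_error(kabsch_superpose(A[1:2, ], A[1:2, ]),
               class = "degenerate_geometry_error")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabsch_superpose(line, line),
               class = "degenerate_geometry_error")
})

test_that("kabsch rmsd matches the quaternion-search oracle", {
  set.seed(21)
  for (rep in 1:20) {
    A <- matrix(rnorm(18), 6, 3)
    B <- matrix(rnorm(18), 6, 3)
    expect_equal(kabsch_superpose(A, B)$rmsd, quat_rmsd_oracle(A, B),
                 tolerance = 1e-4)
  }
})

test_that("kabsch rmsd is invariant under common rigid transforms", {
  set.seed(31)
  for (rep in 1:10) {
    A <- matrix(rnorm(24), 8, 3)
    B <- A + matrix(rnorm(24, sd = 0.1), 8, 3)
    base <- kabsch_superpose(A, B)$rmsd
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); th <- runif(1, 0, 2 * pi)
    K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    shift <- matrix(rnorm(3), 8, 3, byrow = TRUE)
    moved <- kabsch_superpose(A %*% t(R) + shift, B %*% t(R) + shift)$rmsd
    expect_equal(moved, base, tolerance = 1e-9)
  }
})

test_that("rmsd_series captures rigid-body displacement of the analysed group", {
  atoms <- make_atoms(paste0("C", 1:8), "GLY", 1:8, element = "C")
  base <- cbind(seq(0, 2.1, length.out = 8), (1:8) %% 3, rep(c(0, 1), 4))
  # identical frames -> zeros; whole-frame translation -> still zeros
  tr <- make_traj(atoms, list(base, base + 5, base))
  rs <- rmsd_series(tr, 1:8, 1:8, reference = 1L)
  expect_equal(rs$values, c(0, 0, 0), tolerance = 1e-9)

  # displacing one of 4 analysed atoms by d with the align group fixed:
  # RMSD = d / sqrt(4)
  d <- 0.3
  moved <- base
  moved[1, ] <- moved[1, ] + c(d, 0, 0)
  tr2 <- make_traj(atoms, list(base, moved))
  rs2 <- rmsd_series(tr2, analyze_sel = 1:4, align_sel = 5:8, reference = 1L)
  expect_equal(rs2$values[2], d / 2, tolerance = 1e-9)
  expect_equal(rs2$values[1], 0, tolerance = 1e-12)
  expect_error(rmsd_series(tr2, "resid 99", 1:4), class = "selection_error")
})

test_that("rmsd_series values are invariant to global rigid motion", {
  g <- gen_ion_site(site_preset("MG"), frames = 20, seed = 3)
  tr <- g$trajectory
  base <- rmsd_series(tr, "element O", "element C", reference = 1L)
  moved <- tr
  for (k in seq_len(iontraj:::n_frames(tr))) {
    R <- rot_z(k * 17)
    moved$coords[, , k] <- tr$coords[, , k] %*% t(R) +
      matrix(rep(c(k, -k, 0.5), each = dim(tr$coords)[1]), ncol = 3)
  }
  rs <- rmsd_series(moved, "element O", "element C", reference = 1L)
  expect_equal(rs$values, base$values, tolerance = 1e-9)
})

test_that("rmsf recovers the closed form for isotropic Gaussian jitter", {
  set.seed(41)
  sigma <- 0.02
  n <- 20000
  atoms <- make_atoms(paste0("C", 1:7), "GLY", 1:7, element = "C")
  base <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 0), c(0, 1, 1), c(1, 0, 1))
  coords <- array(rep(base, n), c(7, 3, n))
  coords[5:7, , ] <- coords[5:7, , ] + array(rnorm(9 * n, 0, sigma), c(3, 3, n))
  tr <- trajectory(topology(atoms), coords, (seq_len(n) - 1) * 0.01)
  r <- rmsf(tr, 1:7, 1:4)  # align on the static scaffold
  expect_equal(unname(r[1:4]), rep(0, 4), tolerance = 1e-12)
  expect_true(all(abs(unname(r[5:7]) / (sigma * sqrt(3)) - 1) < 0.02))
  expect_error(rmsf(make_traj(atoms, list(base)), 1:7),
               class = "insufficient_data_error")
})

test_that("rmsf recovers the Mg-site preset fluctuation (0.04 nm target)", {
  g <- gen_ion_site(site_preset("MG"), frames = 20000, seed = 2)
  r <- rmsf(g$trajectory, g$manifest$ion_index, g$manifest$align_selection)
  expect_equal(unname(r), g$manifest$expected_rmsf, tolerance = 0.1)
})

test_that("dihedral_angle follows the IUPAC convention", {
  p1 <- c(-1, 1, 0); p2 <- c(0, 0, 0); p3 <- c(1, 0, 0)
  expect_equal(dihedral_angle(p1, p2, p3, c(2, 1, 0)), 0)
  expect_equal(dihedral_angle(p1, p2, p3, c(2, -1, 0)), 180)
  # constructive: rotate p4 from cis by +150 about the p2->p3 (x) axis
  rot_about_x <- function(p, deg) {
    th <- deg * pi / 180
    c(p[1], cos(th) * p[2] - sin(th) * p[3], sin(th) * p[2] + cos(th) * p[3])
  }
  expect_equal(dihedral_angle(p1, p2, p3, rot_about_x(c(2, 1, 0), 150)), 150,
               tolerance = 1e-6)
  expect_equal(dihedral_angle(p1, p2, p3, rot_about_x(c(2, 1, 0), -60)), -60,
               tolerance = 1e-6)
  expect_error(dihedral_angle(p1, p2, p2, c(2, 1, 0)),
               class = "degenerate_geometry_error")
})

test_that("dihedral_angle negates under reversal and mirroring", {
  set.seed(51)
  for (rep in 1:25) {
    p <- lapply(1:4, function(i) rnorm(3))
    a <- dihedral_angle(p[[1]], p[[2]], p[[3]], p[[4]])
    b <- dihedral_angle(p[[4]], p[[3]], p[[2]], p[[1]])
    expect_equal(a, b, tolerance = 1e-9)  # reversal preserves the torsion
    m <- lapply(p, function(v) v * c(1, 1, -1))  # mirror negates it
    expect_equal(dihedral_angle(m[[1]], m[[2]], m[[3]], m[[4]]),
                 -a, tolerance = 1e-9)
  }
})

test_that("pair_distance_series statistics match closed forms", {
  atoms <- make_atoms(c("CA", "CB"), "GLY", c(1L, 2L), element = "C")
  tr <- make_traj(atoms, list(rbind(c(0, 0, 0), c(0.2, 0, 0)),
                              rbind(c(0, 0, 0), c(0.2, 0, 0))))
  ds <- pair_distance_series(tr, 1, 2)
  expect_equal(ds$mean, 0.2)
  expect_equal(ds$sd, 0)

  # oscillation on a line: d(t) = 0.65 + 0.05 sin(t); sd -> 0.05/sqrt(2)
  n <- 4000
  phase <- 2 * pi * (seq_len(n) - 1) / n  # whole periods
  frames <- lapply(phase, function(ph)
    rbind(c(0, 0, 0), c(0.65 + 0.05 * sin(ph), 0, 0)))
  ds2 <- pair_distance_series(make_traj(atoms, frames), 1, 2)
  expect_equal(ds2$mean, 0.65, tolerance = 0.01 * 0.65)
  expect_equal(ds2$sd, 0.05 / sqrt(2), tolerance = 0.01 * 0.05 / sqrt(2))
  expect_error(pair_distance_series(tr, "element C", 2),
               class = "cardinality_error")
})

test_that("axial_rotation_angle recovers exact and noisy rotations", {
  set.seed(61)
  ref <- matrix(rnorm(600), 200, 3)
  expect_equal(axial_rotation_angle(ref, ref), 0)
  expect_equal(axial_rotation_angle(ref, ref %*% t(rot_z(25))), 25,
               tolerance = 1e-6)
  noisy <- ref %*% t(rot_z(25)) + matrix(rnorm(600, 0, 0.05), 200, 3)
  expect_equal(axial_rotation_angle(ref, noisy), 25, tolerance = 1)
  onaxis <- cbind(0, 0, 1:5)
  expect_error(axial_rotation_angle(onaxis, onaxis),
               class = "degenerate_geometry_error")
})

test_that("axial rotations compose modulo 360 on noise-free data", {
  set.seed(71)
  ref <- matrix(rnorm(60), 20, 3)
  for (angles in list(c(10, 20), c(100, 150), c(-40, 70))) {
    f1 <- ref %*% t(rot_z(angles[1]))
    f2 <- f1 %*% t(rot_z(angles[2]))
    total <- axial_rotation_angle(ref, f2)
    expected <- ((sum(angles) + 180) %% 360) - 180
    if (expected == -180) expected <- 180
    expect_equal(total, expected, tolerance = 1e-6)
  }
})
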