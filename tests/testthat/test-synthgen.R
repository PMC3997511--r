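# Synthetic-trajectory generators: reproducibility, manifest fidelity and
# end-to-end recovery of the fixture bundles.

test_that("generators are reproducible under a fixed seed", {
  a <- gen_ion_site(site_preset("MG"), frames = 100, seed = 7)
  b <- gen_ion_site(site_preset("MG"), frames = 100, seed = 7)
  expect_identical(a$trajectory$coords, b$trajectory$coords)
  c <- gen_ion_site(site_preset("MG"), frames = 100, seed = 8)
  expect_false(identical(a$trajectory$coords, c$trajectory$coords))

  d1 <- gen_dihedral(dihedral_preset("E1_MG"), frames = 50, seed = 3)
  d2 <- gen_dihedral(dihedral_preset("E1_MG"), frames = 50, seed = 3)
  expect_identical(d1$trajectory$coords, d2$trajectory$coords)
  h1 <- gen_headpiece(headpiece_preset("E1_2K"), frames = 50, seed = 3)
  h2 <- gen_headpiece(headpiece_preset("E1_2K"), frames = 50, seed = 3)
  expect_identical(h1$trajectory$coords, h2$trajectory$coords)
})

test_that("single-state zero-jitter site preset yields constant CN 6", {
  p <- site_preset("MG")
  p$cn_states <- 6L
  p$cn_probs <- 1
  p$jitter_sd <- 0
  p$dist_jitter <- 1e-6
  g <- gen_ion_site(p, frames = 25, seed = 1)
  cs <- coordination_series(g$trajectory, g$manifest$ion_index, 0.21)
  expect_equal(cs$counts, rep(6L, 25))
  # ion pinned at the origin
  expect_equal(max(abs(g$trajectory$coords[1, , ])), 0)
})

test_that("site preset manifest states the RMSF ground truth", {
  g <- gen_ion_site(site_preset("MG"), frames = 6000, seed = 31)
  expect_equal(g$manifest$expected_rmsf, 0.04, tolerance = 1e-9)
  r <- rmsf(g$trajectory, g$manifest$ion_index, g$manifest$align_selection)
  expect_equal(unname(r), 0.04, tolerance = 0.1)
  # infeasible geometry rejected
  p <- site_preset("MG")
  p$ligands <- p$ligands[rep(1, 20), ]
  p$cn_states <- 1:20
  p$cn_probs <- rep(1 / 20, 20)
  expect_error(gen_ion_site(p, frames = 5, seed = 1),
               class = "parameter_error")
})

test_that("dihedral generator obeys its stated world", {
  p <- dihedral_preset("E1_MG")
  p$lumen_fraction <- 1  # switching disabled, state pinned at +150
  g <- gen_dihedral(p, frames = 200, seed = 5)
  occ <- classify_chi2(chi2_series(g$trajectory, 309L)$angles)$occupancy
  expect_equal(unname(occ["lumen"]), 100)
  expect_null(g$manifest$window_warning)

  # jitter wide enough to cross windows is flagged in the manifest
  p2 <- dihedral_preset("E1_MG")
  p2$jitter_deg <- 25
  g2 <- gen_dihedral(p2, frames = 50, seed = 5)
  expect_match(g2$manifest$window_warning, "jitter")
})

test_that("degenerate headpiece preset gives constant distances at the means", {
  p <- headpiece_preset("E1_MG")
  for (nm in names(p$pairs)) p$pairs[[nm]]$sd <- 0
  g <- gen_headpiece(p, frames = 30, seed = 9)
  for (nm in c("N-A", "N-P", "A-P")) {
    ds <- interdomain_series(g$trajectory, nm)
    expect_equal(ds$values, rep(p$pairs[[nm]]$mean, 30), info = nm)
  }
  bad <- headpiece_preset("E1_MG")
  bad$pairs[["N-A"]]$mean <- -1
  expect_error(gen_headpiece(bad, frames = 10, seed = 1),
               class = "parameter_error")
})

test_that("gen_rotation ramps exactly and tolerates noise", {
  set.seed(151)
  ref <- matrix(rnorm(600), 200, 3)
  tr <- gen_rotation(ref, 25, frames = 10, noise_sd = 0, seed = 1)
  expect_equal(axial_rotation_angle(ref, frame_coords(tr, 10)), 25,
               tolerance = 1e-9)
  expect_equal(frame_coords(tr, 1), ref, tolerance = 1e-12)

  tr0 <- gen_rotation(ref, 0, frames = 5, noise_sd = 0, seed = 1)
  for (k in 2:5) expect_equal(frame_coords(tr0, k), ref, tolerance = 1e-12)

  trn <- gen_rotation(ref, 25, frames = 200, noise_sd = 0.05, seed = 4)
  expect_equal(axial_rotation_angle(ref, frame_coords(trn, 200)), 25,
               tolerance = 1 / 25)
})

test_that("fixture bundles are deterministic and seed-invariant in parameters", {
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  d3 <- file.path(tempdir(), "bundle_c")
  gen_fixture_bundle("E1_MG", d1, seed = 1, frames = 40)
  gen_fixture_bundle("E1_MG", d2, seed = 1, frames = 40)
  gen_fixture_bundle("E1_MG", d3, seed = 2, frames = 40)
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))
  expect_identical(readLines(file.path(d1, "site_mg.pdb")),
                   readLines(file.path(d2, "site_mg.pdb")))
  m1 <- jsonlite::fromJSON(file.path(d1, "manifest.json"), simplifyVector = FALSE)
  m3 <- jsonlite::fromJSON(file.path(d3, "manifest.json"), simplifyVector = FALSE)
  strip_seeds <- function(m) {
    m$seed <- NULL
    m$components <- lapply(m$components, function(cc) { cc$seed <- NULL; cc })
    m
  }
  expect_identical(strip_seeds(m1), strip_seeds(m3))
  expect_false(identical(m1, m3))
})

test_that("E1_MG bundle round-trips and is recovered end-to-end", {
  # Reduced to 4000 frames for runtime; statistical tolerances are the
  # 20,000-frame documented ones scaled by sqrt(20000/4000) ~ 2.24 (the
  # full-size recoveries run in the acceptance suite).
  scale <- sqrt(20000 / 4000)
  d <- file.path(tempdir(), "bundle_e2e")
  paths <- gen_fixture_bundle("E1_MG", d, seed = 11, frames = 4000)
  man <- attr(paths, "manifest")

  site <- read_trajectory(paths$site_MG, 0.01)
  ms <- man$components$site_MG
  pop <- coordination_population(
    coordination_series(site, ms$ion_index, ms$cutoff))
  expect_equal(cn_percent(pop, 6), 80, tolerance = 3 * scale / 80)
  r <- rmsf(site, ms$ion_index, ms$align_selection)
  expect_equal(unname(r), ms$expected_rmsf, tolerance = 0.1)

  dih <- read_trajectory(paths$dihedral, 0.01)
  occ <- classify_chi2(chi2_series(dih, 309L)$angles)$occupancy
  expect_equal(unname(occ["lumen"]),
               man$components$dihedral$expected_lumen_pct,
               tolerance = 2 * scale / 62)

  hp <- read_trajectory(paths$headpiece, 0.01)
  for (nm in c("N-A", "N-P")) {
    truth <- man$components$headpiece$pairs[[nm]]
    f1 <- fit_mixture(estimate_density(interdomain_series(hp, nm)), 1)
    expect_equal(f1$components$mean, truth$means[[1]],
                 tolerance = 0.05 * scale / truth$means[[1]], info = nm)
  }
  dm <- load_domain_map(paths$domain_map)
  expect_s3_class(dm, "domain_map")
  np <- read_nonbonded_params(paths$nonbonded)
  expect_s3_class(np, "nonbonded_params")
})
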