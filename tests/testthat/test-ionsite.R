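# Ion-centric analyses: coordination, ligand tables, binding events,
# gateway ordering, interaction energy.

octahedron_traj <- function(radius, frames = 3, ion_first = TRUE) {
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  atoms <- rbind(
    make_atoms("MG", "MG", 9100L, element = "MG", record = "HETATM"),
    make_atoms(rep("OE1", 6), "GLU", 701:706, element = "O"))
  coords <- rbind(c(0, 0, 0), dirs * radius)
  make_traj(atoms, rep(list(coords), frames))
}

test_that("coordination_series counts oxygens strictly inside the cutoff", {
  tr <- octahedron_traj(0.20)
  cs <- coordination_series(tr, 1L, cutoff = 0.21)
  expect_equal(cs$counts, rep(6L, 3))
  # expanded cage: strict inequality drops everything at/beyond the cutoff
  expect_equal(coordination_series(octahedron_traj(0.22), 1L, 0.21)$counts,
               rep(0L, 3))
  expect_equal(coordination_series(octahedron_traj(0.21), 1L, 0.21)$counts,
               rep(0L, 3))
  expect_error(coordination_series(tr, 2L, 0.21), class = "selection_error")
})

test_that("coordination_series is monotone non-decreasing in cutoff", {
  g <- gen_ion_site(site_preset("MG"), frames = 200, seed = 13)
  cuts <- c(0.15, 0.21, 0.25, 0.32, 0.45)
  counts <- sapply(cuts, function(cc)
    coordination_series(g$trajectory, g$manifest$ion_index, cc)$counts)
  for (j in 2:length(cuts))
    expect_true(all(counts[, j] >= counts[, j - 1]), info = paste(cuts[j]))
})

test_that("coordination_population tabulates percentages", {
  mk <- function(counts) structure(list(ion = 1L, species = "MG",
                                        cutoff = 0.21,
                                        times = seq_along(counts),
                                        counts = counts),
                                   class = "coordination_series")
  p <- coordination_population(mk(rep(6L, 10)))
  expect_equal(p$table, data.frame(cn = 6L, percent = 100))
  p2 <- coordination_population(mk(rep(c(5L, 6L), 50)))
  expect_equal(p2$table$percent, c(50, 50))
  expect_equal(sum(p2$table$percent), 100, tolerance = 0.1)
  expect_error(coordination_population(mk(integer())),
               class = "insufficient_data_error")
})

test_that("Markov site preset recovers its stationary CN law", {
  g <- gen_ion_site(site_preset("MG"), frames = 20000, seed = 17)
  man <- g$manifest
  pop <- coordination_population(
    coordination_series(g$trajectory, man$ion_index, man$cutoff))
  # per-bin agreement within 3 points and total-variation distance < 0.03
  emp <- sapply(man$cn_states, function(cn) cn_percent(pop, cn)) / 100
  expect_true(all(abs(emp - man$cn_probs) < 0.03))
  expect_lt(0.5 * sum(abs(emp - man$cn_probs)) +
              0.5 * (1 - sum(emp)), 0.03)
  expect_equal(cn_percent(pop, 6), 80, tolerance = 3 / 80)
})

test_that("ligand_distance_table applies species bonding thresholds to means", {
  tr <- octahedron_traj(0.20, frames = 2)
  lt <- ligand_distance_table(tr, 1L, species = "MG")
  expect_true(all(lt$table$bonded))
  expect_equal(lt$table$mean_nm, rep(0.2, 6))
  expect_equal(lt$table$sd_nm, rep(0, 6))

  lt2 <- ligand_distance_table(octahedron_traj(0.25), 1L, species = "MG")
  expect_false(any(lt2$table$bonded))
  expect_equal(nrow(bonded_ligands(lt2)), 0L)
  # same geometry is bonded for K+ (threshold 0.30)
  lt3 <- ligand_distance_table(octahedron_traj(0.25), 1L, species = "K")
  expect_true(all(lt3$table$bonded))
  expect_error(ligand_distance_table(tr, 1L, species = "NA"),
               class = "parameter_error")
})

test_that("ligand table recovers preset target distances and matches
           pair_distance_series", {
  g <- gen_ion_site(site_preset("MG"), frames = 20000, seed = 19)
  man <- g$manifest
  lt <- ligand_distance_table(g$trajectory, man$ion_index, species = "MG")
  tab <- lt$table
  for (j in seq_len(nrow(man$ligands))) {
    lg <- man$ligands[j, ]
    row <- tab[tab$resid == lg$resid & tab$atom == lg$name, ]
    expect_equal(row$mean_nm, lg$expected_mean, tolerance = 0.005 / lg$expected_mean,
                 info = paste(lg$resid, lg$name))
  }
  # always-bound carboxyl oxygens sit at the 0.20 nm published target
  core <- tab[tab$resid %in% c(771, 800), ]
  expect_true(all(abs(core$mean_nm - 0.20) < 0.005))
  expect_true(all(core$bonded))

  # cross-module consistency with an independent per-atom distance series
  i_oe1 <- select_atoms(g$trajectory, "resid 771 and name OE1")
  ds <- pair_distance_series(g$trajectory, man$ion_index, i_oe1)
  expect_equal(tab$mean_nm[tab$resid == 771 & tab$atom == "OE1"], ds$mean,
               tolerance = 1e-12)
})

test_that("detect_binding_event finds the first sustained run", {
  # scripted approach: ion enters the site at frame 71 (t = 0.07 us)
  n <- 1000
  atoms <- rbind(make_atoms("POT", "POT", 9100L, element = "K",
                            record = "HETATM"),
                 make_atoms("OD1", "ASP", 800L, element = "O"))
  frames <- lapply(seq_len(n), function(k) {
    x <- if (k >= 71) 0.25 else 2.0
    rbind(c(x, 0, 0), c(0, 0, 0))
  })
  tr <- make_traj(atoms, frames, frame_dt = 0.001)
  ev <- detect_binding_event(tr, 1L, "resid 800", cutoff = 0.30, dwell = 10)
  expect_equal(ev$t_on, 0.07)
  expect_true(ev$sustained)

  # bound from frame 1 -> t_on = 0; never bound -> NULL
  always <- make_traj(atoms, rep(list(rbind(c(0.2, 0, 0), c(0, 0, 0))), 20))
  expect_equal(detect_binding_event(always, 1L, "resid 800", 0.30, 5)$t_on, 0)
  never <- make_traj(atoms, rep(list(rbind(c(2, 0, 0), c(0, 0, 0))), 20))
  expect_null(detect_binding_event(never, 1L, "resid 800", 0.30, 5))
  # a run shorter than dwell does not count
  blip <- make_traj(atoms, c(rep(list(rbind(c(2, 0, 0), c(0, 0, 0))), 5),
                             rep(list(rbind(c(0.2, 0, 0), c(0, 0, 0))), 3),
                             rep(list(rbind(c(2, 0, 0), c(0, 0, 0))), 5)))
  expect_null(detect_binding_event(blip, 1L, "resid 800", 0.30, 5))
  expect_error(detect_binding_event(always, 1L, "resid 999", 0.30, 5),
               class = "selection_error")
})

test_that("gateway_contact_order reports scripted first-contact order", {
  # ion walks past E55 -> E58 -> E59 side-chain oxygens, never reaches E109
  atoms <- rbind(make_atoms("POT", "POT", 9100L, element = "K",
                            record = "HETATM"),
                 make_atoms(rep("OE1", 4), "GLU", c(55L, 58L, 59L, 109L),
                            element = "O"))
  site_pos <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0), c(9, 9, 9))
  frames <- lapply(0:40, function(k) {
    rbind(c(1 + k * 0.05, 0.1, 0), site_pos[2:5, ])
  })
  tr <- make_traj(atoms, frames)
  ord <- gateway_contact_order(tr, 1L, c(55, 58, 59, 109), contact_cutoff = 0.3)
  expect_equal(ord$resid, c(55, 58, 59))
  expect_true(all(diff(ord$t_first) > 0))

  far <- make_traj(atoms, list(rbind(c(50, 50, 50), site_pos[2:5, ])))
  expect_equal(nrow(gateway_contact_order(far, 1L, c(55, 58), 0.3)), 0L)
  expect_error(gateway_contact_order(tr, 1L, c(55, 1234), 0.3),
               class = "selection_error")
})

test_that("interaction_energy matches the Coulomb closed form and is additive", {
  params <- nonbonded_params(data.frame(
    resname = c("MG", "*"), name = c("MG", "OE1"),
    charge = c(2, -1), eps = c(0, 0), rmin = c(0.2, 0.3)))
  atoms <- rbind(make_atoms("MG", "MG", 9100L, element = "MG",
                            record = "HETATM"),
                 make_atoms(rep("OE1", 2), "GLU", c(1L, 2L), element = "O"))
  one <- make_traj(atoms[1:2, ], list(rbind(c(0, 0, 0), c(0.30, 0, 0))))
  e1 <- interaction_energy(one, 1L, 2L, params)
  expect_equal(e1$mean, 332.0636 * 2 * (-1) / 3.0, tolerance = 1e-9)

  # symmetric second partner doubles the energy
  two <- make_traj(atoms, list(rbind(c(0, 0, 0), c(0.30, 0, 0),
                                     c(-0.30, 0, 0))))
  e2 <- interaction_energy(two, 1L, 2:3, params)
  expect_equal(e2$mean, 2 * e1$mean, tolerance = 1e-9)
  # additive over disjoint partner selections
  ea <- interaction_energy(two, 1L, 2L, params)$mean
  eb <- interaction_energy(two, 1L, 3L, params)$mean
  expect_equal(ea + eb, e2$mean, tolerance = 1e-12)

  # linear in ion charge with LJ disabled
  params4 <- nonbonded_params(data.frame(
    resname = c("MG", "*"), name = c("MG", "OE1"),
    charge = c(4, -1), eps = c(0.1, 0.12), rmin = c(0.2, 0.3)))
  expect_equal(interaction_energy(two, 1L, 2:3, params4, lj = FALSE)$mean,
               2 * interaction_energy(two, 1L, 2:3, params, lj = FALSE)$mean,
               tolerance = 1e-9)

  # zero-charge ion, distant partners -> ~0
  params0 <- nonbonded_params(data.frame(
    resname = c("MG", "*"), name = c("MG", "OE1"),
    charge = c(0, -1), eps = c(0.01, 0.12), rmin = c(0.2, 0.3)))
  far <- make_traj(atoms[1:2, ], list(rbind(c(0, 0, 0), c(2.5, 0, 0))))
  expect_lt(abs(interaction_energy(far, 1L, 2L, params0)$mean), 0.01)

  # missing parameter names the atom
  missing <- nonbonded_params(data.frame(resname = "MG", name = "MG",
                                         charge = 2, eps = 0, rmin = 0.2))
  err <- expect_error(interaction_energy(one, 1L, 2L, missing),
                      class = "parameter_error")
  expect_match(conditionMessage(err), "GLU 1 OE1")
})
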