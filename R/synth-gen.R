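# Seeded synthetic-trajectory generators.  Each generator returns a
# trajectory plus a GroundTruthManifest: a list recording every parameter
# actually used and every derived expectation (stationary CN law, expected
# RMSF, expected occupancies, mixture laws), sufficient to recompute the
# expectations without rerunning the generator.

# Sticky-redraw Markov chain over 1..K with exact stationary law `probs`:
# with probability 1/corr_frames redraw from `probs`, else keep the state.
markov_states <- function(n, probs, corr_frames = 20) {
  if (abs(sum(probs) - 1) > 1e-9)
    abort("stationary probabilities must sum to 1", "parameter_error")
  if (corr_frames < 1) abort("corr_frames must be >= 1", "parameter_error")
  a <- 1 / corr_frames
  redraw <- c(TRUE, stats::runif(n - 1) < a)
  draws <- sample.int(length(probs), n, replace = TRUE, prob = probs)
  s <- integer(n)
  cur <- draws[1]
  for (k in seq_len(n)) {
    if (redraw[k]) cur <- draws[k]
    s[k] <- cur
  }
  s
}

# Well-separated unit directions for cage ligands: octahedron, then cube
# corners.
cage_directions <- function(n) {
  oct <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  cube <- as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1))) / sqrt(3)
  dirs <- rbind(oct, cube)
  if (n > nrow(dirs))
    abort(sprintf("cannot place %d ligands on distinct directions", n),
          "parameter_error")
  dirs[seq_len(n), , drop = FALSE]
}

anchor_name_for <- function(oxygen) {
  switch(oxygen, OE1 = "CD", OE2 = "CD", OD1 = "CG", OD2 = "CG",
         OG1 = "CB", O = "C", "C")
}

#' Generate a synthetic ion coordination-site trajectory
#'
#' The ion jitters isotropically about the origin (per-axis sd
#' `jitter_sd`, so its expected RMSF is `jitter_sd * sqrt(3)`).  Each
#' ligand oxygen occupies a fixed cage direction; a Markov chain over the
#' preset's coordination-number states decides, frame by frame, how many
#' ligands (in fixed priority order) sit *inside* the species cutoff.
#' Bound oxygens are placed at their target distance (with truncated-normal
#' radial jitter) from the instantaneous ion position, mimicking the
#' correlated breathing of a real first shell; unbound oxygens are
#' displaced beyond the cutoff.  Protein oxygens carry a static anchor
#' carbon at larger radius; the manifest's `align_selection` (`"element
#' C"`) selects these anchors for RMSF alignment, mirroring the real
#' practice of aligning on the protein rather than on the mobile shell.
#'
#' @param preset a [site_preset()].
#' @param frames,seed overrides for the preset frame count and the RNG seed.
#' @return `list(trajectory=, manifest=)`.
#' @export
gen_ion_site <- function(preset, frames = preset$frames, seed = 1L) {
  stopifnot(inherits(preset, "site_preset"))
  set.seed(seed)
  lg <- preset$ligands
  nl <- nrow(lg)
  dirs <- cage_directions(nl)
  cutoff <- preset$cutoff
  in_cap <- cutoff - 0.002
  out_floor <- cutoff + 0.05

  # topology: ion, ligand oxygens, static anchor carbons for protein ligands
  prot <- lg$resname != "HOH"
  ion_resname <- switch(preset$species, K = "POT", CA = "CAL", preset$species)
  atoms <- data.frame(
    serial = 1L, name = ion_resname, element = preset$species,
    resname = ion_resname, resid = 9100L, chain = "A", altloc = "",
    record = "HETATM", stringsAsFactors = FALSE)
  ox <- data.frame(serial = 1L + seq_len(nl), name = lg$name, element = "O",
                   resname = lg$resname, resid = lg$resid, chain = "A",
                   altloc = "", record = ifelse(prot, "ATOM", "HETATM"),
                   stringsAsFactors = FALSE)
  anc <- data.frame(serial = 1L + nl + seq_len(sum(prot)),
                    name = vapply(lg$name[prot], anchor_name_for, ""),
                    element = "C", resname = lg$resname[prot],
                    resid = lg$resid[prot], chain = "A", altloc = "",
                    record = "ATOM", stringsAsFactors = FALSE)
  atoms <- rbind(atoms, ox, anc)
  top <- topology(atoms)
  ion_idx <- 1L
  ox_idx <- 1L + seq_len(nl)
  anc_idx <- 1L + nl + seq_len(sum(prot))

  states <- markov_states(frames, preset$cn_probs, preset$corr_frames)
  cn <- preset$cn_states[states]
  eps <- matrix(stats::rnorm(3 * frames, 0, preset$jitter_sd), frames, 3)

  coords <- array(0, c(nrow(atoms), 3, frames))
  anchor_pos <- dirs[which(prot), , drop = FALSE] *
    (lg$target[prot] + 0.125)  # static, one C-O bond beyond the oxygen
  for (k in seq_len(frames)) {
    ion <- eps[k, ]
    nb <- cn[k]
    d <- numeric(nl)
    if (nb > 0)
      d[seq_len(nb)] <- rtruncnorm1(nb, lg$target[seq_len(nb)],
                                    preset$dist_jitter, upper = in_cap)
    if (nb < nl)
      d[(nb + 1):nl] <- rtruncnorm1(nl - nb, preset$out_distance,
                                    preset$out_jitter, lower = out_floor)
    coords[ion_idx, , k] <- ion
    coords[ox_idx, , k] <- sweep(dirs * d, 2, ion, `+`)
    coords[anc_idx, , k] <- anchor_pos
  }
  traj <- trajectory(top, coords, (seq_len(frames) - 1) * preset$frame_dt)

  p_bound <- vapply(seq_len(nl), function(i) sum(preset$cn_probs[preset$cn_states >= i]),
                    numeric(1))
  mu_in <- truncnorm_mean(lg$target, preset$dist_jitter, upper = in_cap)
  mu_out <- truncnorm_mean(preset$out_distance, preset$out_jitter,
                           lower = out_floor)
  manifest <- list(
    kind = "ion_site", preset = preset$name, species = preset$species,
    seed = seed, frames = frames, frame_dt = preset$frame_dt,
    cutoff = cutoff, cn_states = preset$cn_states, cn_probs = preset$cn_probs,
    corr_frames = preset$corr_frames,
    jitter_sd = preset$jitter_sd,
    expected_rmsf = preset$jitter_sd * sqrt(3),
    align_selection = "element C",
    ion_index = ion_idx,
    ligands = cbind(lg, priority = seq_len(nl), p_bound = p_bound,
                    expected_mean = p_bound * mu_in + (1 - p_bound) * mu_out),
    dist_jitter = preset$dist_jitter,
    out_distance = preset$out_distance)
  list(trajectory = traj, manifest = manifest)
}

# Internal chi2 side-chain geometry: CB at origin, CG on +x, CA off-axis in
# the +y half-plane (defines chi2 = 0 at cis), CD placed at the requested
# torsion.  Bond lengths/angles are idealised sp3 values.
chi2_fragment <- function(chi_deg) {
  b <- 0.153                      # C-C bond, nm
  theta <- deg2rad(113)           # C-C-C angle
  CA <- b * c(cos(deg2rad(111)), sin(deg2rad(111)), 0)
  CB <- c(0, 0, 0)
  CG <- c(b, 0, 0)
  chi <- deg2rad(chi_deg)
  CD <- CG + b * c(cos(pi - theta),
                   sin(pi - theta) * cos(chi),
                   sin(pi - theta) * sin(chi))
  rbind(CA, CB, CG, CD)
}

#' Generate a synthetic two-state chi2 dihedral trajectory
#'
#' A four-atom glutamate side-chain fragment (CA, CB, CG, CD) whose chi2
#' angle follows a two-state Markov chain (lumen/cytosol state centers)
#' with Gaussian angular jitter.  If the jitter gives a state more than 1%
#' probability of leaving its classification window, a warning is recorded
#' in the manifest.
#'
#' @param preset a [dihedral_preset()].
#' @param frames,seed overrides.
#' @return `list(trajectory=, manifest=)`.
#' @export
gen_dihedral <- function(preset, frames = preset$frames, seed = 1L) {
  stopifnot(inherits(preset, "dihedral_preset"))
  set.seed(seed)
  pl <- preset$lumen_fraction
  states <- markov_states(frames, c(pl, 1 - pl), preset$corr_frames)
  ang <- wrap_angle(preset$centers[states] +
                    stats::rnorm(frames, 0, preset$jitter_deg))

  atoms <- data.frame(serial = 1:4, name = c("CA", "CB", "CG", "CD"),
                      element = "C", resname = "GLU", resid = preset$resid,
                      chain = "A", altloc = "", record = "ATOM",
                      stringsAsFactors = FALSE)
  coords <- array(0, c(4, 3, frames))
  for (k in seq_len(frames)) coords[, , k] <- chi2_fragment(ang[k])
  traj <- trajectory(topology(atoms), coords,
                     (seq_len(frames) - 1) * preset$frame_dt)

  # analytic escape probabilities from each window, given the jitter
  z <- preset$jitter_deg
  p_lumen_stay <- stats::pnorm(180 - preset$centers["lumen"], 0, z) -
    stats::pnorm(120 - preset$centers["lumen"], 0, z) +
    1 - stats::pnorm(180 + 120 - preset$centers["lumen"], 0, z)  # wrap into -180..-120
  p_cyto_stay <- stats::pnorm(119 - preset$centers["cytosol"], 0, z) -
    stats::pnorm(40 - preset$centers["cytosol"], 0, z)
  warning_msg <- NULL
  if (min(p_lumen_stay, p_cyto_stay) < 0.99)
    warning_msg <- "angular jitter crosses classification windows with p > 0.01"
  expected_lumen <- 100 * (pl * p_lumen_stay +
                           (1 - pl) * (1 - stats::pnorm(120 - preset$centers["cytosol"], 0, z)))
  manifest <- list(
    kind = "dihedral", preset = preset$name, resid = preset$resid,
    seed = seed, frames = frames, frame_dt = preset$frame_dt,
    centers = as.list(preset$centers), jitter_deg = preset$jitter_deg,
    corr_frames = preset$corr_frames,
    lumen_fraction = pl,
    expected_lumen_pct = unname(expected_lumen),
    window_warning = warning_msg)
  list(trajectory = traj, manifest = manifest)
}

# Stationary per-pair distance process with the requested marginal mixture
# law: Markov switching between components plus within-state AR(1) jitter
# whose stationary law is exactly N(mean, sd^2).
gen_mixture_trace <- function(n, comps, state_corr, within_corr) {
  states <- if (nrow(comps) == 1L) rep(1L, n)
            else markov_states(n, comps$weight, state_corr)
  phi <- exp(-1 / within_corr)
  z <- matrix(stats::rnorm(n * nrow(comps)), n, nrow(comps))
  # one latent standardised AR(1) per component, active one emitted
  lat <- matrix(0, n, nrow(comps))
  lat[1, ] <- z[1, ]
  if (n > 1)
    for (k in 2:n) lat[k, ] <- phi * lat[k - 1, ] + sqrt(1 - phi^2) * z[k, ]
  comps$mean[states] + comps$sd[states] * lat[cbind(seq_len(n), states)]
}

#' Generate a synthetic cytosolic-headpiece trajectory
#'
#' Four CA marker atoms (K515, T171, R489, E680) whose N-A, N-P and A-P
#' pair distances follow stationary processes with the preset's marginal
#' mixture laws.  The three constrained pairs form a chain
#' (K515-T171-E680-R489), so any positive distance triple is embeddable
#' exactly; coordinates are built frame by frame from the three distances.
#'
#' @param preset a [headpiece_preset()].
#' @param frames,seed overrides.
#' @return `list(trajectory=, manifest=)`.
#' @export
gen_headpiece <- function(preset, frames = preset$frames, seed = 1L) {
  stopifnot(inherits(preset, "headpiece_preset"))
  for (p in preset$pairs)
    if (any(p$mean <= 0)) abort("mixture means must be positive distances",
                                "parameter_error")
  set.seed(seed)
  d_na <- gen_mixture_trace(frames, preset$pairs[["N-A"]],
                            preset$state_corr_frames, preset$within_corr_frames)
  d_np <- gen_mixture_trace(frames, preset$pairs[["N-P"]],
                            preset$state_corr_frames, preset$within_corr_frames)
  d_ap <- gen_mixture_trace(frames, preset$pairs[["A-P"]],
                            preset$state_corr_frames, preset$within_corr_frames)
  if (any(c(d_na, d_np, d_ap) <= 0))
    abort("generated a non-positive distance; check preset means/sds",
          "parameter_error")

  atoms <- data.frame(serial = 1:4, name = "CA", element = "C",
                      resname = c("LYS", "THR", "ARG", "GLU"),
                      resid = c(515L, 171L, 489L, 680L), chain = "A",
                      altloc = "", record = "ATOM", stringsAsFactors = FALSE)
  coords <- array(0, c(4, 3, frames))
  coords[1, 1, ] <- d_na                 # K515 on +x from T171 (origin)
  coords[4, 2, ] <- d_ap                 # E680 on +y from T171
  coords[3, 2, ] <- d_ap                 # R489 above E680 along +z
  coords[3, 3, ] <- d_np
  traj <- trajectory(topology(atoms), coords,
                     (seq_len(frames) - 1) * preset$frame_dt)

  manifest <- list(
    kind = "headpiece", preset = preset$name, seed = seed, frames = frames,
    frame_dt = preset$frame_dt,
    state_corr_frames = preset$state_corr_frames,
    within_corr_frames = preset$within_corr_frames,
    pairs = lapply(preset$pairs, function(p)
      list(order = nrow(p), weights = p$weight, means = p$mean, sds = p$sd)))
  list(trajectory = traj, manifest = manifest)
}

#' Generate a noisy rigid rotation about the z axis
#'
#' Frame `k` of `frames` rotates the reference by `total_angle * (k-1) /
#' (frames-1)` degrees about +z (counter-clockwise viewed from +z) and adds
#' isotropic Gaussian noise.
#'
#' @param reference `n x 3` coordinate matrix (nm).
#' @param total_angle degrees reached at the final frame.
#' @param frames number of frames (>= 2).
#' @param noise_sd per-axis Gaussian noise sd, nm.
#' @param seed RNG seed.
#' @param frame_dt time per frame, us.
#' @return A `"trajectory"` of pseudo-CA atoms.
#' @export
gen_rotation <- function(reference, total_angle, frames = 200L,
                         noise_sd = 0, seed = 1L, frame_dt = SYNTH_FRAME_DT) {
  reference <- as.matrix(reference)
  if (frames < 2L) abort("frames must be >= 2", "parameter_error")
  set.seed(seed)
  n <- nrow(reference)
  atoms <- data.frame(serial = seq_len(n), name = "CA", element = "C",
                      resname = "GLY", resid = seq_len(n), chain = "A",
                      altloc = "", record = "ATOM", stringsAsFactors = FALSE)
  coords <- array(0, c(n, 3, frames))
  for (k in seq_len(frames)) {
    th <- deg2rad(total_angle * (k - 1) / (frames - 1))
    Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    noise <- if (noise_sd > 0)
      matrix(stats::rnorm(3 * n, 0, noise_sd), n, 3) else 0
    coords[, , k] <- reference %*% t(Rz) + noise
  }
  trajectory(topology(atoms), coords, (seq_len(frames) - 1) * frame_dt)
}

#' Write a complete synthetic fixture bundle
#'
#' Writes, under `out_dir`: multi-model PDBs for the ion site(s), the chi2
#' dihedral fragment and the headpiece markers of the chosen ensemble, the
#' default domain map, a nonbonded-parameter stub and a combined
#' ground-truth manifest JSON.  `E1_MG` bundles the Mg site, the 62%-lumen
#' dihedral and the unimodal headpiece; `E1_2K` bundles the two K sites,
#' the 69%-lumen dihedral and the bimodal headpiece.  Manifest parameters
#' are analytic, so two bundles generated with different seeds differ only
#' in their `seed` fields.
#'
#' @param ensemble `"E1_MG"` or `"E1_2K"`.
#' @param out_dir output directory (created if needed).
#' @param seed RNG seed; sub-generator seeds are derived deterministically.
#' @param frames frames per component trajectory.
#' @return Named list of written paths, invisibly; the manifest is also
#'   returned as attribute `"manifest"`.
#' @export
gen_fixture_bundle <- function(ensemble = c("E1_MG", "E1_2K"), out_dir,
                               seed = 1L, frames = 20000L) {
  ensemble <- match.arg(ensemble)
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    abort(sprintf("cannot create output directory '%s'", out_dir), "io_error")
  sub_seed <- function(k) (seed * 13L + k) %% .Machine$integer.max
  paths <- list()
  manifest <- list(ensemble = ensemble, seed = seed, frames = frames,
                   components = list())

  sites <- if (ensemble == "E1_MG") "MG" else c("K_I", "K_IPRIME")
  for (j in seq_along(sites)) {
    g <- gen_ion_site(site_preset(sites[j]), frames = frames,
                      seed = sub_seed(j))
    f <- file.path(out_dir, sprintf("site_%s.pdb", tolower(sites[j])))
    write_trajectory(g$trajectory, f)
    paths[[paste0("site_", sites[j])]] <- f
    manifest$components[[paste0("site_", sites[j])]] <- g$manifest
  }
  g <- gen_dihedral(dihedral_preset(ensemble), frames = frames,
                    seed = sub_seed(5L))
  paths$dihedral <- file.path(out_dir, "dihedral_e309.pdb")
  write_trajectory(g$trajectory, paths$dihedral)
  manifest$components$dihedral <- g$manifest

  g <- gen_headpiece(headpiece_preset(ensemble), frames = frames,
                     seed = sub_seed(6L))
  paths$headpiece <- file.path(out_dir, "headpiece.pdb")
  write_trajectory(g$trajectory, paths$headpiece)
  manifest$components$headpiece <- g$manifest

  paths$domain_map <- file.path(out_dir, "domain_map.yaml")
  file.copy(system.file("extdata", "serca_domain_map.yaml",
                        package = "iontraj", mustWork = TRUE),
            paths$domain_map, overwrite = TRUE)
  paths$nonbonded <- file.path(out_dir, "nonbonded_params.txt")
  file.copy(system.file("extdata", "nonbonded_stub.txt",
                        package = "iontraj", mustWork = TRUE),
            paths$nonbonded, overwrite = TRUE)

  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  attr(paths, "manifest") <- manifest
  invisible(paths)
}
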