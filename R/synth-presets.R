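# Ground-truth presets for the synthetic-trajectory generators.  Presets
# encode the stated world of the analyses they exercise: stationary
# coordination-number laws, two-state dihedral occupancies, interdomain
# mixture laws and the expected positional fluctuation of a tightly bound
# ion.  Every derived expectation is computed analytically and recorded in
# the generator manifest so recovery tests never re-derive targets.
#
# Printed population columns of "<1" percent are encoded as 1; the K(I')
# column (which prints to 100.5) is renormalised.  Gaussian sds that are not
# printed anywhere are fixed package constants: 0.15 nm for unimodal
# distributions and 0.12 nm per bimodal component.
#
# Markov state switching uses a "sticky redraw" chain: with probability
# 1/corr_frames the state is redrawn from the stationary law, otherwise it
# is kept.  The stationary distribution is therefore exact by construction
# and corr_frames sets the correlation time.  The generic default is
# corr_frames = 20; the site and dihedral presets use corr_frames = 2
# because shell and side-chain exchange is nanosecond-scale while frames
# represent 0.01-us samples, so successive samples are nearly decorrelated.

SYNTH_FRAME_DT <- 0.01       # us per synthetic frame (one sample each 0.01 us)
UNIMODAL_SD <- 0.15          # nm, order-1 preset components
BIMODAL_SD <- 0.12           # nm, order-2 preset components

#' Ion coordination-site presets
#'
#' Ground truth for [gen_ion_site()].  `"MG"` encodes the magnesium site:
#' stationary coordination-number law (CN 4:1%, 5:14%, 6:80%, 7:5%), ligand
#' target distances of 0.20-0.21 nm for the carboxyl/amide oxygens of E771,
#' D800 and N796 plus two waters, positional jitter sized so the expected
#' ion RMSF is 0.04 nm.  `"K_I"` and `"K_IPRIME"` encode the two potassium
#' sites with their broader CN laws (CN 2-7) and 0.26-0.30 nm ligands.
#'
#' @param which `"MG"`, `"K_I"` or `"K_IPRIME"`.
#' @return List of class `"site_preset"`.
#' @export
site_preset <- function(which = c("MG", "K_I", "K_IPRIME")) {
  which <- match.arg(which)
  lig <- function(resname, resid, name, target)
    data.frame(resname = resname, resid = resid, name = name,
               target = target, stringsAsFactors = FALSE)
  if (which == "MG") {
    ligands <- rbind(
      lig("GLU", 771, "OE1", 0.20), lig("GLU", 771, "OE2", 0.20),
      lig("ASP", 800, "OD1", 0.20), lig("ASP", 800, "OD2", 0.20),
      lig("ASN", 796, "OD1", 0.21),
      lig("HOH", 9001, "O", 0.20), lig("HOH", 9002, "O", 0.20))
    cn_states <- 4:7
    cn_probs <- c(1, 14, 80, 5) / 100
    species <- "MG"
  } else if (which == "K_I") {
    ligands <- rbind(
      lig("GLU", 771, "OE1", 0.27), lig("THR", 799, "OG1", 0.29),
      lig("ASP", 800, "OD1", 0.30), lig("ASP", 800, "OD2", 0.30),
      lig("GLU", 908, "OE1", 0.29),
      lig("HOH", 9001, "O", 0.28), lig("HOH", 9002, "O", 0.28))
    cn_states <- 2:7
    cn_probs <- c(5, 20, 36, 29, 9, 1) / 100
    species <- "K"
  } else {
    ligands <- rbind(
      lig("ALA", 305, "O", 0.26), lig("ASP", 800, "OD1", 0.30),
      lig("HOH", 9001, "O", 0.28), lig("HOH", 9002, "O", 0.28),
      lig("HOH", 9003, "O", 0.28), lig("HOH", 9004, "O", 0.28),
      lig("HOH", 9005, "O", 0.28))
    cn_states <- 2:7
    p <- c(5, 22, 38, 26, 8.5, 1)
    cn_probs <- p / sum(p)
    species <- "K"
  }
  stopifnot(max(cn_states) <= nrow(ligands))
  structure(list(name = which, species = species,
                 cutoff = bonding_threshold(species),
                 ligands = ligands, cn_states = cn_states,
                 cn_probs = cn_probs,
                 jitter_sd = 0.04 / sqrt(3),  # expected RMSF = 0.04 nm
                 dist_jitter = 0.01, out_distance = 0.35, out_jitter = 0.02,
                 corr_frames = 2, frames = 20000L,
                 frame_dt = SYNTH_FRAME_DT),
            class = "site_preset")
}

#' Two-state side-chain dihedral presets
#'
#' Ground truth for [gen_dihedral()]: a glutamate whose chi2 switches
#' between a lumen-facing state (center +150 deg) and a cytosol-facing
#' state (center +80 deg) with angular jitter of 10 deg and a stated
#' stationary lumen fraction -- 0.62 for the Mg2+-bound ensemble, 0.69 for
#' the 2K+ ensemble.
#'
#' @param which `"E1_MG"` (lumen fraction 0.62) or `"E1_2K"` (0.69).
#' @return List of class `"dihedral_preset"`.
#' @export
dihedral_preset <- function(which = c("E1_MG", "E1_2K")) {
  which <- match.arg(which)
  structure(list(name = which, resid = 309L,
                 centers = c(lumen = 150, cytosol = 80),
                 jitter_deg = 10,
                 lumen_fraction = if (which == "E1_MG") 0.62 else 0.69,
                 corr_frames = 2, frames = 20000L,
                 frame_dt = SYNTH_FRAME_DT),
            class = "dihedral_preset")
}

#' Interdomain headpiece distance presets
#'
#' Ground truth for [gen_headpiece()].  `"E1_MG"`: all three interfaces
#' unimodal with means N-A 2.7 nm, N-P 0.95 nm, A-P 2.6 nm.  `"E1_2K"`:
#' N-A bimodal at 3.3/3.8 nm, N-P bimodal at 1.6/2.4 nm (equal weights),
#' A-P unimodal at 2.6 nm.  Component sds are the package constants (0.15
#' unimodal, 0.12 bimodal); the E1_MG A-P mean is a package choice.
#'
#' @param which `"E1_MG"` or `"E1_2K"`.
#' @return List of class `"headpiece_preset"`.
#' @export
headpiece_preset <- function(which = c("E1_MG", "E1_2K")) {
  which <- match.arg(which)
  comp <- function(weights, means, sds)
    data.frame(weight = weights, mean = means, sd = sds)
  pairs <- if (which == "E1_MG") {
    list("N-A" = comp(1, 2.7, UNIMODAL_SD),
         "N-P" = comp(1, 0.95, UNIMODAL_SD),
         "A-P" = comp(1, 2.6, UNIMODAL_SD))
  } else {
    list("N-A" = comp(c(0.5, 0.5), c(3.3, 3.8), BIMODAL_SD),
         "N-P" = comp(c(0.5, 0.5), c(1.6, 2.4), BIMODAL_SD),
         "A-P" = comp(1, 2.6, UNIMODAL_SD))
  }
  structure(list(name = which, pairs = pairs,
                 state_corr_frames = 20, within_corr_frames = 5,
                 frames = 20000L, frame_dt = SYNTH_FRAME_DT),
            class = "headpiece_preset")
}
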