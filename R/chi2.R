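# Side-chain chi2 dihedral series and lumen/cytosol orientation
# classification for glutamate gating residues.
#
# Classification windows (continuous-boundary reading of the integer
# windows): lumen |chi2| >= 120, cytosol 40 <= |chi2| < 120, otherwise
# unclassified.  Occupancies are percentages of ALL frames, so the three
# fractions always sum to 100.

CHI2_LUMEN_MIN <- 120
CHI2_CYTO_MIN <- 40

#' chi2 dihedral time series of a residue
#'
#' chi2 is defined by atoms CA, CB, CG, CD in that order (glutamate
#' convention).
#'
#' @param traj a trajectory.
#' @param resid residue number; must carry CA, CB, CG and CD atoms.
#' @return Object of class `"chi2_series"`: `resid`, `times` (us),
#'   `angles` (degrees in (-180, 180]).
#' @export
chi2_series <- function(traj, resid) {
  at <- traj$topology$atoms
  idx <- vapply(c("CA", "CB", "CG", "CD"), function(nm) {
    i <- which(at$resid == resid & at$name == nm)
    if (length(i) != 1L)
      abort(sprintf("residue %d lacks atom %s required for chi2", resid, nm),
            "topology_error")
    i
  }, integer(1))
  nf <- n_frames(traj)
  ang <- vapply(seq_len(nf), function(k) {
    p <- traj$coords[idx, , k]
    dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
  }, numeric(1))
  structure(list(resid = resid, times = traj$times, angles = ang),
            class = "chi2_series")
}

#' @export
print.chi2_series <- function(x, ...) {
  cat(sprintf("<chi2_series> residue %d, %d frames\n", x$resid,
              length(x$angles)))
  invisible(x)
}

#' Classify chi2 angles as lumen- or cytosol-facing
#'
#' @param angles numeric vector of degrees in (-180, 180], or a
#'   `"chi2_series"`.
#' @return List of class `"chi2_states"`: `labels` (factor with levels
#'   lumen/cytosol/unclassified) and `occupancy` (named percentages of all
#'   frames, summing to 100).
#' @export
classify_chi2 <- function(angles) {
  if (inherits(angles, "chi2_series")) angles <- angles$angles
  if (any(!is.finite(angles)) || any(angles <= -180 | angles > 180))
    abort("angles must be finite and in (-180, 180]", "parameter_error")
  a <- abs(angles)
  lab <- ifelse(a >= CHI2_LUMEN_MIN, "lumen",
                ifelse(a >= CHI2_CYTO_MIN, "cytosol", "unclassified"))
  lab <- factor(lab, levels = c("lumen", "cytosol", "unclassified"))
  occ <- 100 * table(lab) / length(lab)
  structure(list(labels = lab,
                 occupancy = stats::setNames(as.numeric(occ), names(occ))),
            class = "chi2_states")
}

#' @export
print.chi2_states <- function(x, ...) {
  cat(sprintf("<chi2_states> lumen %.1f%%, cytosol %.1f%%, unclassified %.1f%% (n = %d)\n",
              x$occupancy["lumen"], x$occupancy["cytosol"],
              x$occupancy["unclassified"], length(x$labels)))
  invisible(x)
}

#' chi2 series with per-frame state labels
#'
#' Convenience composition of [chi2_series()] and [classify_chi2()].
#'
#' @inheritParams chi2_series
#' @return Object of class `"chi2_state_series"`: `resid`, `times`,
#'   `angles`, `labels`, `occupancy`.
#' @export
chi2_state_series <- function(traj, resid) {
  cs <- chi2_series(traj, resid)
  st <- classify_chi2(cs$angles)
  structure(list(resid = resid, times = cs$times, angles = cs$angles,
                 labels = st$labels, occupancy = st$occupancy),
            class = "chi2_state_series")
}
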