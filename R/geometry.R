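# Per-frame geometric observables: RMSD series, RMSF, dihedrals, pair
# distances and rotation about a fixed axis.

resolve_reference <- function(traj, reference) {
  if (inherits(reference, "mdstructure")) return(reference$coords)
  if (is.matrix(reference)) return(reference)
  if (is.numeric(reference) && length(reference) == 1L)
    return(frame_coords(traj, reference))
  abort("reference must be a structure, coordinate matrix or frame index",
        "parameter_error")
}

#' Per-frame RMSD of a selection after alignment on another selection
#'
#' Every frame is superposed onto the reference using the `align_sel` atoms
#' only; the RMSD is then computed over `analyze_sel` *without re-fitting*,
#' so rigid-body displacement of the analysed group relative to the aligned
#' group is captured.  Set `self_fit = TRUE` to instead superpose on
#' `analyze_sel` itself (internal-deformation-only mode).
#'
#' @param traj a trajectory.
#' @param analyze_sel,align_sel selection expressions or index vectors;
#'   both nonempty.
#' @param reference reference coordinates: an `"mdstructure"`, a full-topology
#'   coordinate matrix, or a frame index (default 1).
#' @param label series label (e.g. a domain name).
#' @param self_fit logical; see above.
#' @return Object of class `"rmsd_series"`: `label`, `mode`, `times` (us),
#'   `values` (nm).
#' @export
rmsd_series <- function(traj, analyze_sel, align_sel = analyze_sel,
                        reference = 1L, label = "rmsd", self_fit = FALSE) {
  ai <- select_atoms(traj, analyze_sel)
  gi <- if (self_fit) ai else select_atoms(traj, align_sel)
  if (!length(ai) || !length(gi))
    abort("empty selection in rmsd_series", "selection_error")
  ref <- resolve_reference(traj, reference)
  nf <- n_frames(traj)
  vals <- numeric(nf)
  for (k in seq_len(nf)) {
    fc <- traj$coords[, , k]
    tf <- kabsch_superpose(fc[gi, , drop = FALSE], ref[gi, , drop = FALSE])
    moved <- apply_transform(fc[ai, , drop = FALSE], tf)
    vals[k] <- rmsd_between(moved, ref[ai, , drop = FALSE])
  }
  structure(list(label = label,
                 mode = if (self_fit) "self-fit" else "fit-on-align-sel",
                 times = traj$times, values = vals), class = "rmsd_series")
}

#' @export
print.rmsd_series <- function(x, ...) {
  cat(sprintf("<rmsd_series> %s [%s], %d frames, mean %.4f nm\n",
              x$label, x$mode, length(x$values), mean(x$values)))
  invisible(x)
}

#' Root-mean-square fluctuation per atom
#'
#' Frames are aligned to an iteratively re-estimated mean structure (two
#' passes) using `align_sel`; the RMSF of each `atom_sel` atom is the root
#' of its time-averaged squared deviation from its mean position.
#' Mass-unweighted.
#'
#' @param traj a trajectory with at least 2 frames.
#' @param atom_sel atoms to report.
#' @param align_sel atoms used for the superposition (default: `atom_sel`).
#' @return Named numeric vector, nm per atom (names = atom indices).
#' @export
rmsf <- function(traj, atom_sel, align_sel = atom_sel) {
  ai <- select_atoms(traj, atom_sel)
  gi <- select_atoms(traj, align_sel)
  if (!length(ai) || !length(gi)) abort("empty selection in rmsf", "selection_error")
  nf <- n_frames(traj)
  if (nf < 2L) abort("rmsf needs at least 2 frames", "insufficient_data_error")

  use <- sort(unique(c(ai, gi)))
  gpos <- match(gi, use); apos <- match(ai, use)
  coords <- traj$coords[use, , , drop = FALSE]
  mean_ref <- apply(coords[gpos, , , drop = FALSE], c(1, 2), mean)
  for (pass in 1:2) {
    aligned <- coords
    for (k in seq_len(nf)) {
      tf <- kabsch_superpose(coords[gpos, , k], mean_ref)
      aligned[, , k] <- apply_transform(coords[, , k], tf)
    }
    mean_ref <- apply(aligned[gpos, , , drop = FALSE], c(1, 2), mean)
    coords <- aligned
  }
  mean_all <- apply(coords, c(1, 2), mean)
  dev2 <- (coords - array(mean_all, dim(coords)))^2
  out <- sqrt(apply(dev2, 1, mean) * 3)[apos]  # mean over (xyz, frames) * 3
  names(out) <- ai
  out
}

#' Torsion angle of four points
#'
#' IUPAC sign convention: positive for a clockwise rotation of `p4` relative
#' to `p1` when viewed from `p1` along the `p2 -> p3` axis; cis = 0, trans =
#' 180.
#'
#' @param p1,p2,p3,p4 length-3 coordinate vectors.
#' @return Angle in degrees in `(-180, 180]`.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (vec_norm(b1) == 0 || vec_norm(b2) == 0 || vec_norm(b3) == 0)
    abort("coincident consecutive points in dihedral", "degenerate_geometry_error")
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  ang <- atan2(sum(cr(n1, n2) * b2) / vec_norm(b2), sum(n1 * n2))
  wrap_angle(rad2deg(ang))
}

#' Distance series between two single atoms
#'
#' @param traj a trajectory.
#' @param selA,selB selections each resolving to exactly one atom.
#' @param label series label.
#' @return Object of class `"distance_series"`: `label`, `times` (us),
#'   `values`, `mean`, `sd` (nm).
#' @export
pair_distance_series <- function(traj, selA, selB, label = NULL) {
  ia <- select_one(traj, selA); ib <- select_one(traj, selB)
  dx <- traj$coords[ia, , , drop = FALSE] - traj$coords[ib, , , drop = FALSE]
  d <- sqrt(apply(dx^2, 3, sum))
  if (is.null(label)) {
    at <- traj$topology$atoms
    label <- sprintf("%s%d:%s-%s%d:%s", at$resname[ia], at$resid[ia],
                     at$name[ia], at$resname[ib], at$resid[ib], at$name[ib])
  }
  distance_series(label, traj$times, d)
}

distance_series <- function(label, times, values) {
  structure(list(label = label, times = times, values = values,
                 mean = mean(values), sd = stats::sd(values)),
            class = "distance_series")
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf("<distance_series> %s: %d frames, %.4f +/- %.4f nm\n",
              x$label, length(x$values), x$mean,
              if (is.na(x$sd)) 0 else x$sd))
  invisible(x)
}

#' Best-fit rotation angle about a fixed axis
#'
#' After removing the centroid of each point set, returns the angle of the
#' in-plane rotation about `axis` that best maps `reference` onto `frame`
#' (closed form from the summed cross and dot products of the components
#' perpendicular to the axis).  Counter-clockwise positive when viewed from
#' the +axis direction.
#'
#' @param reference,frame `n x 3` matrices, `n >= 3`.
#' @param axis rotation axis, default membrane normal `c(0, 0, 1)`;
#'   normalised internally.
#' @return Angle in degrees in `(-180, 180]`.
#' @export
axial_rotation_angle <- function(reference, frame, axis = c(0, 0, 1)) {
  reference <- as.matrix(reference); frame <- as.matrix(frame)
  if (!all(dim(reference) == dim(frame)) || nrow(reference) < 3L)
    abort("need equal-sized point sets with >= 3 points", "parameter_error")
  a <- axis / vec_norm(axis)
  perp <- function(x) {
    x <- sweep(x, 2, colMeans(x))
    x - outer(as.numeric(x %*% a), a)
  }
  r <- perp(reference); f <- perp(frame)
  if (max(rowSums(r^2)) < 1e-18)
    abort("all points lie on the rotation axis", "degenerate_geometry_error")
  dot <- sum(r * f)
  crs <- sum((r[, 1] * f[, 2] - r[, 2] * f[, 1]) * a[3] +
             (r[, 2] * f[, 3] - r[, 3] * f[, 2]) * a[1] +
             (r[, 3] * f[, 1] - r[, 1] * f[, 3]) * a[2])
  wrap_angle(rad2deg(atan2(crs, dot)))
}
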