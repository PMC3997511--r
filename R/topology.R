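#' Build a topology from an atom table
#'
#' A topology holds the per-atom metadata shared by every frame of a
#' trajectory: serial, atom name, element, residue name/number, chain and
#' altloc, plus derived indices of monatomic ions and water oxygens and an
#' optional domain map.  Residue numbers are taken verbatim from the input
#' (author numbering); nothing is renumbered.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resid`, `chain`, `altloc` (and optionally `record`).
#' @param domain_map optional [domain_map()] to attach.
#' @return An object of class `"topology"`.
#' @export
topology <- function(atoms, domain_map = NULL) {
  req <- c("serial", "name", "element", "resname", "resid", "chain", "altloc")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    abort(paste("atom table lacks columns:", paste(miss, collapse = ", ")),
          "format_error")
  if (nrow(atoms) == 0L) abort("topology has zero atoms", "empty_input_error")
  if (anyDuplicated(atoms$serial))
    abort("atom serial numbers are not unique", "format_error")
  if (any(!nzchar(atoms$name)))
    abort("atom names must be nonempty", "format_error")
  if (is.null(atoms$record)) atoms$record <- "ATOM"
  rownames(atoms) <- NULL

  top <- structure(list(atoms = atoms, domain_map = NULL,
                        ion_atoms = detect_ions(atoms),
                        water_oxygens = detect_water_oxygens(atoms)),
                   class = "topology")
  if (!is.null(domain_map)) top <- attach_domain_map(top, domain_map)
  top
}

ION_RESNAMES <- c(MG = "MG", K = "K", POT = "K", CA = "CA", CAL = "CA")
WATER_RESNAMES <- c("HOH", "TIP3", "WAT", "TIP3P", "SPC")

detect_ions <- function(atoms) {
  hit <- atoms$resname %in% names(ION_RESNAMES)
  data.frame(index = which(hit),
             species = unname(ION_RESNAMES[atoms$resname[hit]]),
             stringsAsFactors = FALSE)
}

detect_water_oxygens <- function(atoms) {
  which(atoms$resname %in% WATER_RESNAMES & atoms$element == "O")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("<topology> %d atoms, %d ions (%s), %d water oxygens, domain map: %s\n",
              nrow(x$atoms), nrow(x$ion_atoms),
              if (nrow(x$ion_atoms)) paste(x$ion_atoms$species, collapse = ",") else "-",
              length(x$water_oxygens),
              if (is.null(x$domain_map)) "none" else "attached"))
  invisible(x)
}

n_atoms <- function(topology) nrow(topology$atoms)

#' Assemble a trajectory object
#'
#' @param topology a [topology()].
#' @param coords numeric array of dimension `c(n_atoms, 3, n_frames)`, nm.
#' @param times frame times in microseconds, strictly increasing.
#' @return Object of class `"trajectory"`.
#' @export
trajectory <- function(topology, coords, times) {
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  d <- dim(coords)
  if (length(d) != 3L || d[2] != 3L)
    abort("coords must be an n_atoms x 3 x n_frames array", "format_error")
  if (d[1] != n_atoms(topology))
    abort("coordinate count does not match topology atom count", "alignment_error")
  if (d[3] < 1L) abort("trajectory needs at least one frame", "empty_input_error")
  if (length(times) != d[3])
    abort("length(times) must equal the number of frames", "format_error")
  if (any(!is.finite(coords))) abort("non-finite coordinates", "format_error")
  if (d[3] > 1L && any(diff(times) <= 0))
    abort("frame times must be strictly increasing", "format_error")
  structure(list(topology = topology, coords = coords, times = as.numeric(times)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d atoms x %d frames, t = %g..%g us\n",
              n_atoms(x$topology), n_frames(x), x$times[1],
              x$times[n_frames(x)]))
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[3]

#' Extract the coordinate matrix of one frame
#'
#' @param traj a trajectory.
#' @param i frame index (1-based).
#' @return `n_atoms x 3` matrix in nm.
#' @export
frame_coords <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) abort("frame index out of range", "parameter_error")
  traj$coords[, , i, drop = TRUE]
}

# Single-model structure (topology + one coordinate set), as returned by
# read_structure() and consumed by the crystal-reference helpers.
structure_frame <- function(topology, coords, time = 0) {
  structure(list(topology = topology, coords = coords, time = time),
            class = "mdstructure")
}

#' @export
print.mdstructure <- function(x, ...) {
  cat(sprintf("<structure> %d atoms at t = %g us\n", n_atoms(x$topology), x$time))
  invisible(x)
}

# Accept a trajectory or single structure and return a trajectory.
as_trajectory <- function(x) {
  if (inherits(x, "trajectory")) return(x)
  if (inherits(x, "mdstructure"))
    return(trajectory(x$topology, array(x$coords, c(nrow(x$coords), 3, 1)), x$time))
  abort("expected a trajectory or structure", "parameter_error")
}
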