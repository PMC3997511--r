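# Multi-model PDB reading and writing.  PDB is the package's canonical,
# text-diffable interchange format; coordinates are converted Angstrom <-> nm
# at this boundary and nowhere else.

parse_pdb_atoms <- function(lines, path, altloc_policy = "first") {
  rec <- substr(lines, 1, 6)
  sel <- rec %in% c("ATOM  ", "HETATM")
  idx <- which(sel)
  if (!length(idx)) abort(sprintf("no ATOM/HETATM records in '%s'", path),
                          "empty_input_error")
  ln <- lines[idx]

  num <- function(s, what) {
    v <- suppressWarnings(as.numeric(s))
    if (anyNA(v)) {
      bad <- idx[which(is.na(v))[1]]
      abort(sprintf("unparseable %s in '%s' at line %d", what, path, bad),
            "format_error")
    }
    v
  }

  serial  <- num(substr(ln, 7, 11), "atom serial")
  name    <- trimws(substr(ln, 13, 16))
  altloc  <- trimws(substr(ln, 17, 17))
  resname <- trimws(substr(ln, 18, 21))
  chain   <- trimws(substr(ln, 22, 22))
  resid   <- num(substr(ln, 23, 26), "residue number")
  x <- num(substr(ln, 31, 38), "x coordinate")
  y <- num(substr(ln, 39, 46), "y coordinate")
  z <- num(substr(ln, 47, 54), "z coordinate")
  element <- trimws(substr(ln, 77, 78))
  element <- ifelse(nzchar(element), toupper(element), element_from_name(name))

  atoms <- data.frame(serial = as.integer(serial), name = name,
                      element = element, resname = resname,
                      resid = as.integer(resid), chain = chain,
                      altloc = altloc, record = trimws(substr(ln, 1, 6)),
                      stringsAsFactors = FALSE)
  keep <- resolve_altloc(atoms, altloc_policy)
  coords <- unname(cbind(x, y, z))[keep, , drop = FALSE] / ANGSTROM_PER_NM
  dimnames(coords) <- NULL
  list(atoms = atoms[keep, , drop = FALSE], coords = coords)
}

# Element heuristic for files lacking columns 77-78: strip digits, take the
# leading letter; names starting with a digit (e.g. "1HB") are hydrogens.
element_from_name <- function(name) {
  first <- substr(gsub("[0-9']", "", name), 1, 1)
  toupper(ifelse(grepl("^[0-9]", name), "H", first))
}

resolve_altloc <- function(atoms, policy) {
  if (identical(policy, "all")) return(seq_len(nrow(atoms)))
  has_alt <- nzchar(atoms$altloc)
  if (!any(has_alt)) return(seq_len(nrow(atoms)))
  key <- paste(atoms$chain, atoms$resid, atoms$resname, atoms$name, sep = "\r")
  if (identical(policy, "first")) return(which(!duplicated(key)))
  if (is_string(policy) && nchar(policy) == 1L) {
    keep <- !has_alt | atoms$altloc == policy
    return(which(keep))
  }
  abort("altloc_policy must be \"first\", \"all\", or a single location code",
        "parameter_error")
}

#' Read a single-model PDB structure
#'
#' Coordinates are converted from Angstrom to nm.  Monatomic ions (resname
#' MG, K/POT, CA/CAL) and water oxygens (resname HOH/TIP3/WAT) are detected
#' and indexed on the returned topology.
#'
#' @param path PDB file with ATOM/HETATM records (first MODEL used if several).
#' @param altloc_policy `"first"` (default: keep the first-listed alternate
#'   location), `"all"`, or a single altloc code such as `"A"`.
#' @return An object of class `"mdstructure"`: a topology plus one
#'   coordinate set (`$topology`, `$coords` in nm).
#' @export
read_structure <- function(path, altloc_policy = "first") {
  lines <- readLines(path, warn = FALSE)
  models <- split_models(lines)
  p <- parse_pdb_atoms(models[[1]], path, altloc_policy)
  structure_frame(topology(p$atoms), p$coords)
}

split_models <- function(lines) {
  starts <- grep("^MODEL", lines)
  if (!length(starts)) return(list(lines))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  mapply(function(s, e) lines[s:e], starts, ends, SIMPLIFY = FALSE)
}

#' Read a multi-model PDB trajectory
#'
#' Model `k` (1-based) is assigned time `(k-1) * frame_dt` microseconds; the
#' topology is taken from the first model.  Atom ordering must be constant
#' across models.
#'
#' @param path multi-model PDB file (a single-model file yields a one-frame
#'   trajectory at t = 0).
#' @param frame_dt time spacing between consecutive models, microseconds.
#' @param altloc_policy see [read_structure()].
#' @return A `"trajectory"`.
#' @export
read_trajectory <- function(path, frame_dt, altloc_policy = "first") {
  check_scalar_number(frame_dt, "frame_dt", positive = TRUE)
  lines <- readLines(path, warn = FALSE)
  models <- split_models(lines)
  first <- parse_pdb_atoms(models[[1]], path, altloc_policy)
  nat <- nrow(first$atoms)
  coords <- array(NA_real_, c(nat, 3, length(models)))
  coords[, , 1] <- first$coords
  if (length(models) > 1) {
    for (k in 2:length(models)) {
      p <- parse_pdb_atoms(models[[k]], path, altloc_policy)
      if (nrow(p$atoms) != nat)
        abort(sprintf("model %d of '%s' has %d atoms, expected %d",
                      k, path, nrow(p$atoms), nat), "alignment_error")
      coords[, , k] <- p$coords
    }
  }
  trajectory(topology(first$atoms), coords,
             (seq_along(models) - 1) * frame_dt)
}

format_pdb_block <- function(atoms, coords_nm) {
  xyz <- coords_nm * ANGSTROM_PER_NM
  # PDB atom-name column convention: names shorter than 4 characters start
  # in column 14
  nm <- ifelse(nchar(atoms$name) >= 4, substr(atoms$name, 1, 4),
               sprintf(" %-3s", atoms$name))
  sprintf("%-6s%5d %4s%1s%-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          atoms$record, atoms$serial %% 100000L, nm,
          substr(paste0(atoms$altloc, " "), 1, 1), atoms$resname,
          substr(paste0(atoms$chain, " "), 1, 1), atoms$resid %% 10000L,
          xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, atoms$element)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Inverse of [read_trajectory()]; coordinates round-trip to PDB precision
#' (0.0001 nm).
#'
#' @param traj a trajectory.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  atoms <- traj$topology$atoms
  nf <- n_frames(traj)
  blocks <- character(nf)
  for (k in seq_len(nf)) {
    blocks[k] <- paste(c(sprintf("MODEL %8d", k),
                         format_pdb_block(atoms, traj$coords[, , k]),
                         "ENDMDL"), collapse = "\n")
  }
  writeLines(c(blocks, "END"), path)
  invisible(path)
}

#' Write a single-model PDB structure
#'
#' @param struct an `"mdstructure"` (or one-frame trajectory).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(struct, path) {
  if (inherits(struct, "trajectory")) {
    struct <- structure_frame(struct$topology, frame_coords(struct, 1),
                              struct$times[1])
  }
  writeLines(c(format_pdb_block(struct$topology$atoms, struct$coords), "END"),
             path)
  invisible(path)
}
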