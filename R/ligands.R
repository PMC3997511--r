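# Ion-ligand distance tables, binding-event detection and entry-pathway
# contact ordering.

#' Ion-ligand mean distance table with bonding filter
#'
#' For every candidate oxygen atom, computes the mean and standard deviation
#' of its distance to the ion over all frames.  The `bonded` flag applies
#' the species bonding threshold (0.21 / 0.30 / 0.25 nm for Mg2+ / K+ /
#' Ca2+) to the *mean*: a mean at or above the threshold is non-bonding.
#'
#' @param traj a trajectory.
#' @param ion atom index of the ion.
#' @param candidate_atoms selection of candidate coordinating atoms
#'   (default: all oxygens).
#' @param species `"MG"`, `"K"` or `"CA"`; fixes the bonding threshold.
#' @return Object of class `"ligand_table"` wrapping a data.frame with
#'   columns `resname`, `resid`, `atom`, `mean_nm`, `sd_nm`, `bonded`,
#'   sorted by residue number.
#' @export
ligand_distance_table <- function(traj, ion, candidate_atoms = "element O",
                                  species) {
  check_ion_index(traj, ion)
  threshold <- bonding_threshold(species)
  cand <- setdiff(select_atoms(traj, candidate_atoms), ion)
  at <- traj$topology$atoms
  rows <- lapply(cand, function(i) {
    dx <- traj$coords[i, , , drop = FALSE] - traj$coords[ion, , , drop = FALSE]
    d <- sqrt(apply(dx^2, 3, sum))
    data.frame(resname = at$resname[i], resid = at$resid[i], atom = at$name[i],
               mean_nm = mean(d),
               sd_nm = if (length(d) > 1) stats::sd(d) else 0,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$resid, tab$atom), , drop = FALSE]
  tab$bonded <- tab$mean_nm < threshold
  rownames(tab) <- NULL
  structure(list(table = tab, species = toupper(species),
                 threshold = threshold, ion = ion),
            class = "ligand_table")
}

#' @export
print.ligand_table <- function(x, ...) {
  cat(sprintf("<ligand_table> %s ion (atom %d), bonding threshold %.2f nm\n",
              x$species, x$ion, x$threshold))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Bonded-only view of a ligand table
#'
#' Mirrors the published-table convention of removing non-bonding rows.
#'
#' @param lt a `"ligand_table"`.
#' @return data.frame of bonded rows only.
#' @export
bonded_ligands <- function(lt) lt$table[lt$table$bonded, , drop = FALSE]

#' Detect a sustained ion binding event
#'
#' The binding time `t_on` is the time of the first sampled frame that
#' begins a run of at least `dwell` consecutive sampled frames in which the
#' ion lies within `cutoff` of at least one site atom.
#'
#' @param traj a trajectory.
#' @param ion atom index of the ion.
#' @param site_atoms nonempty selection defining the site.
#' @param cutoff contact cutoff, nm.
#' @param dwell minimum run length in sampled frames (default 10).
#' @param stride frame stride for sampling (default 1).
#' @param site site name recorded on the event.
#' @return A list of class `"binding_event"` (`ion`, `site`, `t_on`,
#'   `sustained`), or `NULL` if no qualifying run exists.  `sustained` is
#'   `TRUE` when the detected run extends to the end of the trajectory.
#' @export
detect_binding_event <- function(traj, ion, site_atoms, cutoff, dwell = 10L,
                                 stride = 1L, site = "site") {
  check_ion_index(traj, ion)
  check_scalar_number(cutoff, "cutoff", positive = TRUE)
  if (dwell < 1L) abort("dwell must be >= 1", "parameter_error")
  si <- select_atoms(traj, site_atoms)
  if (!length(si)) abort("empty site selection", "selection_error")
  ks <- sample_frames(traj, stride)
  inside <- vapply(ks, function(k) {
    dx <- sweep(matrix(traj$coords[si, , k], ncol = 3), 2,
                traj$coords[ion, , k], `-`)
    any(rowSums(dx^2) < cutoff^2)
  }, logical(1))
  runs <- rle(inside)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  hit <- which(runs$values & runs$lengths >= dwell)
  if (!length(hit)) return(NULL)
  first <- hit[1]
  structure(list(ion = ion, site = site,
                 t_on = traj$times[ks[starts[first]]],
                 sustained = ends[first] == length(ks)),
            class = "binding_event")
}

#' @export
print.binding_event <- function(x, ...) {
  cat(sprintf("<binding_event> ion atom %d binds %s at t = %g us (%s)\n",
              x$ion, x$site, x$t_on,
              if (x$sustained) "sustained to end" else "transient"))
  invisible(x)
}

#' First-contact order along an entry pathway
#'
#' For each gateway residue, finds the time of the first sampled frame in
#' which the ion comes within `contact_cutoff` of any of its side-chain
#' oxygens.  Residues never contacted are omitted; rows are sorted by time.
#'
#' @param traj a trajectory.
#' @param ion atom index of the ion.
#' @param gateway_resids residue numbers lining the pathway (all must exist
#'   in the topology).
#' @param contact_cutoff nm.
#' @param stride frame stride (default 1).
#' @return data.frame with columns `resid`, `t_first` (us), sorted by
#'   `t_first`; zero rows if no residue is ever contacted.
#' @export
gateway_contact_order <- function(traj, ion, gateway_resids, contact_cutoff,
                                  stride = 1L) {
  check_ion_index(traj, ion)
  check_scalar_number(contact_cutoff, "contact_cutoff", positive = TRUE)
  at <- traj$topology$atoms
  missing <- setdiff(gateway_resids, unique(at$resid))
  if (length(missing))
    abort(paste("gateway residue(s) absent from topology:",
                paste(missing, collapse = ", ")), "selection_error")
  ks <- sample_frames(traj, stride)
  rows <- lapply(gateway_resids, function(r) {
    oi <- which(at$resid == r & at$element == "O" & !(at$name %in% c("O", "OXT")))
    if (!length(oi)) return(NULL)
    for (j in seq_along(ks)) {
      k <- ks[j]
      dx <- sweep(matrix(traj$coords[oi, , k], ncol = 3), 2,
                  traj$coords[ion, , k], `-`)
      if (any(rowSums(dx^2) < contact_cutoff^2))
        return(data.frame(resid = r, t_first = traj$times[k]))
    }
    NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(resid = integer(), t_first = numeric()))
  out <- out[order(out$t_first), , drop = FALSE]
  rownames(out) <- NULL
  out
}
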