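# Nonbonded ion-protein interaction energy: Coulomb (no cutoff, uniform
# relative dielectric) plus 12-6 Lennard-Jones with Lorentz-Berthelot
# combining.  The result is an estimate labelled as such: reproducing
# force-field publication values requires the original parameter set and
# protocol, which are not bundled.

COULOMB_KCAL_A <- 332.0636  # kcal * Angstrom / (mol * e^2)

#' Build a nonbonded parameter set
#'
#' @param table data.frame with columns `resname` (residue name or `"*"`),
#'   `name` (atom name or `"*"`), `charge` (e), `eps` (kcal/mol, >= 0) and
#'   `rmin` (nm; self-pair minimum-energy distance).  Rows are matched to
#'   atoms most-specific first: exact (resname, name), then (`"*"`, name),
#'   then (resname, `"*"`).
#' @param dielectric relative dielectric constant (> 0), default 1 (vacuum).
#' @return Object of class `"nonbonded_params"`.
#' @export
nonbonded_params <- function(table, dielectric = 1) {
  req <- c("resname", "name", "charge", "eps", "rmin")
  miss <- setdiff(req, names(table))
  if (length(miss))
    abort(paste("parameter table lacks columns:", paste(miss, collapse = ", ")),
          "parameter_error")
  if (any(table$eps < 0)) abort("LJ well depth must be >= 0", "parameter_error")
  check_scalar_number(dielectric, "dielectric", positive = TRUE)
  structure(list(table = table, dielectric = dielectric),
            class = "nonbonded_params")
}

#' Read nonbonded parameters from a whitespace-separated text table
#'
#' Columns: `resname name charge eps rmin`; `#` starts a comment; `*` is a
#' wildcard.  `eps` in kcal/mol, `rmin` in nm.
#'
#' @param path parameter file.
#' @param dielectric relative dielectric constant, default 1.
#' @return A `"nonbonded_params"`.
#' @export
read_nonbonded_params <- function(path, dielectric = 1) {
  tab <- utils::read.table(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  nonbonded_params(tab, dielectric)
}

lookup_params <- function(params, atoms, idx) {
  tab <- params$table
  out <- data.frame(charge = numeric(length(idx)), eps = numeric(length(idx)),
                    rmin = numeric(length(idx)))
  for (j in seq_along(idx)) {
    i <- idx[j]
    hit <- which(tab$resname == atoms$resname[i] & tab$name == atoms$name[i])
    if (!length(hit)) hit <- which(tab$resname == "*" & tab$name == atoms$name[i])
    if (!length(hit)) hit <- which(tab$resname == atoms$resname[i] & tab$name == "*")
    if (!length(hit))
      abort(sprintf("no nonbonded parameters for atom %s %d %s",
                    atoms$resname[i], atoms$resid[i], atoms$name[i]),
            "parameter_error")
    out[j, ] <- tab[hit[1], c("charge", "eps", "rmin")]
  }
  out
}

#' Trajectory-averaged nonbonded ion interaction energy
#'
#' Per frame, sums over partner atoms the Coulomb term
#' `332.0636 * qi * qj / (dielectric * r_Angstrom)` and, unless `lj =
#' FALSE`, the 12-6 Lennard-Jones term `eps_ij * ((rmin_ij/r)^12 - 2 *
#' (rmin_ij/r)^6)` with Lorentz-Berthelot combining (`eps_ij =
#' sqrt(eps_i*eps_j)`, `rmin_ij = (rmin_i+rmin_j)/2`).  No distance cutoff.
#'
#' @param traj a trajectory.
#' @param ion atom index of the ion.
#' @param partner_sel selection of partner atoms.
#' @param params a [nonbonded_params()] covering the ion and every partner.
#' @param lj logical; include the Lennard-Jones term (default TRUE).
#' @return List of class `"interaction_energy"`: `mean` (kcal/mol),
#'   `series`, `times`, `dielectric`.
#' @export
interaction_energy <- function(traj, ion, partner_sel, params, lj = TRUE) {
  check_ion_index(traj, ion)
  if (!inherits(params, "nonbonded_params"))
    abort("'params' must be a nonbonded_params object", "parameter_error")
  pi_ <- setdiff(select_atoms(traj, partner_sel), ion)
  if (!length(pi_)) abort("empty partner selection", "selection_error")
  at <- traj$topology$atoms
  ip <- lookup_params(params, at, ion)
  pp <- lookup_params(params, at, pi_)
  eps_ij <- sqrt(ip$eps * pp$eps)
  rmin_ij <- (ip$rmin + pp$rmin) / 2
  qq <- ip$charge * pp$charge

  nf <- n_frames(traj)
  e <- numeric(nf)
  for (k in seq_len(nf)) {
    dx <- sweep(matrix(traj$coords[pi_, , k], ncol = 3), 2,
                traj$coords[ion, , k], `-`)
    r_nm <- sqrt(rowSums(dx^2))
    ec <- COULOMB_KCAL_A * qq / (params$dielectric * r_nm * ANGSTROM_PER_NM)
    el <- if (lj) {
      s6 <- (rmin_ij / r_nm)^6
      eps_ij * (s6^2 - 2 * s6)
    } else 0
    e[k] <- sum(ec + el)
  }
  structure(list(mean = mean(e), series = e, times = traj$times,
                 dielectric = params$dielectric),
            class = "interaction_energy")
}

#' @export
print.interaction_energy <- function(x, ...) {
  cat(sprintf("<interaction_energy> estimate: mean %.1f kcal/mol over %d frames (dielectric %g)\n",
              x$mean, length(x$series), x$dielectric))
  invisible(x)
}
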