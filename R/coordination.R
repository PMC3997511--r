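# Metal-ion coordination analysis: per-frame shell counts and their
# population distribution.

#' Species-specific oxygen-metal cutoffs and bonding thresholds (nm)
#'
#' Coordination cutoffs: 0.21 nm (Mg2+) and 0.30 nm (K+).  Bonding
#' thresholds applied to mean ion-ligand distances: 0.21 (Mg2+), 0.30 (K+),
#' 0.25 (Ca2+); a mean at or above the threshold is non-bonding.
#'
#' @param species one of `"MG"`, `"K"`, `"CA"`.
#' @return The threshold in nm.
#' @export
bonding_threshold <- function(species) {
  th <- c(MG = 0.21, K = 0.30, CA = 0.25)
  if (!is_string(species) || !(toupper(species) %in% names(th)))
    abort(sprintf("unknown ion species '%s' (expected MG, K or CA)",
                  as.character(species)[1]), "parameter_error")
  unname(th[toupper(species)])
}

check_ion_index <- function(traj, ion) {
  ion <- as.integer(ion)
  hit <- match(ion, traj$topology$ion_atoms$index)
  if (length(ion) != 1L || is.na(hit))
    abort("'ion' must be the atom index of a detected ion", "selection_error")
  traj$topology$ion_atoms$species[hit]
}

sample_frames <- function(traj, stride) {
  stride <- as.integer(stride)
  if (stride < 1L) abort("stride must be >= 1 frame", "parameter_error")
  seq(1L, n_frames(traj), by = stride)
}

#' Coordination-number time series of an ion
#'
#' Counts, in each sampled frame, the oxygen atoms (protein *and* water)
#' strictly within `cutoff` of the ion.
#'
#' @param traj a trajectory.
#' @param ion atom index of the ion (must be a detected ion).
#' @param cutoff oxygen-metal cutoff in nm (default: species bonding cutoff,
#'   0.21 for Mg2+ / 0.30 for K+).
#' @param stride sample every `stride`-th frame (default 1; the source
#'   convention of one sample per 0.01 us corresponds to
#'   `stride = round(0.01 / frame_dt)`).
#' @return Object of class `"coordination_series"`: `ion`, `species`,
#'   `cutoff`, `times`, `counts`.
#' @export
coordination_series <- function(traj, ion, cutoff = NULL, stride = 1L) {
  species <- check_ion_index(traj, ion)
  cutoff <- cutoff %||% bonding_threshold(species)
  check_scalar_number(cutoff, "cutoff", positive = TRUE)
  ox <- which(traj$topology$atoms$element == "O")
  ks <- sample_frames(traj, stride)
  counts <- integer(length(ks))
  for (j in seq_along(ks)) {
    k <- ks[j]
    dx <- sweep(traj$coords[ox, , k, drop = FALSE][, , 1, drop = TRUE],
                2, traj$coords[ion, , k], `-`)
    if (is.null(dim(dx))) dx <- matrix(dx, ncol = 3)
    counts[j] <- sum(rowSums(dx^2) < cutoff^2)
  }
  structure(list(ion = ion, species = species, cutoff = cutoff,
                 times = traj$times[ks], counts = counts),
            class = "coordination_series")
}

#' @export
print.coordination_series <- function(x, ...) {
  cat(sprintf("<coordination_series> %s ion (atom %d), cutoff %.2f nm, %d samples\n",
              x$species, x$ion, x$cutoff, length(x$counts)))
  invisible(x)
}

#' Population distribution of coordination numbers
#'
#' @param series a `"coordination_series"`.
#' @return Object of class `"coordination_population"`: data.frame with
#'   columns `cn` and `percent` (summing to 100), one row per observed
#'   coordination number.
#' @export
coordination_population <- function(series) {
  if (!length(series$counts))
    abort("empty coordination series", "insufficient_data_error")
  tab <- table(series$counts)
  out <- data.frame(cn = as.integer(names(tab)),
                    percent = 100 * as.numeric(tab) / length(series$counts))
  structure(list(table = out, n = length(series$counts),
                 species = series$species),
            class = "coordination_population")
}

#' @export
print.coordination_population <- function(x, ...) {
  cat(sprintf("<coordination_population> %s, n = %d samples\n", x$species, x$n))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Percent of samples at a given coordination number
#'
#' @param pop a `"coordination_population"`.
#' @param cn coordination number.
#' @return Percent (0 if never observed).
#' @export
cn_percent <- function(pop, cn) {
  hit <- match(cn, pop$table$cn)
  if (is.na(hit)) 0 else pop$table$percent[hit]
}
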