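# CSV/JSON export helpers.  Every time series exports as CSV with columns
# (time_us, value_nm) plus a JSON sidecar carrying summary statistics and
# provenance; tables mirror their published layouts.

write_json_sidecar <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export a time series as CSV with a JSON sidecar
#'
#' @param series a `"distance_series"`, `"rmsd_series"` or
#'   `"coordination_series"`.
#' @param path CSV output path; the sidecar goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  if (inherits(series, "coordination_series")) {
    df <- data.frame(time_us = series$times, coordination_number = series$counts)
    side <- list(type = "coordination_series", ion = series$ion,
                 species = series$species, cutoff_nm = series$cutoff,
                 n = length(series$counts))
  } else if (inherits(series, "rmsd_series")) {
    df <- data.frame(time_us = series$times, value_nm = series$values)
    side <- list(type = "rmsd_series", label = series$label,
                 mode = series$mode, mean_nm = mean(series$values))
  } else if (inherits(series, "distance_series")) {
    df <- data.frame(time_us = series$times, value_nm = series$values)
    side <- list(type = "distance_series", label = series$label,
                 mean_nm = series$mean, sd_nm = series$sd)
  } else abort("unsupported series type", "parameter_error")
  utils::write.csv(df, path, row.names = FALSE)
  write_json_sidecar(side, paste0(path, ".json"))
  invisible(path)
}

#' Export a ligand distance table as CSV
#'
#' Mirrors the published layout (residue, oxygen type, mean +/- sd, bonded
#' flag); set `bonded_only = TRUE` to drop non-bonding rows as the printed
#' table does.
#'
#' @param lt a `"ligand_table"`.
#' @param path CSV output path.
#' @param bonded_only drop non-bonding rows.
#' @return `path`, invisibly.
#' @export
write_ligand_table <- function(lt, path, bonded_only = FALSE) {
  tab <- if (bonded_only) bonded_ligands(lt) else lt$table
  utils::write.csv(tab, path, row.names = FALSE)
  write_json_sidecar(list(type = "ligand_table", species = lt$species,
                          threshold_nm = lt$threshold, ion = lt$ion),
                     paste0(path, ".json"))
  invisible(path)
}

#' Export a coordination population as CSV
#'
#' @param pop a `"coordination_population"`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_population <- function(pop, path) {
  utils::write.csv(pop$table, path, row.names = FALSE)
  invisible(path)
}

#' Export a chi2 state series as CSV plus occupancy JSON
#'
#' @param css a `"chi2_state_series"`.
#' @param path CSV output path (columns time_us, angle_deg, label).
#' @return `path`, invisibly.
#' @export
write_chi2_series <- function(css, path) {
  utils::write.csv(data.frame(time_us = css$times, angle_deg = css$angles,
                              label = as.character(css$labels)),
                   path, row.names = FALSE)
  write_json_sidecar(list(type = "chi2_state_series", resid = css$resid,
                          occupancy_pct = as.list(css$occupancy)),
                     paste0(path, ".json"))
  invisible(path)
}

#' Export a distance distribution and its fit as CSV plus a JSON summary
#'
#' @param fit a `"mixture_fit"`.
#' @param path CSV output path (columns bin_center_nm, empirical_density,
#'   fitted_density).
#' @param crystal optional `"crystal_comparison"` to embed in the summary.
#' @return `path`, invisibly.
#' @export
write_mixture_fit <- function(fit, path, crystal = NULL) {
  utils::write.csv(data.frame(bin_center_nm = fit$centers,
                              empirical_density = fit$empirical,
                              fitted_density = fit$fitted),
                   path, row.names = FALSE)
  side <- list(type = "mixture_fit", pair = fit$pair, order = fit$order,
               weights = fit$components$weight, means = fit$components$mean,
               sds = fit$components$sd, r = fit$r)
  if (!is.null(crystal))
    side$crystal <- list(bounds_nm = crystal$bounds,
                         within = crystal$within$within_bounds)
  write_json_sidecar(side, paste0(path, ".json"))
  invisible(path)
}
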