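# Configuration-driven orchestration: run the full analysis battery on a
# trajectory and emit a report bundle (CSV tables + JSON summaries + a
# structured run log).  Stages are isolated: a failing stage is recorded
# and the remaining independent stages still run; the bundle is then
# marked partial.  Output tables are deterministic for a fixed config and
# inputs; wall-clock timestamps live only in the run log.

#' Read a run configuration
#'
#' YAML (or JSON) with keys: `trajectory` (path), `frame_dt` (us),
#' `domain_map` (path, optional), `ions` (named list: each with `select`
#' or `index`, `species`, optional `cutoff`, `site_selection`), `analyses`
#' (toggles/parameter lists: `coordination`, `ligand_table`, `carboxyl`,
#' `chi2`, `rmsd`, `rmsf`, `rotation`, `headpiece`), `crystal_refs`
#' (named paths, optional), `out_dir`, `seed`.
#'
#' @param path config file.
#' @return The config list (class `"run_config"`).
#' @export
read_run_config <- function(path) {
  cfg <- read_config_file(path)
  structure(cfg, class = "run_config")
}

stage_runner <- function(bundle, name, fun) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(fun(), error = function(e) e)
  elapsed <- proc.time()[["elapsed"]] - t0
  if (inherits(res, "error")) {
    bundle$errors[[name]] <- conditionMessage(res)
    bundle$log[[length(bundle$log) + 1L]] <-
      list(stage = name, status = "error", message = conditionMessage(res),
           seconds = round(elapsed, 3))
  } else {
    bundle$log[[length(bundle$log) + 1L]] <-
      list(stage = name, status = "ok", rows = res$rows %||% NA,
           seconds = round(elapsed, 3))
    for (nm in names(res$tables)) bundle$tables[[nm]] <- res$tables[[nm]]
    for (nm in names(res$fits)) bundle$fits[[nm]] <- res$fits[[nm]]
  }
  bundle
}

#' Run the full analysis battery
#'
#' Executes, as enabled by the config: per-ion coordination series and
#' populations plus ligand distance tables (and optional binding-event
#' detection), carboxyl-pair distance series, chi2 classification,
#' per-domain RMSD and ion RMSF, A-domain axial rotation between first and
#' last frame, and interdomain distance distributions with mixture fits
#' and optional crystal comparison.  Writes CSV/JSON under `out_dir` when
#' given.
#'
#' @param config a `"run_config"`, a config list, or a path.
#' @return Object of class `"report_bundle"`: `tables` (named data.frames),
#'   `fits`, `errors`, `partial`, `log`, `provenance`.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- config
  an <- cfg$analyses %||% list()
  bundle <- structure(list(tables = list(), fits = list(), errors = list(),
                           log = list(), partial = FALSE,
                           provenance = list()), class = "report_bundle")
  bundle$provenance <- list(
    config = unclass(cfg),
    config_hash = config_hash(cfg),
    package_version = as.character(utils::packageVersion("iontraj")),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  traj <- NULL
  if (!is.null(cfg$trajectory)) {
    traj <- read_trajectory(cfg$trajectory, cfg$frame_dt %||% 0.01)
    if (!is.null(cfg$domain_map)) traj <- attach_domain_map(traj, cfg$domain_map)
  }

  for (ion_name in names(cfg$ions %||% list())) {
    ion_cfg <- cfg$ions[[ion_name]]
    bundle <- stage_runner(bundle, paste0("ion_", ion_name), function() {
      idx <- if (!is.null(ion_cfg$index)) as.integer(ion_cfg$index)
             else select_one(traj, ion_cfg$select, "ion selection")
      out <- list(tables = list(), rows = 0)
      if (isTRUE(an$coordination) || is.list(an$coordination)) {
        p <- if (is.list(an$coordination)) an$coordination else list()
        cs <- coordination_series(traj, idx, cutoff = ion_cfg$cutoff %||% NULL,
                                  stride = p$stride %||% 1L)
        pop <- coordination_population(cs)
        out$tables[[paste0(ion_name, "_coordination_population")]] <- pop$table
        out$tables[[paste0(ion_name, "_coordination_series")]] <-
          data.frame(time_us = cs$times, cn = cs$counts)
      }
      if (isTRUE(an$ligand_table) || is.list(an$ligand_table)) {
        p <- if (is.list(an$ligand_table)) an$ligand_table else list()
        lt <- ligand_distance_table(traj, idx,
                                    candidate_atoms = p$candidates %||% "element O",
                                    species = ion_cfg$species)
        out$tables[[paste0(ion_name, "_ligand_table")]] <- lt$table
      }
      if (is.list(an$binding) && !is.null(ion_cfg$site_selection)) {
        ev <- detect_binding_event(traj, idx, ion_cfg$site_selection,
                                   cutoff = an$binding$cutoff %||%
                                     bonding_threshold(ion_cfg$species),
                                   dwell = an$binding$dwell %||% 10L,
                                   site = ion_name)
        out$tables[[paste0(ion_name, "_binding_event")]] <- if (is.null(ev))
          data.frame(site = character(), t_on = numeric(),
                     sustained = logical())
        else data.frame(site = ev$site, t_on = ev$t_on,
                        sustained = ev$sustained)
      }
      out$rows <- length(out$tables)
      out
    })
  }

  if (isTRUE(an$carboxyl) || is.list(an$carboxyl)) {
    bundle <- stage_runner(bundle, "carboxyl_pairs", function() {
      rows <- lapply(names(carboxyl_pair_specs()), function(nm) {
        ds <- carboxyl_pair_series(traj, nm)
        data.frame(pair = nm, mean_nm = ds$mean, sd_nm = ds$sd)
      })
      list(tables = list(carboxyl_pairs = do.call(rbind, rows)),
           rows = length(rows))
    })
  }

  if (is.list(an$chi2)) {
    bundle <- stage_runner(bundle, "chi2", function() {
      css <- chi2_state_series(traj, an$chi2$resid %||% 309L)
      list(tables = list(chi2_occupancy = data.frame(
        label = names(css$occupancy), percent = as.numeric(css$occupancy))),
        rows = 1)
    })
  }

  if (is.list(an$rmsd)) {
    bundle <- stage_runner(bundle, "rmsd", function() {
      doms <- an$rmsd$domains %||% c("N", "P", "A", "TM")
      align <- an$rmsd$align %||% "domain TM and backbone"
      rows <- lapply(doms, function(d) {
        rs <- rmsd_series(traj, sprintf("domain %s and backbone", d),
                          align, reference = 1L, label = d)
        data.frame(domain = d, mean_nm = mean(rs$values),
                   final_nm = rs$values[length(rs$values)])
      })
      list(tables = list(domain_rmsd = do.call(rbind, rows)),
           rows = length(rows))
    })
  }

  if (is.list(an$rmsf)) {
    bundle <- stage_runner(bundle, "rmsf", function() {
      r <- rmsf(traj, an$rmsf$atoms, an$rmsf$align %||% an$rmsf$atoms)
      list(tables = list(rmsf = data.frame(atom_index = as.integer(names(r)),
                                           rmsf_nm = as.numeric(r))),
           rows = length(r))
    })
  }

  if (is.list(an$rotation)) {
    bundle <- stage_runner(bundle, "rotation", function() {
      sel <- an$rotation$selection %||%
        sprintf("domain %s and backbone", an$rotation$domain %||% "A")
      idx <- select_atoms(traj, sel)
      ang <- axial_rotation_angle(frame_coords(traj, 1)[idx, , drop = FALSE],
                                  frame_coords(traj, n_frames(traj))[idx, , drop = FALSE])
      list(tables = list(axial_rotation = data.frame(
        selection = sel, angle_deg = ang)), rows = 1)
    })
  }

  if (is.list(an$headpiece) || isTRUE(an$headpiece)) {
    p <- if (is.list(an$headpiece)) an$headpiece else list()
    bundle <- stage_runner(bundle, "headpiece", function() {
      pairs <- p$pairs %||% names(interdomain_pairs())
      fits <- list(); rows <- list()
      for (nm in pairs) {
        ds <- interdomain_series(traj, nm)
        dd <- estimate_density(ds, bin_width = p$bin_width %||% 0.05)
        f1 <- fit_mixture(dd, 1); f2 <- fit_mixture(dd, 2)
        ch <- select_model(f1, f2)
        fits[[nm]] <- ch
        rows[[nm]] <- data.frame(pair = nm, order = ch$order,
                                 component = seq_len(ch$order),
                                 weight = ch$components$weight,
                                 mean_nm = ch$components$mean,
                                 sd_nm = ch$components$sd, r = ch$r)
      }
      list(tables = list(headpiece_fits = do.call(rbind, rows)),
           fits = fits, rows = length(pairs))
    })
  }

  if (!is.null(cfg$crystal_refs) && length(bundle$fits)) {
    bundle <- stage_runner(bundle, "crystal_comparison", function() {
      anchors <- lapply(cfg$crystal_refs, read_structure)
      rows <- list()
      for (nm in names(bundle$fits)) {
        reg <- interdomain_pairs()[[nm]]
        if (is.null(reg)) next
        vals <- vapply(anchors, function(s) crystal_reference_distance(
          s, sprintf("resid %d and name CA", reg)), numeric(1))
        cmpr <- compare_to_crystal(bundle$fits[[nm]], vals)
        rows[[nm]] <- cbind(pair = nm, cmpr$within)
      }
      list(tables = list(crystal_comparison = do.call(rbind, rows)),
           rows = length(rows))
    })
  }

  bundle$partial <- length(bundle$errors) > 0
  if (!is.null(cfg$out_dir)) write_bundle(bundle, cfg$out_dir)
  bundle
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(bundle$tables))
    utils::write.csv(bundle$tables[[nm]],
                     file.path(out_dir, paste0(nm, ".csv")), row.names = FALSE)
  write_json_sidecar(list(partial = bundle$partial, errors = bundle$errors,
                          provenance = bundle$provenance, log = bundle$log),
                     file.path(out_dir, "run_log.json"))
  invisible(out_dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> %d tables, %d fits, %s\n",
              length(x$tables), length(x$fits),
              if (x$partial) sprintf("PARTIAL (%d stage errors)",
                                     length(x$errors)) else "complete"))
  for (nm in names(x$tables)) cat("  -", nm, "\n")
  invisible(x)
}

#' Compare two report bundles
#'
#' Shared tables are aligned on their non-numeric key columns and numeric
#' columns are differenced row by row; mixture fits are compared on order
#' and component means.  Tables present on only one side are flagged, not
#' fatal.
#'
#' @param bundleA,bundleB `"report_bundle"` objects from [run_analysis()].
#' @return List of class `"bundle_comparison"`: `tables` (named list of
#'   difference data.frames), `fits` (data.frame of order/mean
#'   differences), `only_in_a`, `only_in_b`, `warnings`.
#' @export
compare_runs <- function(bundleA, bundleB) {
  shared <- intersect(names(bundleA$tables), names(bundleB$tables))
  warnings <- character()
  if (!length(shared))
    warnings <- c(warnings, "bundles share no tables; empty comparison")
  diffs <- list()
  for (nm in shared) {
    a <- bundleA$tables[[nm]]; b <- bundleB$tables[[nm]]
    keys <- names(a)[!vapply(a, is.numeric, logical(1))]
    num <- intersect(names(a)[vapply(a, is.numeric, logical(1))],
                     names(b)[vapply(b, is.numeric, logical(1))])
    if (length(keys) && all(keys %in% names(b))) {
      m <- merge(a, b, by = keys, suffixes = c("_a", "_b"))
      for (cn in num) m[[paste0(cn, "_diff")]] <-
        m[[paste0(cn, "_b")]] - m[[paste0(cn, "_a")]]
      diffs[[nm]] <- m
    } else if (nrow(a) == nrow(b)) {
      d <- a
      for (cn in num) d[[paste0(cn, "_diff")]] <- b[[cn]] - a[[cn]]
      diffs[[nm]] <- d
    } else {
      warnings <- c(warnings,
                    sprintf("table %s: incompatible shapes, skipped", nm))
    }
  }
  fit_rows <- list()
  for (nm in intersect(names(bundleA$fits), names(bundleB$fits))) {
    fa <- bundleA$fits[[nm]]; fb <- bundleB$fits[[nm]]
    fit_rows[[nm]] <- data.frame(
      pair = nm, order_a = fa$order, order_b = fb$order,
      mean_shift_nm = mean(fb$components$mean) - mean(fa$components$mean))
  }
  structure(list(tables = diffs,
                 fits = if (length(fit_rows)) do.call(rbind, fit_rows)
                        else data.frame(),
                 only_in_a = setdiff(names(bundleA$tables), names(bundleB$tables)),
                 only_in_b = setdiff(names(bundleB$tables), names(bundleA$tables)),
                 warnings = warnings),
            class = "bundle_comparison")
}

#' @export
print.bundle_comparison <- function(x, ...) {
  cat(sprintf("<bundle_comparison> %d shared tables, %d fit rows\n",
              length(x$tables), nrow(x$fits)))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
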