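# Carboxyl-carboxyl pair distances between the TM acidic residues that form
# the cation-binding sites, using fixed atom conventions, plus single-frame
# crystal-reference distances.

#' Built-in carboxyl-pair atom conventions
#'
#' Three centrally positioned acidic residues are tracked with the following
#' atom conventions:
#' * `E771-D800`: CD of E771 to CG of D800;
#' * `E771-E908`: OE1 of E771 to the protonated OE2 of E908;
#' * `D800-E908`: CG of D800 to OE2 of E908 (E908 is modelled protonated, so
#'   its "O-epsilon" is taken as OE2, consistently with `E771-E908`).
#'
#' @return Named list of specs, each a list with `name`, `selA`, `selB`.
#' @export
carboxyl_pair_specs <- function() {
  list(
    "E771-D800" = list(name = "E771-D800",
                       selA = "resid 771 and name CD",
                       selB = "resid 800 and name CG"),
    "E771-E908" = list(name = "E771-E908",
                       selA = "resid 771 and name OE1",
                       selB = "resid 908 and name OE2"),
    "D800-E908" = list(name = "D800-E908",
                       selA = "resid 800 and name CG",
                       selB = "resid 908 and name OE2")
  )
}

resolve_pair_spec <- function(pair) {
  if (is_string(pair)) {
    specs <- carboxyl_pair_specs()
    if (is.null(specs[[pair]]))
      abort(sprintf("unknown carboxyl pair '%s' (built-ins: %s)", pair,
                    paste(names(specs), collapse = ", ")), "parameter_error")
    return(specs[[pair]])
  }
  if (is.list(pair) && all(c("selA", "selB") %in% names(pair))) {
    pair$name <- pair$name %||% "custom-pair"
    return(pair)
  }
  abort("pair must be a built-in name or a list(selA=, selB=)", "parameter_error")
}

#' Carboxyl-pair distance series
#'
#' @param traj a trajectory.
#' @param pair a built-in pair name (`"E771-D800"`, `"E771-E908"`,
#'   `"D800-E908"`) or a custom `list(name=, selA=, selB=)`.
#' @return A `"distance_series"`.
#' @export
carboxyl_pair_series <- function(traj, pair) {
  spec <- resolve_pair_spec(pair)
  tryCatch(
    pair_distance_series(traj, spec$selA, spec$selB, label = spec$name),
    iontraj_error = function(e) {
      if (inherits(e, "cardinality_error"))
        abort(sprintf("pair %s: %s", spec$name, conditionMessage(e)),
              "topology_error")
      stop(e)
    })
}

#' Single-structure reference distance
#'
#' Extracts one pair distance from a single-model structure (typically a
#' crystal reference).  Averaging over several structures is the caller's
#' loop.
#'
#' @param struct an `"mdstructure"` (e.g. from [read_structure()]).
#' @param pair a built-in carboxyl pair name, a `list(selA=, selB=)`, or a
#'   length-2 character vector of single-atom selections.
#' @return Distance in nm.
#' @export
crystal_reference_distance <- function(struct, pair) {
  if (is.character(pair) && length(pair) == 2L)
    pair <- list(name = "custom-pair", selA = pair[1], selB = pair[2])
  spec <- resolve_pair_spec(pair)
  traj <- as_trajectory(struct)
  ia <- tryCatch(select_one(traj, spec$selA), iontraj_error = function(e)
    abort(sprintf("pair %s: %s", spec$name, conditionMessage(e)), "topology_error"))
  ib <- tryCatch(select_one(traj, spec$selB), iontraj_error = function(e)
    abort(sprintf("pair %s: %s", spec$name, conditionMessage(e)), "topology_error"))
  vec_norm(traj$coords[ia, , 1] - traj$coords[ib, , 1])
}
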