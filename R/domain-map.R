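# Domain maps: named residue-range lists for the four functional domains of
# a P-type ATPase (N, P, A, TM) plus optional helix sub-ranges.  The four
# core domains must be pairwise disjoint.  No published per-residue partition
# is assumed; the shipped default map (inst/extdata/serca_domain_map.yaml)
# is a documented package default for SERCA1a author numbering.

CORE_DOMAINS <- c("N", "P", "A", "TM")

#' Construct and validate a domain map
#'
#' @param domains named list; each element is a two-column matrix/data.frame
#'   or list of `c(start, end)` closed residue-number intervals.  Must
#'   contain at least `N`, `P`, `A` and `TM`.
#' @return Object of class `"domain_map"`.
#' @export
domain_map <- function(domains) {
  miss <- setdiff(CORE_DOMAINS, names(domains))
  if (length(miss))
    abort(paste("domain map is missing domain(s):", paste(miss, collapse = ", ")),
          "validation_error")
  parsed <- lapply(names(domains), function(d) parse_ranges(domains[[d]], d))
  names(parsed) <- names(domains)

  for (d in names(parsed)) {
    r <- expand_ranges(parsed[[d]])
    if (anyDuplicated(r))
      abort(sprintf("overlapping ranges within domain %s (residue %d)",
                    d, r[duplicated(r)][1]), "validation_error")
  }
  core <- lapply(parsed[CORE_DOMAINS], expand_ranges)
  all_res <- unlist(core)
  if (anyDuplicated(all_res)) {
    dup <- all_res[duplicated(all_res)][1]
    owners <- CORE_DOMAINS[vapply(core, function(r) dup %in% r, logical(1))]
    abort(sprintf("domains %s overlap at residue %d",
                  paste(owners, collapse = " and "), dup), "validation_error")
  }
  structure(list(domains = parsed), class = "domain_map")
}

parse_ranges <- function(x, dom) {
  if (is.data.frame(x) && all(c("start", "end") %in% names(x))) {
    rg <- x[c("start", "end")]
  } else {
    if (is.matrix(x)) x <- split(x, row(x))
    if (!is.list(x)) x <- list(x)
    rows <- lapply(x, function(r) {
      if (is.list(r)) r <- unlist(r)
      if (is.character(r) && length(r) == 1L) {
        r <- as.numeric(strsplit(r, "[:-]")[[1]])
      }
      if (!is.numeric(r) || length(r) != 2L || anyNA(r))
        abort(sprintf("domain %s: each range must be two integers", dom),
              "validation_error")
      r
    })
    rg <- data.frame(start = vapply(rows, `[`, 0, 1),
                     end = vapply(rows, `[`, 0, 2))
  }
  rg$start <- as.integer(rg$start); rg$end <- as.integer(rg$end)
  bad <- rg$start > rg$end
  if (any(bad))
    abort(sprintf("domain %s: range start %d > end %d", dom,
                  rg$start[bad][1], rg$end[bad][1]), "validation_error")
  rg
}

expand_ranges <- function(rg) unlist(mapply(seq, rg$start, rg$end, SIMPLIFY = FALSE))

#' Load a domain map from a YAML (or JSON) config file
#'
#' Expected layout:
#' ```yaml
#' domains:
#'   N:  [[360, 600]]
#'   P:  [[330, 359], [601, 739]]
#'   A:  [[1, 43], [124, 242]]
#'   TM: [[44, 123], [243, 329], [740, 994]]
#' ```
#' Ranges may also be written as strings `"360-600"`.
#'
#' @param path config file.
#' @return A `"domain_map"`.
#' @export
load_domain_map <- function(path) {
  cfg <- read_config_file(path)
  if (is.null(cfg$domains))
    abort(sprintf("'%s' has no top-level 'domains' key", path), "validation_error")
  domain_map(cfg$domains)
}

read_config_file <- function(path) {
  if (!file.exists(path)) abort(sprintf("file '%s' not found", path), "io_error")
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else
    yaml::read_yaml(path)
}

#' Attach a domain map to a topology
#'
#' Domain residues absent from the topology are allowed but recorded in the
#' `missing_resids` attribute.
#'
#' @param topology a topology (or structure/trajectory, modified in place and
#'   returned).
#' @param map a `"domain_map"` or path to one.
#' @return The input with `$domain_map` set.
#' @export
attach_domain_map <- function(topology, map) {
  if (is.character(map)) map <- load_domain_map(map)
  if (!inherits(map, "domain_map"))
    abort("'map' must be a domain_map or file path", "parameter_error")
  target <- topology
  top <- if (inherits(topology, c("trajectory", "mdstructure")))
    topology$topology else topology
  mapped <- unlist(lapply(map$domains[CORE_DOMAINS], expand_ranges))
  attr(map, "missing_resids") <- setdiff(mapped, unique(top$atoms$resid))
  top$domain_map <- map
  if (inherits(target, c("trajectory", "mdstructure"))) {
    target$topology <- top
    return(target)
  }
  top
}

#' @export
print.domain_map <- function(x, ...) {
  cat("<domain_map>\n")
  for (d in names(x$domains)) {
    rg <- x$domains[[d]]
    cat(sprintf("  %-3s %s\n", d,
                paste(sprintf("%d-%d", rg$start, rg$end), collapse = ", ")))
  }
  invisible(x)
}

#' Default SERCA1a domain map shipped with the package
#'
#' Approximate block partition of SERCA1a author numbering into A, N, P and
#' TM regions.  The exact boundaries are a documented package default, not a
#' published partition.
#'
#' @return A `"domain_map"`.
#' @export
default_serca_domain_map <- function() {
  load_domain_map(system.file("extdata", "serca_domain_map.yaml",
                              package = "iontraj", mustWork = TRUE))
}
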