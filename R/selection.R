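# Atom selection language.  Grammar (case-insensitive keywords):
#
#   expr    := term ( "or" term )*
#   term    := factor ( "and" factor )*
#   factor  := "not" factor | "(" expr ")" | primary
#   primary := "resid"   (N | N:M)+
#            | "resname" TOKEN+ | "name" TOKEN+ | "element" TOKEN+
#            | "chain" TOKEN+ | "domain" TOKEN+
#            | "backbone" | "protein" | "water" | "ion" | "all"
#
# Results are deterministic, order-preserving atom index lists.

BACKBONE_NAMES <- c("N", "CA", "C", "O")
AMINO_RESNAMES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                    "HIS", "HSD", "HSE", "HSP", "ILE", "LEU", "LYS", "MET",
                    "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

sel_tokenize <- function(expr) {
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, expr)[[1]]
  if (m[1] == -1) abort("empty selection expression", "selection_parse_error")
  data.frame(text = regmatches(expr, gregexpr(pat, expr))[[1]],
             pos = as.integer(m), stringsAsFactors = FALSE)
}

SEL_KEYWORDS <- c("and", "or", "not", "(", ")", "resid", "resname", "name",
                  "element", "chain", "domain", "backbone", "protein",
                  "water", "ion", "all")

#' Select atoms with a selection expression
#'
#' Small boolean selection language over residue number, residue name, atom
#' name, element, chain, domain membership and the convenience classes
#' `backbone` (N, CA, C, O), `protein`, `water`, `ion` and `all`.  Examples:
#' `"resid 771 and name OE1"`, `"domain TM and backbone"`,
#' `"resid 55 58 59 109"`, `"resid 330:359 and not name CA"`.
#'
#' @param topology a [topology()] (a structure or trajectory is also accepted).
#' @param expr selection expression string, or an integer index vector which
#'   is validated and returned as-is.
#' @return Increasing integer vector of atom indices (possibly empty).
#' @export
select_atoms <- function(topology, expr) {
  if (inherits(topology, c("trajectory", "mdstructure")))
    topology <- topology$topology
  if (is.numeric(expr)) {
    idx <- as.integer(expr)
    if (any(idx < 1 | idx > n_atoms(topology)))
      abort("atom index out of range", "selection_error")
    return(idx)
  }
  if (!is_string(expr)) abort("selection must be a string or index vector",
                              "selection_parse_error")
  toks <- sel_tokenize(expr)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$i <- 1L; st$top <- topology; st$expr <- expr
  mask <- sel_expr(st)
  if (st$i <= nrow(st$toks))
    sel_fail(st, sprintf("unexpected token '%s'", st$toks$text[st$i]))
  which(mask)
}

sel_fail <- function(st, msg) {
  pos <- if (st$i <= nrow(st$toks)) st$toks$pos[st$i] else nchar(st$expr) + 1L
  abort(sprintf("selection parse error at position %d: %s", pos, msg),
        "selection_parse_error")
}

sel_peek <- function(st) if (st$i <= nrow(st$toks)) tolower(st$toks$text[st$i]) else ""
sel_next <- function(st) { t <- st$toks$text[st$i]; st$i <- st$i + 1L; t }

sel_expr <- function(st) {
  m <- sel_term(st)
  while (sel_peek(st) == "or") { sel_next(st); m <- m | sel_term(st) }
  m
}

sel_term <- function(st) {
  m <- sel_factor(st)
  while (sel_peek(st) == "and") { sel_next(st); m <- m & sel_factor(st) }
  m
}

sel_factor <- function(st) {
  tok <- sel_peek(st)
  if (tok == "") sel_fail(st, "unexpected end of expression")
  if (tok == "not") { sel_next(st); return(!sel_factor(st)) }
  if (tok == "(") {
    sel_next(st)
    m <- sel_expr(st)
    if (sel_peek(st) != ")") sel_fail(st, "expected ')'")
    sel_next(st)
    return(m)
  }
  sel_primary(st)
}

sel_values <- function(st, kw) {
  vals <- character()
  while (st$i <= nrow(st$toks) && !(tolower(st$toks$text[st$i]) %in% SEL_KEYWORDS))
    vals <- c(vals, sel_next(st))
  if (!length(vals)) sel_fail(st, sprintf("'%s' needs at least one value", kw))
  vals
}

sel_primary <- function(st) {
  at <- st$top$atoms
  kw <- sel_peek(st)
  switch(kw,
    "all"      = { sel_next(st); rep(TRUE, nrow(at)) },
    "backbone" = { sel_next(st); at$name %in% BACKBONE_NAMES &
                                 at$resname %in% AMINO_RESNAMES },
    "protein"  = { sel_next(st); at$resname %in% AMINO_RESNAMES },
    "water"    = { sel_next(st); at$resname %in% WATER_RESNAMES },
    "ion"      = { sel_next(st); seq_len(nrow(at)) %in% st$top$ion_atoms$index },
    "resid"    = { sel_next(st); at$resid %in% sel_resid_values(st) },
    "resname"  = { sel_next(st); at$resname %in% toupper(sel_values(st, kw)) },
    "name"     = { sel_next(st); at$name %in% toupper(sel_values(st, kw)) },
    "element"  = { sel_next(st); at$element %in% toupper(sel_values(st, kw)) },
    "chain"    = { sel_next(st); at$chain %in% sel_values(st, kw) },
    "domain"   = { sel_next(st); at$resid %in% sel_domain_resids(st, sel_values(st, kw)) },
    sel_fail(st, sprintf("unknown keyword '%s'", kw))
  )
}

sel_resid_values <- function(st) {
  vals <- sel_values(st, "resid")
  out <- integer()
  for (v in vals) {
    if (grepl("^-?[0-9]+[:|-][0-9]+$", v)) {
      ab <- as.integer(strsplit(v, "[:|-]")[[1]])
      out <- c(out, ab[1]:ab[2])
    } else if (grepl("^-?[0-9]+$", v)) {
      out <- c(out, as.integer(v))
    } else sel_fail(st, sprintf("'%s' is not a residue number or range", v))
  }
  out
}

sel_domain_resids <- function(st, domains) {
  dm <- st$top$domain_map
  if (is.null(dm))
    abort("selection uses 'domain' but no domain map is attached", "selection_error")
  out <- integer()
  for (d in toupper(domains)) {
    if (is.null(dm$domains[[d]]))
      abort(sprintf("domain '%s' not present in domain map", d), "selection_error")
    rg <- dm$domains[[d]]
    out <- c(out, unlist(mapply(seq, rg$start, rg$end, SIMPLIFY = FALSE)))
  }
  out
}

# Resolve a selection that must identify exactly one atom.
select_one <- function(topology, expr, what = "selection") {
  idx <- select_atoms(topology, expr)
  if (length(idx) != 1L)
    abort(sprintf("%s '%s' resolves to %d atoms, expected exactly 1",
                  what, if (is.character(expr)) expr else "index",
                  length(idx)), "cardinality_error")
  idx
}
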