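# Internal helpers shared across modules.  All coordinates are nm, all times
# are microseconds; PDB Angstroms are converted at the file boundary only.

ANGSTROM_PER_NM <- 10

`%||%` <- function(a, b) if (is.null(a)) b else a

abort <- function(msg, class) {
  stop(structure(class = c(class, "iontraj_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

check_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("'%s' must be a single finite number", name), "parameter_error")
  if (positive && x <= 0)
    abort(sprintf("'%s' must be > 0", name), "parameter_error")
  invisible(x)
}

# Mean of a normal truncated above (X < b) or below (X > a); used by the
# synthetic generators to state exact ground-truth expectations.
truncnorm_mean <- function(mu, sd, upper = NULL, lower = NULL) {
  if (!is.null(upper)) {
    z <- (upper - mu) / sd
    return(mu - sd * stats::dnorm(z) / stats::pnorm(z))
  }
  if (!is.null(lower)) {
    z <- (lower - mu) / sd
    return(mu + sd * stats::dnorm(z) / (1 - stats::pnorm(z)))
  }
  mu
}

# Exact inverse-CDF sampling of a one-sided truncated normal.
rtruncnorm1 <- function(n, mu, sd, upper = NULL, lower = NULL) {
  u <- stats::runif(n)
  if (!is.null(upper)) {
    p <- stats::pnorm(upper, mu, sd)
    out <- stats::qnorm(u * p, mu, sd)
    out[!is.finite(out)] <- upper  # truncation far in the tail: mass at bound
    return(pmin(out, upper))
  }
  if (!is.null(lower)) {
    p <- stats::pnorm(lower, mu, sd)
    out <- stats::qnorm(p + u * (1 - p), mu, sd)
    out[!is.finite(out)] <- lower
    return(pmax(out, lower))
  }
  stats::rnorm(n, mu, sd)
}

vec_norm <- function(v) sqrt(sum(v * v))

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Map degrees onto (-180, 180].
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}
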