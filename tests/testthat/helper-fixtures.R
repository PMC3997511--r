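# Shared fixture builders and independent oracles.  Fixtures are always
# generated in code; nothing binary is stored.

# -- quick topology/trajectory builders --------------------------------------

make_atoms <- function(name, resname, resid, element = NULL, chain = "A",
                       record = "ATOM") {
  n <- max(length(name), length(resname), length(resid))
  data.frame(serial = seq_len(n), name = name,
             element = element %||% substr(name, 1, 1), resname = resname,
             resid = resid, chain = chain, altloc = "", record = record,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_traj <- function(atoms, coords_list, frame_dt = 0.01) {
  atoms$serial <- seq_len(nrow(atoms))  # rbind-ed fixtures get fresh serials
  arr <- array(0, c(nrow(atoms), 3, length(coords_list)))
  for (k in seq_along(coords_list)) arr[, , k] <- coords_list[[k]]
  trajectory(topology(atoms), arr, (seq_along(coords_list) - 1) * frame_dt)
}

# Hand-written 3-atom PDB (one MG HETATM) used by the structio tests.
write_tiny_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  CA  GLU A 771       2.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  OE1 GLU A 771       1.500   1.000   0.000  1.00  0.00           O",
    "HETATM    3 MG    MG A9100       0.000   0.000   0.500  1.00  0.00          MG",
    "END"), path)
  path
}

# altloc fixture: one atom with A/B locations plus two plain atoms.
write_altloc_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  CA  GLU A 771       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB AGLU A 771       2.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CB BGLU A 771       2.200   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CG  GLU A 771       3.000   0.000   0.000  1.00  0.00           C",
    "END"), path)
  path
}

# -- independent oracles -----------------------------------------------------

# Quaternion-search superposition RMSD: coarse random-quaternion grid plus
# Nelder-Mead polish over rotation vectors.  Never uses the SVD route.
quat_rmsd_oracle <- function(A, B, n_grid = 4000, seed = 99) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  rot_from_quat <- function(q) {
    q <- q / sqrt(sum(q^2)); w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
          c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
          c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
  }
  obj_rot <- function(R) sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  rot_from_vec <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    k <- v / th
    K <- rbind(c(0, -k[3], k[2]), c(k[3], 0, -k[1]), c(-k[2], k[1], 0))
    diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  }
  if (!exists(".Random.seed", envir = globalenv())) set.seed(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  qs <- matrix(stats::rnorm(4 * n_grid), n_grid, 4)
  vals <- apply(qs, 1, function(q) obj_rot(rot_from_quat(q)))
  best <- order(vals)[1:3]
  quat_to_vec <- function(q) {
    q <- q / sqrt(sum(q^2)); if (q[1] < 0) q <- -q
    th <- 2 * acos(pmin(1, q[1]))
    s <- sqrt(max(1 - q[1]^2, 1e-16))
    th * q[2:4] / s
  }
  res <- vapply(best, function(b) {
    stats::optim(quat_to_vec(qs[b, ]), function(v) obj_rot(rot_from_vec(v)),
                 method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))$value
  }, numeric(1))
  min(res)
}

# Independent torsion formula (acos magnitude + separate sign), used to
# cross-check dihedral_angle.
torsion_oracle <- function(p1, p2, p3, p4) {
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  s <- sign(sum(cr(n1, n2) * b2))
  out <- if (s < 0) -ang else ang
  if (out <= -180) out + 360 else out
}

# Brute-force selection oracle: per-atom predicate scan.
brute_select <- function(top, pred) which(vapply(seq_len(nrow(top$atoms)),
                                                 pred, logical(1)))

# Synthetic stand-ins for the open (1su4-like) and compact (1vfp-like)
# crystal references, which cannot be downloaded in this environment.
# Geometry is constructed so the D800-E908 convention distance (CG of D800
# to OE2 of E908) is 0.66 / 0.68 nm; they exercise the measurement
# machinery, not real crystal coordinates.
synthetic_crystal_structure <- function(which = c("open", "compact")) {
  which <- match.arg(which)
  d <- if (which == "open") 0.66 else 0.68
  atoms <- make_atoms(name = c("CB", "CG", "OD1", "OD2", "CD", "OE1", "OE2"),
                      resname = c(rep("ASP", 4), rep("GLU", 3)),
                      resid = c(rep(800L, 4), rep(908L, 3)),
                      element = c("C", "C", "O", "O", "C", "O", "O"))
  coords <- rbind(c(-0.15, 0, 0), c(0, 0, 0), c(0.06, 0.11, 0),
                  c(0.06, -0.11, 0),
                  c(d + 0.12, 0, 0), c(d + 0.18, 0.10, 0), c(d, 0, 0))
  iontraj:::structure_frame(topology(atoms), coords)
}
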