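# Optimal rigid-body superposition (Kabsch, SVD route, reflections excluded).

#' Least-squares rigid superposition of two point sets
#'
#' Finds the proper rotation `R` (det = +1) and translation `t` minimising
#' the RMSD between `mobile %*% t(R) + t` and `reference`.
#'
#' @param mobile,reference `n x 3` coordinate matrices (nm), `n >= 3`,
#'   not all collinear.
#' @return List of class `"rigid_transform"` with elements `rotation`
#'   (3x3), `translation` (length 3, nm) and `rmsd` (nm).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L)
    abort("point sets must be equal-sized n x 3 matrices", "parameter_error")
  n <- nrow(mobile)
  if (n < 3L) abort("superposition needs at least 3 points", "degenerate_geometry_error")

  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  if (qr(A)$rank < 2L || qr(B)$rank < 2L)
    abort("points are collinear; rotation is underdetermined",
          "degenerate_geometry_error")

  H <- crossprod(A, B)                      # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)  # acts on column vectors
  tr <- as.numeric(cr - R %*% cm)
  fitted <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param coords `n x 3` matrix (nm).
#' @param transform a `"rigid_transform"`.
#' @return Transformed `n x 3` matrix.
#' @export
apply_transform <- function(coords, transform) {
  sweep(as.matrix(coords) %*% t(transform$rotation), 2,
        transform$translation, `+`)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rmsd = %.5f nm\n", x$rmsd))
  invisible(x)
}

rmsd_between <- function(a, b) sqrt(mean(rowSums((a - b)^2)))
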