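#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising the RMSD
#' between corresponding points, `||(A R + t) - B||`, by SVD of the
#' cross-covariance matrix with the usual determinant correction so that the
#' returned rotation is always proper (`det(R) = +1`, no reflection).
#'
#' @param A,B Numeric n x 3 matrices of corresponding coordinates (n >= 3);
#'   the correspondence is row order. `A` is moved onto `B`.
#' @return A list with `R` (3 x 3 rotation applied on the right of row-vector
#'   coordinates), `t` (length-3 translation), `rmsd` (residual in the same
#'   units as the input) and `transform(x)`, a function applying the fit to
#'   any n x 3 matrix.
#' @export
#' @examples
#' A <- matrix(rnorm(51), ncol = 3)
#' superpose(A, A)$rmsd   # 0
superpose <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!is.numeric(A) || !is.numeric(B) || ncol(A) != 3L || ncol(B) != 3L)
    stop("superpose: inputs must be numeric n x 3 matrices")
  if (nrow(A) != nrow(B))
    stop("superpose: length mismatch (", nrow(A), " vs ", nrow(B), " points)")
  if (nrow(A) < 3L) stop("superpose: need at least 3 points")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- crossprod(A0, B0)              # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)           # row-vector convention: x %*% R
  t <- cb - drop(ca %*% R)
  fitted <- sweep(A %*% R, 2, t, "+")
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(R = R, t = t, rmsd = rmsd,
       transform = function(x) sweep(as.matrix(x) %*% R, 2, t, "+"))
}

#' Rotation angle of a 3 x 3 rotation matrix
#'
#' @param R A proper rotation matrix.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
rotation_angle <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, ct))) * 180 / pi
}

#' Root-mean-square deviation between two coordinate sets
#'
#' Computed as-is (no fitting); use [superpose()] first for the
#' least-squares-aligned value.
#'
#' @param A,B Numeric n x 3 matrices.
#' @return RMSD in input units.
#' @export
rmsd_raw <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(all(dim(A) == dim(B)))
  sqrt(mean(rowSums((A - B)^2)))
}

# rotation matrix about a unit axis (row-vector convention, x %*% R)
rotation_about <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  Rm <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  t(Rm)   # transpose: column convention -> row convention
}
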