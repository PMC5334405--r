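# Rigid-body geometry: Euler rotations and least-squares superposition.

#' Rotation matrix for z-y-z intrinsic Euler angles
#'
#' Angles in degrees: first rotate by `alpha` about z, then `beta` about the
#' new y, then `gamma` about the new z (intrinsic z-y-z, equivalently
#' `Rz(alpha) %*% Ry(beta) %*% Rz(gamma)` as extrinsic matrices).
#'
#' @param alpha,beta,gamma Angles in degrees; `beta` in \[0, 180\].
#' @return 3 x 3 proper rotation matrix.
#' @export
euler_matrix <- function(alpha, beta, gamma) {
  d2r <- pi / 180
  a <- alpha * d2r; b <- beta * d2r; g <- gamma * d2r
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  rz(a) %*% ry(b) %*% rz(g)
}

#' Rotate a structure about its centroid by Euler angles
#'
#' z-y-z intrinsic convention, degrees. The centroid is unchanged.
#'
#' @param s An `rpc_structure`.
#' @param angles Numeric length-3 vector `(alpha, beta, gamma)` in degrees.
#' @return The rotated structure.
#' @export
rotate_euler <- function(s, angles) {
  stopifnot(length(angles) == 3, all(is.finite(angles)))
  if (n_atoms(s) == 0) stop("empty structure")
  R <- euler_matrix(angles[1], angles[2], angles[3])
  xyz <- coords(s)
  c0 <- colMeans(xyz)
  out <- sweep(xyz, 2, c0) %*% t(R)
  out <- sweep(out, 2, c0, "+")
  set_coords(s, out)
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation `U` and translation `t` minimizing the RMSD of
#' `P %*% t(U) + t` against `Q` (i.e. superposes `P` onto `Q`), via SVD of
#' the covariance matrix with determinant sign correction.
#'
#' @param P,Q k x 3 coordinate matrices, k >= 3.
#' @return List with `rotation` (3 x 3, det +1), `translation` (length 3),
#'   and `rmsd` (Angstrom).
#' @export
kabsch_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q) || ncol(P) != 3 || ncol(Q) != 3) {
    stop("P and Q must be k x 3 matrices of equal size")
  }
  if (nrow(P) < 3) stop("need at least 3 points for superposition")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- t(P0) %*% Q0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  U <- sv$v %*% D %*% t(sv$u)
  fitted <- P0 %*% t(U)
  rmsd <- sqrt(mean(rowSums((fitted - Q0)^2)))
  list(rotation = U, translation = as.numeric(cq - U %*% cp), rmsd = rmsd)
}

#' RMSD between two coordinate sets without superposition
#' @param P,Q k x 3 matrices.
#' @return Root-mean-square deviation in Angstrom.
#' @export
rmsd_raw <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q))
  sqrt(mean(rowSums((as.matrix(P) - as.matrix(Q))^2)))
}

#' Apply a rigid transform to a coordinate matrix
#' @param xyz k x 3 matrix.
#' @param rotation 3 x 3 matrix.
#' @param translation length-3 vector.
#' @return Transformed k x 3 matrix.
#' @export
apply_transform <- function(xyz, rotation, translation = c(0, 0, 0)) {
  sweep(as.matrix(xyz) %*% t(rotation), 2, translation, "+")
}
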