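#' Rigid-body transforms
#'
#' Rotations follow the intrinsic z-y-z Euler convention: a rotation by
#' `phi` about z, then `theta` about the new y, then `psi` about the newest
#' z. All angles are in degrees. A `rigid_transform` applies
#' `x' = R (x - center) + center + t`, i.e. rotation about a chosen pivot
#' followed by a translation.
#'
#' @param phi,theta,psi Euler angles in degrees (z-y-z intrinsic).
#' @return `euler_to_matrix`: a 3x3 rotation matrix.
#' @export
euler_to_matrix <- function(phi, theta, psi) {
  rz <- function(a) {
    a <- a * pi / 180
    matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  }
  ry <- function(a) {
    a <- a * pi / 180
    matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  }
  rz(phi) %*% ry(theta) %*% rz(psi)
}

#' @rdname euler_to_matrix
#' @param R a 3x3 rotation matrix.
#' @return `matrix_to_euler`: named vector `c(phi, theta, psi)` in degrees.
#' @export
matrix_to_euler <- function(R) {
  ct <- max(-1, min(1, R[3, 3]))
  theta <- acos(ct)
  if (abs(sin(theta)) > 1e-9) {
    phi <- atan2(R[2, 3], R[1, 3])
    psi <- atan2(R[3, 2], -R[3, 1])
  } else {
    # gimbal: only phi + psi (theta = 0) or phi - psi (theta = 180) defined
    phi <- atan2(R[2, 1], R[1, 1])
    if (ct < 0) phi <- -phi
    psi <- 0
  }
  c(phi = phi, theta = theta, psi = psi) * 180 / pi
}

#' Rotation about an arbitrary axis
#'
#' @param axis unit (or any nonzero) direction vector.
#' @param angle rotation angle in degrees.
#' @return 3x3 rotation matrix (Rodrigues formula).
#' @export
axis_angle_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  a <- angle * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' @rdname euler_to_matrix
#' @param t translation, length 3 (Angstrom).
#' @param center pivot of the rotation, length 3.
#' @export
rigid_transform <- function(phi = 0, theta = 0, psi = 0, t = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  structure(list(R = euler_to_matrix(phi, theta, psi),
                 euler = c(phi = phi, theta = theta, psi = psi),
                 t = as.numeric(t), center = as.numeric(center)),
            class = "rigid_transform")
}

#' Apply a rigid transform to a model or coordinate matrix
#'
#' @param x an [atomic_model], bead model, or n x 3 matrix.
#' @param tr a `rigid_transform`, or a 3x3 rotation matrix (with `t` and
#'   `center` given separately).
#' @param t,center used when `tr` is a bare rotation matrix.
#' @return Object of the same type with transformed coordinates.
#' @export
apply_transform <- function(x, tr, t = c(0, 0, 0), center = c(0, 0, 0)) {
  if (inherits(tr, "rigid_transform")) {
    R <- tr$R; t <- tr$t; center <- tr$center
  } else R <- tr
  if (is.matrix(x) && !is.data.frame(x)) {
    xc <- sweep(x, 2, center)
    return(sweep(xc %*% t(R), 2, center + t, "+"))
  }
  xyz <- apply_transform(coords(x), R, t = t, center = center)
  x$x <- xyz[, 1]; x$y <- xyz[, 2]; x$z <- xyz[, 3]
  x
}

#' Geodesic angle between two rotations
#'
#' @param R1,R2 3x3 rotation matrices.
#' @return Angle in degrees of the rotation `R1 %*% t(R2)`.
#' @export
rotation_angle <- function(R1, R2 = diag(3)) {
  tr <- sum(diag(R1 %*% t(R2)))
  acos(max(-1, min(1, (tr - 1) / 2))) * 180 / pi
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the rotation `R` and translation `t` minimizing
#' `sum ||R x_i + t - y_i||^2`, with a reflection guard so `det(R) = +1`.
#'
#' @param x,y n x 3 matrices of paired coordinates (x is moved onto y).
#' @return List with `R`, `t`, and `rmsd` after superposition.
#' @export
kabsch <- function(x, y) {
  stopifnot(nrow(x) == nrow(y), ncol(x) == 3, ncol(y) == 3)
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  s <- svd(t(xc) %*% yc)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cy - as.vector(R %*% cx)
  fit <- sweep(xc %*% t(R), 2, cy, "+")
  list(R = R, t = t, rmsd = sqrt(mean(rowSums((fit - y)^2))))
}

#' Rotation matrix from a rotation vector
#'
#' The rotation vector `v` (degrees) encodes a rotation by `|v|` degrees
#' about the axis `v / |v|`; the zero vector gives the identity. Unlike
#' Euler angles, the three components stay independent near the identity,
#' which makes this the parametrization of choice for local refinement.
#'
#' @param v numeric length-3 rotation vector in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotvec_matrix <- function(v) {
  ang <- sqrt(sum(v^2))
  if (ang < 1e-12) return(diag(3))
  axis_angle_matrix(v / ang, ang)
}
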