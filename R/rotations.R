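# Rotation algebra: Euler angles (degrees), rotation matrices, quaternions
# and axis-angle vectors. Euler conventions are intrinsic and named by the
# order in which the elementary rotations are composed, e.g. "ZXY" means
# R = Rz(a1) %*% Rx(a2) %*% Ry(a3) with (a1, a2, a3) the stored angles.

.axis_rotation <- function(axis, theta) {
  c <- cos(theta); s <- sin(theta)
  switch(axis,
    X = matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3),
    Y = matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3),
    Z = matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3),
    stop("invalid rotation axis: ", axis)
  )
}

.check_order <- function(order) {
  if (!is.character(order) || nchar(order) != 3L ||
      !all(strsplit(order, "")[[1]] %in% c("X", "Y", "Z"))) {
    stop("invalid Euler order label: ", order)
  }
  strsplit(order, "")[[1]]
}

#' Euler angles to rotation matrix
#'
#' @param euler_deg Numeric length-3 vector of angles in degrees, one per
#'   letter of `order`.
#' @param order Euler convention label such as `"ZXY"`.
#' @return A 3x3 rotation matrix.
#' @export
euler_to_matrix <- function(euler_deg, order = "ZXY") {
  ax <- .check_order(order)
  th <- euler_deg * pi / 180
  .axis_rotation(ax[1], th[1]) %*%
    .axis_rotation(ax[2], th[2]) %*%
    .axis_rotation(ax[3], th[3])
}

#' Rotation matrix to ZXY Euler angles (degrees)
#'
#' Analytic decomposition R = Rz(z) Rx(x) Ry(y). The middle angle is taken
#' in [-90, 90]; gimbal-locked inputs resolve the free angle to the Z slot.
#' @param R A 3x3 rotation matrix.
#' @return Length-3 vector (z, x, y) in degrees.
#' @export
matrix_to_euler_zxy <- function(R) {
  sx <- clip(R[3, 2], -1, 1)
  x <- asin(sx)
  if (abs(sx) < 1 - 1e-10) {
    y <- atan2(-R[3, 1], R[3, 3])
    z <- atan2(-R[1, 2], R[2, 2])
  } else {
    # gimbal lock: only z +/- y is determined
    y <- 0
    z <- atan2(R[2, 1], R[1, 1])
  }
  c(z, x, y) * 180 / pi
}

#' Euler angles to unit quaternion, vectorized over rows
#'
#' @param euler_deg n x 3 matrix (or length-3 vector) of angles in degrees.
#' @param order Euler convention label.
#' @return n x 4 matrix of quaternions (w, x, y, z), scalar part first.
#' @export
euler_to_quaternion <- function(euler_deg, order = "ZXY") {
  ax <- .check_order(order)
  if (is.null(dim(euler_deg))) euler_deg <- matrix(euler_deg, nrow = 1)
  th <- euler_deg * pi / 360  # half angles in radians
  qs <- lapply(1:3, function(i) {
    w <- cos(th[, i]); s <- sin(th[, i])
    q <- matrix(0, nrow(th), 4)
    q[, 1] <- w
    q[, 1 + match(ax[i], c("X", "Y", "Z"))] <- s
    q
  })
  quat_multiply(quat_multiply(qs[[1]], qs[[2]]), qs[[3]])
}

#' Hamilton product of quaternion rows
#' @param a,b n x 4 matrices (w, x, y, z).
#' @keywords internal
quat_multiply <- function(a, b) {
  cbind(
    a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4],
    a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3],
    a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2],
    a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  )
}

#' Quaternion rows to axis-angle vectors
#'
#' The returned 3-vector is the unit rotation axis scaled by the rotation
#' angle in [0, pi] radians; the identity rotation maps to the zero vector.
#' @param q n x 4 matrix of unit quaternions.
#' @return n x 3 matrix of axis-angle vectors (radians * axis).
#' @export
quat_to_axis_angle <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1)
  # canonicalize to w >= 0 so the angle lands in [0, pi]
  flip <- q[, 1] < 0
  q[flip, ] <- -q[flip, , drop = FALSE]
  vnorm <- sqrt(rowSums(q[, 2:4, drop = FALSE]^2))
  angle <- 2 * atan2(vnorm, q[, 1])
  scale <- ifelse(vnorm > 1e-12, angle / vnorm, 0)
  q[, 2:4, drop = FALSE] * scale
}

#' Euler angles to axis-angle representation
#'
#' @inheritParams euler_to_quaternion
#' @return n x 3 matrix (or length-3 vector for vector input) of axis-angle
#'   vectors in radians * axis.
#' @export
euler_to_axis_angle <- function(euler_deg, order = "ZXY") {
  vec_in <- is.null(dim(euler_deg))
  aa <- quat_to_axis_angle(euler_to_quaternion(euler_deg, order))
  if (vec_in) drop(aa) else aa
}

#' Rotation matrix to axis-angle vector (oracle-friendly scalar path)
#' @param R 3x3 rotation matrix.
#' @return Length-3 axis-angle vector, angle in [0, pi].
#' @export
matrix_to_axis_angle <- function(R) {
  angle <- acos(clip((sum(diag(R)) - 1) / 2, -1, 1))
  if (angle < 1e-12) return(c(0, 0, 0))
  if (abs(angle - pi) < 1e-6) {
    # near pi: axis from the dominant column of R + I
    B <- (R + diag(3)) / 2
    axis <- sqrt(pmax(diag(B), 0))
    k <- which.max(axis)
    # fix signs from off-diagonal terms
    if (k == 1) axis <- c(axis[1], B[1, 2] / axis[1], B[1, 3] / axis[1])
    if (k == 2) axis <- c(B[1, 2] / axis[2], axis[2], B[2, 3] / axis[2])
    if (k == 3) axis <- c(B[1, 3] / axis[3], B[2, 3] / axis[3], axis[3])
    axis <- axis / sqrt(sum(axis^2))
    return(axis * angle)
  }
  axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(angle))
  axis * angle
}
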