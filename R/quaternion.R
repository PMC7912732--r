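# Unit-quaternion helpers for rigid-body orientations (w, x, y, z convention).
# Internal: all public types store orientations as length-4 unit vectors.

quat_identity <- function() c(1, 0, 0, 0)

quat_normalize <- function(q) q / sqrt(sum(q * q))

# rotation matrix from unit quaternion
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Hamilton product p * q (apply q first, then p)
quat_multiply <- function(p, q) {
  c(
    p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1]
  )
}

quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis * axis))
  s <- sin(angle / 2)
  c(cos(angle / 2), axis * s)
}

# Shoemake's uniform random rotation
quat_random <- function() {
  u <- stats::runif(3)
  c(
    sqrt(1 - u[1]) * sin(2 * pi * u[2]),
    sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]),
    sqrt(u[1]) * cos(2 * pi * u[3])
  )
}

# best-fit rotation (Kabsch, via SVD) mapping local coords onto centred
# observed coords; exact for rigid molecules, used when reading trajectories
quat_from_kabsch <- function(local, observed) {
  lc <- scale(local, scale = FALSE)
  oc <- scale(observed, scale = FALSE)
  h <- t(lc) %*% oc
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  r <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  matrix_to_quat(r)
}

matrix_to_quat <- function(r) {
  tr <- r[1, 1] + r[2, 2] + r[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (r[3, 2] - r[2, 3]) / s,
           (r[1, 3] - r[3, 1]) / s, (r[2, 1] - r[1, 2]) / s)
  } else if (r[1, 1] > r[2, 2] && r[1, 1] > r[3, 3]) {
    s <- sqrt(1 + r[1, 1] - r[2, 2] - r[3, 3]) * 2
    q <- c((r[3, 2] - r[2, 3]) / s, 0.25 * s,
           (r[1, 2] + r[2, 1]) / s, (r[1, 3] + r[3, 1]) / s)
  } else if (r[2, 2] > r[3, 3]) {
    s <- sqrt(1 + r[2, 2] - r[1, 1] - r[3, 3]) * 2
    q <- c((r[1, 3] - r[3, 1]) / s, (r[1, 2] + r[2, 1]) / s,
           0.25 * s, (r[2, 3] + r[3, 2]) / s)
  } else {
    s <- sqrt(1 + r[3, 3] - r[1, 1] - r[2, 2]) * 2
    q <- c((r[2, 1] - r[1, 2]) / s, (r[1, 3] + r[3, 1]) / s,
           (r[2, 3] + r[3, 2]) / s, 0.25 * s)
  }
  quat_normalize(q)
}
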