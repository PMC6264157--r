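# Small vector-geometry helpers shared across modules.

vnorm <- function(v) sqrt(sum(v * v))

unit_vector <- function(v, what = "vector") {
  n <- vnorm(v)
  if (n < 1e-8) stop("degenerate ", what, " (norm < 1e-8)")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# angle between two vectors, degrees in [0, 180]
vec_angle <- function(a, b) {
  ca <- sum(a * b) / (vnorm(a) * vnorm(b))
  acos(max(-1, min(1, ca))) * 180 / pi
}

# rotation matrix for angle (degrees) about unit axis u (Rodrigues)
rotation_matrix <- function(axis, angle_deg) {
  u <- unit_vector(axis, "rotation axis")
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# rotate points (n x 3) about an axis through `origin`
rotate_about <- function(xyz, axis, angle_deg, origin = c(0, 0, 0)) {
  R <- rotation_matrix(axis, angle_deg)
  sweep(sweep(xyz, 2, origin) %*% t(R), 2, origin, "+")
}

# a deterministic unit vector perpendicular to w
perp_vector <- function(w) {
  w <- unit_vector(w, "axis")
  ref <- if (abs(w[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  unit_vector(cross3(ref, w))
}

# dihedral angle (degrees, in (-180, 180]) of four points
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * unit_vector(b2))
  atan2(y, x) * 180 / pi
}
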