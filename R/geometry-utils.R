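# Small vector-geometry helpers shared by the builder and the analyzer.
# Coordinates are plain n x 3 matrices in Angstrom.

.unit <- function(v) v / sqrt(sum(v * v))

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rotation about z by theta (degrees), 3x3
.rot_z <- function(theta) {
  t <- theta * pi / 180
  matrix(c(cos(t), -sin(t), 0,
           sin(t),  cos(t), 0,
           0,       0,      1), 3, 3, byrow = TRUE)
}

# 180 degree rotation about x: used to flip a base/residue onto the
# complementary strand (y -> -y, z -> -z).
.rot180_x <- diag(c(1, -1, -1))

# Apply rotation R then translation t to an n x 3 coordinate block.
.xform <- function(xyz, R, t = c(0, 0, 0)) {
  sweep(xyz %*% t(R), 2, -t)
}

# Signed dihedral angle (degrees) of the ordered quadruple p1-p2-p3-p4.
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  m1 <- .cross(n1, .unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Interior angle (degrees) at p2 of p1-p2-p3.
.angle3 <- function(p1, p2, p3) {
  a <- .unit(p1 - p2)
  b <- .unit(p3 - p2)
  acos(max(-1, min(1, sum(a * b)))) * 180 / pi
}

# Kabsch superposition: least-squares rotation (no reflection) and
# translation mapping x onto y (both n x 3).  Returns R, t and the RMSD,
# with y ~ x %*% t(R) + t.
.kabsch <- function(x, y) {
  stopifnot(nrow(x) == nrow(y), nrow(x) >= 3)
  cx <- colMeans(x)
  cy <- colMeans(y)
  x0 <- sweep(x, 2, cx)
  y0 <- sweep(y, 2, cy)
  s <- svd(crossprod(x0, y0))            # X' Y = U D V'
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- unname(cy - as.vector(R %*% cx))
  fit <- sweep(x0 %*% t(R), 2, -cy)
  rmsd <- sqrt(mean(rowSums((fit - y)^2)))
  list(R = R, t = t, rmsd = rmsd)
}

# Nearest rotation matrix to an arbitrary 3x3 (polar projection).
.nearest_rotation <- function(M) {
  s <- svd(M)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

# Regular n-gon with side length `side`, counterclockwise in the xy plane,
# centred on the origin; returns n x 2.
.regular_ring2d <- function(n, side) {
  R <- side / (2 * sin(pi / n))
  ang <- (seq_len(n) - 1) * 2 * pi / n
  cbind(R * cos(ang), R * sin(ang))
}

# Regular n-gon sharing the directed edge p -> q (2d points); remaining
# vertices are laid out by turning `turn_sign` * exterior angle at each
# step.  Returns the full vertex list starting at p.
.fused_ring2d <- function(p, q, n, turn_sign = 1) {
  side <- sqrt(sum((q - p)^2))
  ext <- turn_sign * 2 * pi / n
  rot <- function(v, a) c(cos(a) * v[1] - sin(a) * v[2],
                          sin(a) * v[1] + cos(a) * v[2])
  verts <- matrix(0, n, 2)
  verts[1, ] <- p
  verts[2, ] <- q
  d <- (q - p) / side
  for (k in 3:n) {
    d <- rot(d, ext)
    verts[k, ] <- verts[k - 1, ] + side * d
  }
  verts
}
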