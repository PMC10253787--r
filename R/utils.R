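# Internal geometry helpers shared across modules.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

rot_x <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
rot_y <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
rot_z <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

# xyz flat vector (x1,y1,z1,x2,...) <-> n x 3 matrix
vec2mat <- function(xyz) matrix(xyz, ncol = 3, byrow = TRUE)
mat2vec <- function(m) as.numeric(t(m))

# flat-vector indices for atom indices
xyz_ind <- function(atom_inds) {
  as.vector(rbind(3 * atom_inds - 2, 3 * atom_inds - 1, 3 * atom_inds))
}

# Dihedral angle (degrees, in (-180, 180]) of four points; each argument is
# either a 3-vector or an n x 3 matrix of per-frame positions.
dihedral_angle <- function(p1, p2, p3, p4) {
  as_m <- function(p) if (is.matrix(p)) p else matrix(p, 1, 3)
  p1 <- as_m(p1); p2 <- as_m(p2); p3 <- as_m(p3); p4 <- as_m(p4)
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  cross <- function(a, b) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  }
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  m1 <- cross(n1, b2 / sqrt(rowSums(b2^2)))
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  # IUPAC sign convention (matches bio3d::torsion.xyz)
  ang <- -rad2deg(atan2(y, x))
  ang[ang <= -180] <- ang[ang <= -180] + 360
  ang
}

# wrap angle in degrees to (-180, 180]
wrap180 <- function(x) {
  out <- (x + 180) %% 360 - 180
  out[out == -180] <- 180
  out
}
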