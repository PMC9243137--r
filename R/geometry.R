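# Low-level 3D geometry shared by the superposition, rotamer and pore code.
# Angles in degrees, coordinates in Angstrom, right-handed axes.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

vnorm <- function(v) sqrt(sum(v^2))
unit <- function(v) v / vnorm(v)

# Rotation matrix for angle `deg` about unit axis `u` (Rodrigues).
rotation_about <- function(u, deg) {
  u <- unit(u)
  th <- deg2rad(deg)
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %*% t(u))
}

# Signed dihedral a-b-c-d in (-180, 180], IUPAC convention.
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- -rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  if (ang > 180) ang <- ang - 360
  ang
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Place atom D given positions A, B, C, bond length |CD|, angle B-C-D (deg)
# and dihedral A-B-C-D (deg).  Standard internal-coordinate (NeRF) step.
place_atom <- function(a, b, c, bond, angle, dihedral) {
  th <- deg2rad(angle); ph <- deg2rad(dihedral)
  bc <- unit(c - b)
  n <- unit(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Apply a rigid transform (3x3 rotation R, translation t) to an n x 3 matrix.
transform_xyz <- function(xyz, R, t = c(0, 0, 0)) {
  sweep(xyz %*% t(R), 2, t, FUN = "+")
}
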