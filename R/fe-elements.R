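# Element-level matrices for the linear-elastic core.
# Units: mm, N, MPa; displacements mm, rotations rad.

# 6x6 isotropic elasticity matrix, engineering shear convention
iso_D <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

# trilinear hexahedron shape-function derivative matrix (6 x 24) at natural
# coordinates (xi, eta, zeta) for a cube of edge h; VTK node ordering
.hex_signs <- rbind(
  c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
  c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1)
)

hex_B <- function(xi, eta, zeta, h) {
  s <- .hex_signs
  # dN/dxi etc., then scale by inverse Jacobian 2/h
  dN <- cbind(
    s[, 1] * (1 + s[, 2] * eta) * (1 + s[, 3] * zeta),
    s[, 2] * (1 + s[, 1] * xi) * (1 + s[, 3] * zeta),
    s[, 3] * (1 + s[, 1] * xi) * (1 + s[, 2] * eta)
  ) / 8 * (2 / h)
  B <- matrix(0, 6, 24)
  ix <- seq(1, 24, by = 3)
  B[1, ix] <- dN[, 1]
  B[2, ix + 1] <- dN[, 2]
  B[3, ix + 2] <- dN[, 3]
  B[4, ix] <- dN[, 2]; B[4, ix + 1] <- dN[, 1]
  B[5, ix + 1] <- dN[, 3]; B[5, ix + 2] <- dN[, 2]
  B[6, ix] <- dN[, 3]; B[6, ix + 2] <- dN[, 1]
  B
}

# 24x24 stiffness of a cube voxel element, 2x2x2 Gauss integration
hex_stiffness <- function(E, nu, h) {
  D <- iso_D(E, nu)
  g <- 1 / sqrt(3)
  K <- matrix(0, 24, 24)
  detJ <- (h / 2)^3
  for (xi in c(-g, g)) for (eta in c(-g, g)) for (zeta in c(-g, g)) {
    B <- hex_B(xi, eta, zeta, h)
    K <- K + t(B) %*% D %*% B * detJ
  }
  (K + t(K)) / 2
}

# circular-section properties
beam_section <- function(d) {
  list(A = pi * d^2 / 4, I = pi * d^4 / 64, J = pi * d^4 / 32, c = d / 2)
}

# 12x12 local stiffness of a 3D two-node Timoshenko beam, circular section.
# DOF order per node: ux uy uz rx ry rz; local x along the axis.
beam_stiffness_local <- function(E, nu, d, L, shear_k = 0.9) {
  if (d <= 0) stop_invalid("beam diameter must be > 0")
  if (L <= 0) stop_invalid("beam length must be > 0")
  G <- E / (2 * (1 + nu))
  sec <- beam_section(d)
  A <- sec$A; I <- sec$I; J <- sec$J
  phi <- 12 * E * I / (shear_k * G * A * L^2)
  K <- matrix(0, 12, 12)
  # axial
  ka <- E * A / L
  K[c(1, 7), c(1, 7)] <- ka * matrix(c(1, -1, -1, 1), 2)
  # torsion
  kt <- G * J / L
  K[c(4, 10), c(4, 10)] <- kt * matrix(c(1, -1, -1, 1), 2)
  # bending in local x-y plane (v, theta_z)
  f <- E * I / ((1 + phi) * L^3)
  kb <- f * matrix(c(
    12, 6 * L, -12, 6 * L,
    6 * L, (4 + phi) * L^2, -6 * L, (2 - phi) * L^2,
    -12, -6 * L, 12, -6 * L,
    6 * L, (2 - phi) * L^2, -6 * L, (4 + phi) * L^2
  ), 4, 4, byrow = TRUE)
  idx <- c(2, 6, 8, 12)
  K[idx, idx] <- K[idx, idx] + kb
  # bending in local x-z plane (w, theta_y): mirrored signs
  kb2 <- f * matrix(c(
    12, -6 * L, -12, -6 * L,
    -6 * L, (4 + phi) * L^2, 6 * L, (2 - phi) * L^2,
    -12, 6 * L, 12, 6 * L,
    -6 * L, (2 - phi) * L^2, 6 * L, (4 + phi) * L^2
  ), 4, 4, byrow = TRUE)
  idx <- c(3, 5, 9, 11)
  K[idx, idx] <- K[idx, idx] + kb2
  (K + t(K)) / 2
}

# rotation matrix rows = local axes (ex along the strut); deterministic
# reference choice for circular sections
beam_axes <- function(a, b) {
  ex <- b - a
  L <- sqrt(sum(ex^2))
  ex <- ex / L
  ref <- if (abs(ex[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  ey <- c(ref[2] * ex[3] - ref[3] * ex[2],
          ref[3] * ex[1] - ref[1] * ex[3],
          ref[1] * ex[2] - ref[2] * ex[1])
  ey <- ey / sqrt(sum(ey^2))
  ez <- c(ex[2] * ey[3] - ex[3] * ey[2],
          ex[3] * ey[1] - ex[1] * ey[3],
          ex[1] * ey[2] - ex[2] * ey[1])
  R <- rbind(ex, ey, ez)  # proper orthogonal; local = R %*% global
  list(R = R, L = L)
}

#' von-Mises equivalent stress
#'
#' @param sigma either a symmetric 3x3 stress tensor (MPa) or a length-6
#'   vector `(sxx, syy, szz, sxy, syz, szx)`.
#' @return scalar equivalent stress (MPa), non-negative.
#' @export
von_mises <- function(sigma) {
  if (is.matrix(sigma)) {
    if (any(abs(sigma - t(sigma)) > 1e-8 * max(1, max(abs(sigma)))))
      stop_invalid("stress tensor must be symmetric")
    s <- c(sigma[1, 1], sigma[2, 2], sigma[3, 3],
           sigma[1, 2], sigma[2, 3], sigma[3, 1])
  } else s <- sigma
  sqrt(0.5 * ((s[1] - s[2])^2 + (s[2] - s[3])^2 + (s[3] - s[1])^2) +
         3 * (s[4]^2 + s[5]^2 + s[6]^2))
}

#' Equivalent (von-Mises-type) strain in microstrain
#'
#' Computes `sqrt(2/3 * e:e)` with `e` the deviatoric part of the strain
#' tensor, reported in microstrain. Zero for purely volumetric strain;
#' homogeneous of degree one.
#'
#' @param eps a symmetric 3x3 strain tensor (tensor shear components), or a
#'   length-6 vector `(exx, eyy, ezz, gxy, gyz, gzx)` with engineering shear.
#' @return equivalent strain in microstrain.
#' @export
equivalent_strain <- function(eps) {
  if (is.matrix(eps)) {
    e <- c(eps[1, 1], eps[2, 2], eps[3, 3], eps[1, 2], eps[2, 3], eps[3, 1])
  } else {
    e <- eps
    e[4:6] <- e[4:6] / 2  # engineering -> tensor shear
  }
  em <- (e[1] + e[2] + e[3]) / 3
  dd <- (e[1] - em)^2 + (e[2] - em)^2 + (e[3] - em)^2 + 2 * sum(e[4:6]^2)
  sqrt(2 / 3 * dd) * 1e6
}

#' Surface-fiber equivalent stress of a circular strut
#'
#' Combines axial, biaxial bending and torsional shear at the surface fiber:
#' the maximizing circumferential angle gives `|N|/A + sqrt(My^2+Mz^2)*c/I`
#' for the normal part, combined with torsion `|T|*c/J` in a von-Mises sense.
#' Transverse shear is neglected (it vanishes at the extreme bending fiber).
#'
#' @param d strut diameter (mm).
#' @param N axial force (N).
#' @param Ty torque about the axis (N mm).
#' @param My,Mz bending moments about the two transverse axes (N mm).
#' @return equivalent stress (MPa). Vectorized over all arguments.
#' @export
beam_equivalent_stress <- function(d, N, Ty = 0, My = 0, Mz = 0) {
  if (any(d <= 0)) stop_invalid("beam diameter must be > 0")
  A <- pi * d^2 / 4
  I <- pi * d^4 / 64
  J <- 2 * I
  c <- d / 2
  sig <- abs(N) / A + sqrt(My^2 + Mz^2) * c / I
  tau <- abs(Ty) * c / J
  sqrt(sig^2 + 3 * tau^2)
}
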