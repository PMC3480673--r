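# ---- trilinear 8-node hexahedron (isoparametric) --------------------------
#
# Local node ordering follows the VTK_HEXAHEDRON convention:
# bottom face (zeta = -1) counter-clockwise, then top face (zeta = +1).

hex_corner_xi <- matrix(c(
  -1, -1, -1,
   1, -1, -1,
   1,  1, -1,
  -1,  1, -1,
  -1, -1,  1,
   1, -1,  1,
   1,  1,  1,
  -1,  1,  1), ncol = 3, byrow = TRUE)

#' Trilinear shape functions at a local point
#' @param xi length-3 local coordinates in \[-1, 1\]^3
#' @return length-8 vector of shape function values
#' @keywords internal
hex_shape <- function(xi) {
  0.125 * (1 + hex_corner_xi[, 1] * xi[1]) *
          (1 + hex_corner_xi[, 2] * xi[2]) *
          (1 + hex_corner_xi[, 3] * xi[3])
}

#' Shape-function derivatives w.r.t. local coordinates
#' @return 8 x 3 matrix, entry (a, j) = dN_a / dxi_j
#' @keywords internal
hex_shape_deriv <- function(xi) {
  s <- hex_corner_xi
  cbind(
    0.125 * s[, 1] * (1 + s[, 2] * xi[2]) * (1 + s[, 3] * xi[3]),
    0.125 * s[, 2] * (1 + s[, 1] * xi[1]) * (1 + s[, 3] * xi[3]),
    0.125 * s[, 3] * (1 + s[, 1] * xi[1]) * (1 + s[, 2] * xi[2]))
}

#' Gauss-Legendre points/weights on [-1,1]^3
#' @param n points per axis (1..5 supported)
#' @return list with `points` (n^3 x 3) and `weights` (n^3)
#' @export
hex_quadrature <- function(n = 2) {
  gl <- switch(as.character(n),
    "1" = list(x = 0, w = 2),
    "2" = list(x = c(-1, 1) / sqrt(3), w = c(1, 1)),
    "3" = list(x = c(-sqrt(3 / 5), 0, sqrt(3 / 5)), w = c(5, 8, 5) / 9),
    "4" = {
      a <- sqrt(3 / 7 - 2 / 7 * sqrt(6 / 5)); b <- sqrt(3 / 7 + 2 / 7 * sqrt(6 / 5))
      wa <- (18 + sqrt(30)) / 36; wb <- (18 - sqrt(30)) / 36
      list(x = c(-b, -a, a, b), w = c(wb, wa, wa, wb))
    },
    "5" = {
      a <- 1 / 3 * sqrt(5 - 2 * sqrt(10 / 7)); b <- 1 / 3 * sqrt(5 + 2 * sqrt(10 / 7))
      wa <- (322 + 13 * sqrt(70)) / 900; wb <- (322 - 13 * sqrt(70)) / 900
      list(x = c(-b, -a, 0, a, b), w = c(wb, wa, 128 / 225, wa, wb))
    },
    stop("unsupported quadrature order: ", n))
  g <- expand.grid(xi = gl$x, eta = gl$x, zeta = gl$x)
  w <- expand.grid(a = gl$w, b = gl$w, c = gl$w)
  list(points = as.matrix(g), weights = w$a * w$b * w$c)
}

# Jacobian of the isoparametric map at a local point.
# X: 8 x 3 element node coordinates. Returns list(J, detJ, dNdx).
hex_jacobian <- function(X, xi) {
  dN <- hex_shape_deriv(xi)
  J <- crossprod(X, dN)            # J[i, j] = dx_i / dxi_j
  detJ <- det(J)
  list(J = J, detJ = detJ, dN = dN)
}

hex_grad_global <- function(X, xi) {
  jac <- hex_jacobian(X, xi)
  if (jac$detJ <= 0) stop("non-positive Jacobian determinant in element")
  # dN/dx = dN/dxi %*% d(xi)/dx ; d(xi)/dx = J^{-1} with our index convention
  list(dNdx = jac$dN %*% solve(jac$J), detJ = jac$detJ)
}

#' Minimum Jacobian determinant of an element over a quadrature rule
#' @keywords internal
hex_min_detJ <- function(X, quad = hex_quadrature(2)) {
  min(vapply(seq_along(quad$weights), function(q) {
    hex_jacobian(X, quad$points[q, ])$detJ
  }, numeric(1)))
}

# ---- scalar diffusion (monodomain) element matrices -----------------------

# Element stiffness for div(D grad u): 8x8, D a 3x3 SPD tensor.
hex_diffusion_stiffness <- function(X, D, quad = hex_quadrature(2)) {
  K <- matrix(0, 8, 8)
  for (q in seq_along(quad$weights)) {
    g <- hex_grad_global(X, quad$points[q, ])
    K <- K + quad$weights[q] * g$detJ * (g$dNdx %*% D %*% t(g$dNdx))
  }
  K
}

# Lumped (row-sum of consistent) mass vector, 8 values.
hex_lumped_mass <- function(X, quad = hex_quadrature(2)) {
  m <- numeric(8)
  for (q in seq_along(quad$weights)) {
    jac <- hex_jacobian(X, quad$points[q, ])
    N <- hex_shape(quad$points[q, ])
    m <- m + quad$weights[q] * jac$detJ * N
  }
  m
}

# ---- elasticity -----------------------------------------------------------

# Strain-displacement matrix B (6 x 24) at a local point.
# Voigt order: (e11, e22, e33, g23, g13, g12) with engineering shears.
hex_B_matrix <- function(dNdx) {
  B <- matrix(0, 6, 24)
  for (a in 1:8) {
    c0 <- 3 * (a - 1)
    bx <- dNdx[a, 1]; by <- dNdx[a, 2]; bz <- dNdx[a, 3]
    B[1, c0 + 1] <- bx
    B[2, c0 + 2] <- by
    B[3, c0 + 3] <- bz
    B[4, c0 + 2] <- bz; B[4, c0 + 3] <- by
    B[5, c0 + 1] <- bz; B[5, c0 + 3] <- bx
    B[6, c0 + 1] <- by; B[6, c0 + 2] <- bx
  }
  B
}

#' Element stiffness matrix of an 8-node isoparametric hexahedron
#'
#' Integrates \eqn{K_e = \int B^T C B \, |J| \, d\xi d\eta d\zeta} over the
#' reference cube with Gauss quadrature. `C` is the 6x6 elasticity matrix in
#' global axes (kPa, Voigt order e11,e22,e33,g23,g13,g12).
#'
#' @param X 8 x 3 matrix of element node coordinates (mm).
#' @param C 6 x 6 symmetric positive definite elasticity matrix (kPa).
#' @param quad quadrature rule from [hex_quadrature()]; 2x2x2 by default.
#' @return 24 x 24 symmetric element stiffness matrix.
#' @export
element_stiffness <- function(X, C, quad = hex_quadrature(2)) {
  stopifnot(is.matrix(X), nrow(X) == 8, ncol(X) == 3,
            is.matrix(C), all(dim(C) == c(6, 6)))
  K <- matrix(0, 24, 24)
  for (q in seq_along(quad$weights)) {
    g <- hex_grad_global(X, quad$points[q, ])
    B <- hex_B_matrix(g$dNdx)
    K <- K + quad$weights[q] * g$detJ * (t(B) %*% C %*% B)
  }
  (K + t(K)) / 2
}

#' Nodal force vector equivalent to a uniaxial active fiber stress
#'
#' Computes \eqn{f_e = -\int B^T \sigma \, |J| \, d\xi d\eta d\zeta} where
#' \eqn{\sigma} is the global Voigt stress of a uniaxial tension of magnitude
#' `sigma` (kPa) along the unit `fiber` direction. The resulting 24-vector is
#' self-equilibrated (zero net force and moment).
#'
#' @param X 8 x 3 element node coordinates (mm).
#' @param sigma active fiber stress magnitude (kPa).
#' @param fiber unit fiber direction in global coordinates.
#' @param quad quadrature rule; 2x2x2 Gauss by default.
#' @return length-24 nodal force vector (element dof order x1,y1,z1,...).
#' @export
element_active_force <- function(X, sigma, fiber, quad = hex_quadrature(2)) {
  stopifnot(is.finite(sigma), length(fiber) == 3)
  f <- fiber / sqrt(sum(fiber^2))
  # uniaxial stress tensor sigma * f f^T in Voigt stress order
  s <- sigma * c(f[1]^2, f[2]^2, f[3]^2, f[2] * f[3], f[1] * f[3], f[1] * f[2])
  out <- numeric(24)
  for (q in seq_along(quad$weights)) {
    g <- hex_grad_global(X, quad$points[q, ])
    B <- hex_B_matrix(g$dNdx)
    out <- out - quad$weights[q] * g$detJ * drop(t(B) %*% s)
  }
  out
}

# ---- Voigt (Bond) rotation for elasticity matrices ------------------------

#' 6x6 stress rotation (Bond) matrix from a 3x3 rotation
#'
#' For a rotation matrix `R` whose rows are the material axes expressed in
#' global coordinates (x_mat = R x_glob), returns the 6x6 matrix `M` with
#' sigma_mat = M sigma_glob in Voigt stress notation
#' (s11,s22,s33,s23,s13,s12). An elasticity matrix given in material axes
#' transforms to global axes as \eqn{C_{glob} = M^T C_{mat} M^{-T}}... in
#' practice use [rotate_elasticity()].
#'
#' @param R 3 x 3 rotation matrix (orthonormal rows).
#' @return 6 x 6 Bond stress-rotation matrix.
#' @export
bond_stress_rotation <- function(R) {
  stopifnot(all(dim(R) == c(3, 3)))
  if (max(abs(R %*% t(R) - diag(3))) > 1e-8) stop("R is not orthonormal")
  M <- matrix(0, 6, 6)
  # index pairs for Voigt slots 4,5,6 -> (2,3), (1,3), (1,2)
  p <- rbind(c(2, 3), c(1, 3), c(1, 2))
  for (i in 1:3) for (j in 1:3) M[i, j] <- R[i, j]^2
  for (i in 1:3) for (q in 1:3) {
    k <- p[q, 1]; l <- p[q, 2]
    M[i, 3 + q] <- 2 * R[i, k] * R[i, l]
  }
  for (q in 1:3) for (j in 1:3) {
    k <- p[q, 1]; l <- p[q, 2]
    M[3 + q, j] <- R[k, j] * R[l, j]
  }
  for (q in 1:3) for (r in 1:3) {
    k <- p[q, 1]; l <- p[q, 2]; m <- p[r, 1]; n <- p[r, 2]
    M[3 + q, 3 + r] <- R[k, m] * R[l, n] + R[k, n] * R[l, m]
  }
  M
}

#' Rotate an elasticity matrix from material to global axes
#'
#' `R` has rows = material axes in global coordinates. With the Bond stress
#' rotation `M = bond_stress_rotation(R)` the global-axis elasticity matrix is
#' \eqn{C_{glob} = M^{-1} C_{mat} M^{-T}}, which for orthogonal `R` equals
#' the congruence by the inverse rotation. Symmetry and positive definiteness
#' are preserved.
#'
#' @param C_mat 6 x 6 elasticity matrix in material axes.
#' @param R 3 x 3 rotation, rows = material axes in global coordinates.
#' @return 6 x 6 elasticity matrix in global axes.
#' @export
rotate_elasticity <- function(C_mat, R) {
  M <- bond_stress_rotation(R)
  Minv <- bond_stress_rotation(t(R))   # inverse rotation
  C <- Minv %*% C_mat %*% t(Minv)
  (C + t(C)) / 2
}

#' Strain/stress transformation for a fiber-aligned material frame
#'
#' Returns the 6x6 Voigt stress rotation taking global-axis stress to the
#' fiber frame in which the fiber is the third material axis (so a uniaxial
#' active fiber stress is \{0,0,sigma,0,0,0\}). The local frame must be
#' orthonormal.
#'
#' @param fiber unit fiber vector (3rd material axis).
#' @param sheet unit vector orthogonal to `fiber` (1st material axis); the
#'   2nd axis completes the right-handed frame.
#' @return 6 x 6 transformation matrix.
#' @export
fiber_rotation_matrix <- function(fiber, sheet) {
  f <- fiber / sqrt(sum(fiber^2))
  s <- sheet - sum(sheet * f) * f
  ns <- sqrt(sum(s^2))
  if (ns < 1e-10) stop("degenerate local frame: sheet parallel to fiber")
  s <- s / ns
  n <- c(f[2] * s[3] - f[3] * s[2], f[3] * s[1] - f[1] * s[3],
         f[1] * s[2] - f[2] * s[1])   # n = f x s, right-handed (s, n, f)
  R <- rbind(s, n, f)               # rows = material axes in global coords
  rownames(R) <- NULL
  bond_stress_rotation(R)
}
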