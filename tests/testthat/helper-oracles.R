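# Independent brute-force oracles, deliberately written without the
# package's FEM helpers so they can cross-check them.

# Gauss-Legendre nodes/weights on [-1,1] via the eigenvalue method
# (Golub-Welsch), independent of the package's tabulated rules.
oracle_gauss_1d <- function(n) {
  if (n == 1) return(list(x = 0, w = 2))
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- diag(0, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  ev <- eigen(J, symmetric = TRUE)
  list(x = ev$values, w = 2 * ev$vectors[1, ]^2)
}

# shape function values/derivatives of the trilinear hex, recomputed from
# the product form (corner signs written out explicitly)
oracle_hex_corners <- function() {
  as.matrix(expand.grid(s1 = c(-1, 1), s2 = c(-1, 1), s3 = c(-1, 1)))[
    c(1, 2, 4, 3, 5, 6, 8, 7), ]   # VTK ordering
}

oracle_shape <- function(xi) {
  s <- oracle_hex_corners()
  apply(s, 1, function(r) prod((1 + r * xi) / 2))
}

oracle_shape_grad <- function(xi) {
  s <- oracle_hex_corners()
  t(apply(s, 1, function(r) {
    c(r[1] / 2 * (1 + r[2] * xi[2]) / 2 * (1 + r[3] * xi[3]) / 2,
      r[2] / 2 * (1 + r[1] * xi[1]) / 2 * (1 + r[3] * xi[3]) / 2,
      r[3] / 2 * (1 + r[1] * xi[1]) / 2 * (1 + r[2] * xi[2]) / 2)
  }))
}

# dense high-order-quadrature element stiffness (elastic), order n per axis
oracle_element_stiffness <- function(X, C, n = 4) {
  gl <- oracle_gauss_1d(n)
  K <- matrix(0, 24, 24)
  for (a in seq_len(n)) for (b in seq_len(n)) for (cc in seq_len(n)) {
    xi <- c(gl$x[a], gl$x[b], gl$x[cc])
    w <- gl$w[a] * gl$w[b] * gl$w[cc]
    dN <- oracle_shape_grad(xi)
    J <- t(X) %*% dN
    dNdx <- dN %*% solve(J)
    B <- matrix(0, 6, 24)
    for (k in 1:8) {
      c0 <- 3 * (k - 1)
      B[1, c0 + 1] <- dNdx[k, 1]
      B[2, c0 + 2] <- dNdx[k, 2]
      B[3, c0 + 3] <- dNdx[k, 3]
      B[4, c0 + 2] <- dNdx[k, 3]; B[4, c0 + 3] <- dNdx[k, 2]
      B[5, c0 + 1] <- dNdx[k, 3]; B[5, c0 + 3] <- dNdx[k, 1]
      B[6, c0 + 1] <- dNdx[k, 2]; B[6, c0 + 2] <- dNdx[k, 1]
    }
    K <- K + w * det(J) * (t(B) %*% C %*% B)
  }
  K
}

# dense high-order-quadrature uniaxial active force
oracle_active_force <- function(X, sigma, fiber, n = 4) {
  gl <- oracle_gauss_1d(n)
  f <- fiber / sqrt(sum(fiber^2))
  sv <- sigma * c(f[1]^2, f[2]^2, f[3]^2, f[2] * f[3], f[1] * f[3], f[1] * f[2])
  out <- numeric(24)
  for (a in seq_len(n)) for (b in seq_len(n)) for (cc in seq_len(n)) {
    xi <- c(gl$x[a], gl$x[b], gl$x[cc])
    w <- gl$w[a] * gl$w[b] * gl$w[cc]
    dN <- oracle_shape_grad(xi)
    J <- t(X) %*% dN
    dNdx <- dN %*% solve(J)
    for (k in 1:8) {
      c0 <- 3 * (k - 1)
      bx <- dNdx[k, 1]; by <- dNdx[k, 2]; bz <- dNdx[k, 3]
      # B^T s for node k
      out[c0 + 1] <- out[c0 + 1] - w * det(J) * (bx * sv[1] + bz * sv[5] + by * sv[6])
      out[c0 + 2] <- out[c0 + 2] - w * det(J) * (by * sv[2] + bz * sv[4] + bx * sv[6])
      out[c0 + 3] <- out[c0 + 3] - w * det(J) * (bz * sv[3] + by * sv[4] + bx * sv[5])
    }
  }
  out
}

# rotate a 6x6 Voigt elasticity matrix by brute-force rotation of the full
# 3x3x3x3 stiffness tensor (loops over all 8 indices)
oracle_rotate_elasticity <- function(C, R) {
  vi <- rbind(c(1, 1), c(2, 2), c(3, 3), c(2, 3), c(1, 3), c(1, 2))
  voigt_index <- matrix(0L, 3, 3)
  for (q in 1:6) {
    voigt_index[vi[q, 1], vi[q, 2]] <- q
    voigt_index[vi[q, 2], vi[q, 1]] <- q
  }
  Ct <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
    Ct[i, j, k, l] <- C[voigt_index[i, j], voigt_index[k, l]]
  # material-to-global: x_glob = t(R) x_mat when rows of R are material axes
  Q <- t(R)
  Cr <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
    s <- 0
    for (p in 1:3) for (q in 1:3) for (r in 1:3) for (t in 1:3)
      s <- s + Q[i, p] * Q[j, q] * Q[k, r] * Q[l, t] * Ct[p, q, r, t]
    Cr[i, j, k, l] <- s
  }
  out <- matrix(0, 6, 6)
  for (a in 1:6) for (b in 1:6)
    out[a, b] <- Cr[vi[a, 1], vi[a, 2], vi[b, 1], vi[b, 2]]
  out
}

# direct-summation circumferential Fourier powers (no fft, no shortcuts)
oracle_ring_power <- function(ecc) {
  n <- length(ecc)
  theta <- 2 * pi * (seq_len(n) - 1) / n
  a0 <- sum(ecc) / n
  re <- sum(ecc * cos(theta)) * 2 / n
  im <- sum(ecc * sin(theta)) * 2 / n
  c(a0^2, re^2 + im^2)
}

# random rotation matrix from QR of a fixed-seed Gaussian matrix
oracle_random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
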