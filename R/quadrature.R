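# Gauss-Jacobi quadrature via Golub-Welsch, and conical-product rules on the
# reference triangle/tetrahedron (Duffy collapse). Self-contained because no
# quadrature package is available; exactness is asserted in the test suite
# against closed-form barycentric monomial integrals.

# n-point Gauss-Jacobi rule for integral_{-1}^{1} (1-x)^alpha f(x) dx
gauss_jacobi <- function(n, alpha = 0) {
  b <- 0  # beta = 0 throughout
  k <- seq_len(n) - 1
  diag_k <- ifelse(k == 0 & alpha + b == 0, 0,
                   (b^2 - alpha^2) / ((2 * k + alpha + b) * (2 * k + alpha + b + 2)))
  mu0 <- 2^(alpha + b + 1) * gamma(alpha + 1) * gamma(b + 1) / gamma(alpha + b + 2)
  off <- numeric(0)
  if (n > 1) {
    kk <- seq_len(n - 1)
    off2 <- 4 * kk * (kk + alpha) * (kk + b) * (kk + alpha + b) /
      ((2 * kk + alpha + b)^2 * (2 * kk + alpha + b + 1) * (2 * kk + alpha + b - 1))
    off <- sqrt(off2)
  }
  J <- diag(diag_k, n, n)
  if (n > 1) {
    J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
    J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  }
  e <- eigen(J, symmetric = TRUE)
  nodes <- e$values
  weights <- mu0 * e$vectors[1, ]^2
  ord <- order(nodes)
  list(x = nodes[ord], w = weights[ord])
}

# shifted to [0,1] with weight (1-t)^alpha
gauss_jacobi01 <- function(n, alpha = 0) {
  g <- gauss_jacobi(n, alpha)
  list(x = (1 + g$x) / 2, w = g$w / 2^(alpha + 1))
}

# conical-product rule on the reference triangle {x,y >= 0, x+y <= 1};
# exact for total degree <= 2n-1
tri_quadrature <- function(n = 3) {
  g1 <- gauss_jacobi01(n, alpha = 1)   # radial-like, carries (1-u) jacobian
  g0 <- gauss_jacobi01(n, alpha = 0)
  pts <- matrix(0, n * n, 2)
  w <- numeric(n * n)
  idx <- 1
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      u <- g1$x[i]; v <- g0$x[j]
      pts[idx, ] <- c(u, v * (1 - u))
      w[idx] <- g1$w[i] * g0$w[j]
      idx <- idx + 1
    }
  }
  list(points = pts, weights = w)   # weights sum to 1/2 (reference area)
}

# conical-product rule on the reference tetrahedron; exact for degree <= 2n-1
tet_quadrature <- function(n = 3) {
  g2 <- gauss_jacobi01(n, alpha = 2)
  g1 <- gauss_jacobi01(n, alpha = 1)
  g0 <- gauss_jacobi01(n, alpha = 0)
  m <- n^3
  pts <- matrix(0, m, 3)
  w <- numeric(m)
  idx <- 1
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    u <- g2$x[i]; v <- g1$x[j]; s <- g0$x[k]
    pts[idx, ] <- c(u, v * (1 - u), s * (1 - u) * (1 - v))
    w[idx] <- g2$w[i] * g1$w[j] * g0$w[k]
    idx <- idx + 1
  }
  list(points = pts, weights = w)   # weights sum to 1/6 (reference volume)
}
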