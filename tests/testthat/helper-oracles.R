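# Independent oracles used across the suite. These deliberately avoid the
# package's production code paths.

# Gaussian bump density, zero-extended outside [0, L]: both as a function
# (for quadrature paths) and as nodal values.
bump_fun <- function(center = 3, sd = 0.4, mass = 10, L = 6) {
  function(x) ifelse(x >= 0 & x <= L, mass * stats::dnorm(x, center, sd), 0)
}

# Direct double-loop Riemann sum with the printed index bounds; oracle for
# the vectorised grid stencil.
riemann_sum_direct <- function(values, h, r, Ffun = function(s) rep(1, length(s))) {
  lr <- as.integer(round(r / h))
  M <- length(values) - 1L
  s <- numeric(M + 1L)
  for (m in 0:M) {
    a <- max(-(lr - 1L), -m)
    b <- min(lr, M - m)
    acc <- 0
    for (l in a:b) {
      if (l == 0L) next
      acc <- acc + values[m + l + 1L] * sign(l * h) * Ffun(abs(l) * h)
    }
    s[m + 1L] <- h * acc
  }
  s
}

# Dense-matrix Crank-Nicolson solver for the linear no-flux diffusion
# problem (chi0 = 0, delta = 0): (a+1) u_t = c1 D0 u_xx. Conservative
# finite-volume Laplacian with half cells at the boundary, assembled as a
# dense matrix and stepped by direct solves.
crank_nicolson_diffusion <- function(u0, h, D0, a, T, dt) {
  M1 <- length(u0)
  c1 <- (1 / (2 * a + 1)) * (1 / 3)
  kappa <- c1 * D0 / (a + 1)
  A <- matrix(0, M1, M1)
  for (i in 2:(M1 - 1L)) {
    A[i, i - 1L] <- kappa / h^2
    A[i, i] <- -2 * kappa / h^2
    A[i, i + 1L] <- kappa / h^2
  }
  A[1L, 1L] <- -kappa / h^2 * 2; A[1L, 2L] <- kappa / h^2 * 2
  A[M1, M1] <- -kappa / h^2 * 2; A[M1, M1 - 1L] <- kappa / h^2 * 2
  n <- as.integer(round(T / dt))
  I <- diag(M1)
  lhs <- I - dt / 2 * A
  rhs <- I + dt / 2 * A
  u <- u0
  for (k in seq_len(n)) u <- solve(lhs, rhs %*% u)
  as.numeric(u)
}

# Scalar quadratic-root oracle for the bound-fraction fixed point with
# spatially constant fields: y solves (B - A) y^2 + 2 A y - A = 0 where A
# and B are the G+/G- weighted densities.
bound_fraction_quadratic <- function(A, B) {
  if (abs(B - A) < 1e-14) return(0.5)
  (-2 * A + sqrt(4 * A^2 + 4 * (B - A) * A)) / (2 * (B - A))
}
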