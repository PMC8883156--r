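# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths.

# Quadrature oracle for the 3-alternative oddity differencing rule.
# With target u ~ N(d,1) and non-targets v, w ~ N(0,1), the target is
# chosen iff |u - xbar| is the largest deviation from the grand mean,
# which is algebraically equivalent to
#   |u - w| > |v - w|   and   |u - v| > |w - v|.
# For fixed (u, v) the admissible w form a single interval:
#   u > v :  (v - |u - v|, (u + v)/2)
#   u < v :  ((u + v)/2, v + |u - v|)
# so the innermost integral is exact via pnorm and the outer two are done
# by trapezoidal quadrature on a fine grid.
oddity_pc_quadrature_m3 <- function(d, n_grid = 1201, half_width = 8) {
  u <- seq(d - half_width, d + half_width, length.out = n_grid)
  v <- seq(-half_width, half_width, length.out = n_grid)
  du <- u[2] - u[1]; dv <- v[2] - v[1]
  U <- matrix(u, n_grid, n_grid)
  V <- matrix(v, n_grid, n_grid, byrow = TRUE)
  r <- abs(U - V)
  mid <- (U + V) / 2
  lo <- ifelse(U > V, V - r, mid)
  hi <- ifelse(U > V, mid, V + r)
  inner <- pnorm(hi) - pnorm(lo)
  wu <- rep(1, n_grid); wu[c(1, n_grid)] <- 0.5
  wv <- wu
  f <- dnorm(U, mean = d) * dnorm(V) * inner
  sum((wu %o% wv) * f) * du * dv
}

# Scalar Ward BRDF evaluation written directly from the formula with
# explicit 3-vectors (no reuse of package internals).
ward_scalar_oracle <- function(rho_d, rho_s, alpha,
                               theta_i, phi_i, theta_o, phi_o) {
  wi <- c(sin(theta_i) * cos(phi_i), sin(theta_i) * sin(phi_i), cos(theta_i))
  wo <- c(sin(theta_o) * cos(phi_o), sin(theta_o) * sin(phi_o), cos(theta_o))
  h <- (wi + wo) / sqrt(sum((wi + wo)^2))
  delta <- acos(h[3])
  rho_d / pi + rho_s * exp(-tan(delta)^2 / alpha^2) /
    (4 * pi * alpha^2 * sqrt(cos(theta_i) * cos(theta_o)))
}

# Moore-Penrose least squares (pseudo-inverse) oracle for OLS checks.
ols_pinv_oracle <- function(X, y) {
  Xi <- cbind(1, X)
  s <- svd(Xi)
  tol <- max(dim(Xi)) * max(s$d) * .Machine$double.eps
  dinv <- ifelse(s$d > tol, 1 / s$d, 0)
  as.numeric(s$v %*% (dinv * (t(s$u) %*% y)))
}
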