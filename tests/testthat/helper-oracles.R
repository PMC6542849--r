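# Independent numerical oracles used by the tests. Each reimplements the
# quantity under test by a different method than the package.

# Brute-force ensemble variance: explicit covariance double sum over all
# carrier pairs, Cov(i_m, i_n) = var_single * (xi + (1 - xi) * [m == n]).
oracle_ensemble_variance <- function(N, var_single, xi) {
  total <- 0
  for (m in seq_len(N)) {
    for (n in seq_len(N)) {
      total <- total + var_single * if (m == n) 1 else xi
    }
  }
  total
}

# Thomas solve for the tridiagonal systems of the oracles below.
oracle_tridiag <- function(lo, di, up, b) {
  n <- length(di)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- up[1] / di[1]; dp[1] <- b[1] / di[1]
  for (i in 2:n) {
    m <- di[i] - lo[i - 1] * cp[i - 1]
    if (i < n) cp[i] <- up[i] / m
    dp[i] <- (b[i] - lo[i - 1] * dp[i - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

# Classical-PB shooting oracle (alpha = 0): integrate the cylindrical ODE
#   Psi'' + Psi'/r = sinh(Psi)/lambda^2
# outward from the axis with deSolve and root-find the axis value so that
# Psi'(R) matches the wall boundary condition. Returns Psi on r_out.
oracle_pb_shooting <- function(R, lambda_D, bc, r_out) {
  deriv <- function(r, y, parms) {
    list(c(y[2], sinh(y[1]) / lambda_D^2 - y[2] / r))
  }
  r0 <- 1e-8
  shoot <- function(s) {
    # series start to step over the r = 0 singularity; divergent trial
    # shots (sinh blow-up) are mapped to a large signed mismatch
    y0 <- c(s + sinh(s) / lambda_D^2 * r0^2 / 4,
            sinh(s) / lambda_D^2 * r0 / 2)
    sol <- suppressWarnings(
      deSolve::lsoda(y0, c(r0, R), deriv, parms = NULL,
                     rtol = 1e-12, atol = 1e-12, maxsteps = 1e5))
    end <- sol[nrow(sol), ]
    if (abs(end[1] - R) > 1e-9 || !is.finite(end[3])) return(sign(s) * 1e6)
    end[3]
  }
  f <- function(s) shoot(s) - bc
  s_star <- stats::uniroot(f, lower = -15, upper = 0, tol = 1e-13)$root
  y0 <- c(s_star + sinh(s_star) / lambda_D^2 * r0^2 / 4,
          sinh(s_star) / lambda_D^2 * r0 / 2)
  times <- pmax(r_out, r0)
  sol <- suppressWarnings(
    deSolve::lsoda(y0, unique(c(r0, times)), deriv, parms = NULL,
                   rtol = 1e-12, atol = 1e-12, maxsteps = 1e5))
  stats::approx(sol[, 1], sol[, 2], xout = times, rule = 2)$y
}

# Wall boundary condition dPsi/dr(R) in nm^-1 for surface charge rho_s
# (e/nm^2), matching the package's Gauss-law convention.
oracle_pb_bc <- function(rho_s, T = 298.15, epsilon_r = 78.4) {
  e <- 1.602176634e-19; kB <- 1.380649e-23; eps0 <- 8.8541878128e-12
  sigma_s <- rho_s * e * 1e18
  e * sigma_s / (epsilon_r * eps0 * kB * T) * 1e-9
}

# Mean first passage time to either absorbing end of [a, b], starting at z0,
# for overdamped diffusion in potential W (kBT) with diffusivity D:
# solve D T'' - D W' T' = -1, T(a) = T(b) = 0, by finite differences.
oracle_mfpt <- function(W_fun, D, a, b, z0, n = 4001) {
  z <- seq(a, b, length.out = n)
  h <- z[2] - z[1]
  W <- W_fun(z)
  dW <- c(diff(W)[1], (W[3:n] - W[1:(n - 2)]) / 2, diff(W)[n - 1]) / h
  m <- n - 2
  idx <- 2:(n - 1)
  di <- rep(-2 * D / h^2, m)
  up <- D / h^2 - D * dW[idx][-m] / (2 * h)
  lo <- D / h^2 + D * dW[idx][-1] / (2 * h)
  Tin <- oracle_tridiag(lo, di, up, rep(-1, m))
  stats::approx(z[idx], Tin, xout = z0)$y
}

# Direct (non-Welch) one-sided periodogram level of a white trace, for
# Parseval-style cross-checks.
oracle_white_psd_level <- function(x, fs) {
  2 * stats::var(x) / fs
}
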