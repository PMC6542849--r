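# Steric-modified Poisson-Boltzmann radial solver and the reduced-order
# conductance model (series resistance integral + access resistance + a
# parallel counter-ion surface term).

#' Steric-modified Poisson-Boltzmann radial solver
#'
#' Solves the radial (cylindrical, waist cross-section) modified
#' Poisson-Boltzmann equation for the reduced potential `Psi = e psi / kB T`:
#' \deqn{\nabla^2 \Psi = \sinh(\Psi) / [\lambda^2 (1 + \alpha(\cosh\Psi - 1))]}
#' with `alpha = 2 a^3 n0` the steric (Bikerman) parameter for solvated ion
#' radius `a` and bulk number density `n0`. Boundary conditions: symmetry at
#' the axis and a wall field set by the surface charge density via Gauss's
#' law. `alpha = 0` recovers classical Poisson-Boltzmann.
#'
#' Solved by damped Newton iteration on a second-order finite-difference grid;
#' the initial guess is the linearized (Debye-Hueckel) modified-Bessel
#' solution.
#'
#' @param pore A [pore_model()] (uses `d_mean` and `rho_s`).
#' @param cond An [electrolyte_condition()] (uses `I_strength`, `C`, `T`,
#'   `epsilon_r`).
#' @param a_solv Solvated ion radius (nm), `>= 0`; 0 gives `alpha = 0`.
#' @param n_grid Number of radial grid points.
#' @param tol Supremum-norm residual tolerance of the discretized equation.
#' @param max_iter Newton iteration budget.
#' @return An object of class `continuum_field` with the radial grid `r_grid`
#'   (nm), reduced potential `Psi`, per-species concentration profiles
#'   `c_profiles` (M), `alpha`, and a Gauss-law charge-balance diagnostic.
#' @export
modified_pb_radial <- function(pore, cond, a_solv = 0, n_grid = 2000,
                               tol = 1e-8, max_iter = 200) {
  stopifnot(inherits(pore, "pore_model"), inherits(cond, "electrolyte_condition"))
  R <- pore$d_mean / 2                     # nm
  lam <- cond$lambda_D                     # nm
  n0 <- cond$C * pn_constants$N_A * 1e-24   # bulk cation number density, nm^-3
  alpha <- 2 * a_solv^3 * n0
  # wall boundary condition dPsi/dr(R) in nm^-1 from Gauss's law
  sigma_s <- pore$rho_s * pn_constants$e * 1e18          # C m^-2
  kT <- pn_constants$kB * cond$T
  bc <- pn_constants$e * sigma_s /
    (cond$epsilon_r * pn_constants$eps0 * kT) * 1e-9     # nm^-1
  h <- R / (n_grid - 1)
  r <- seq(0, R, length.out = n_grid)

  if (pore$rho_s == 0) {
    Psi <- rep(0, n_grid)
    return(.continuum_field(r, Psi, alpha, a_solv, cond, pore, residual = 0,
                            iterations = 0L, converged = TRUE))
  }

  rhs <- function(p) sinh(p) / (lam^2 * (1 + alpha * (cosh(p) - 1)))
  drhs <- function(p) {
    den <- 1 + alpha * (cosh(p) - 1)
    (cosh(p) * den - sinh(p) * alpha * sinh(p)) / (lam^2 * den^2)
  }
  # residual of the discretized equation, F(Psi) = Laplacian(Psi) - rhs(Psi)
  resid <- function(p) {
    F <- numeric(n_grid)
    F[1] <- 4 * (p[2] - p[1]) / h^2 - rhs(p[1])
    i <- 2:(n_grid - 1)
    F[i] <- (p[i + 1] * (1 + h / (2 * r[i])) - 2 * p[i] +
             p[i - 1] * (1 - h / (2 * r[i]))) / h^2 - rhs(p[i])
    # wall: ghost node from dPsi/dr(R) = bc
    F[n_grid] <- (2 * p[n_grid - 1] - 2 * p[n_grid] +
                  2 * h * bc * (1 + h / (2 * R))) / h^2 - rhs(p[n_grid])
    F
  }
  # tridiagonal Jacobian bands
  jac_bands <- function(p) {
    lo <- numeric(n_grid - 1); di <- numeric(n_grid); up <- numeric(n_grid - 1)
    di[1] <- -4 / h^2 - drhs(p[1]); up[1] <- 4 / h^2
    i <- 2:(n_grid - 1)
    di[i] <- -2 / h^2 - drhs(p[i])
    up[i] <- (1 + h / (2 * r[i])) / h^2
    lo[i - 1] <- (1 - h / (2 * r[i])) / h^2
    di[n_grid] <- -2 / h^2 - drhs(p[n_grid])
    lo[n_grid - 1] <- 2 / h^2
    list(lo = lo, di = di, up = up)
  }

  # initial guess: linearized solution Psi = bc * lambda * I0(r/lam) / I1(R/lam)
  Psi <- pb_linearized(r, R, lam, bc)
  res <- resid(Psi)
  for (it in seq_len(max_iter)) {
    if (max(abs(res)) < tol)
      return(.continuum_field(r, Psi, alpha, a_solv, cond, pore,
                              residual = max(abs(res)), iterations = it - 1L,
                              converged = TRUE))
    jb <- jac_bands(Psi)
    dPsi <- solve_tridiag(jb$lo, jb$di, jb$up, -res)
    # the discrete Laplacian amplifies rounding noise by ~1/h^2, so the
    # residual has a floating-point floor; the Newton step does not
    if (max(abs(dPsi)) < tol)
      return(.continuum_field(r, Psi, alpha, a_solv, cond, pore,
                              residual = max(abs(res)), iterations = it,
                              converged = TRUE))
    # damped step: halve until the residual norm decreases
    lambda_damp <- 1
    repeat {
      Psi_new <- Psi + lambda_damp * dPsi
      res_new <- resid(Psi_new)
      if (max(abs(res_new)) < max(abs(res)) || lambda_damp < 1e-6) break
      lambda_damp <- lambda_damp / 2
    }
    Psi <- Psi_new; res <- res_new
  }
  stop(sprintf("modified_pb_radial failed to converge in %d iterations (residual %.3g)",
               max_iter, max(abs(res))))
}

# linearized (Debye-Hueckel) closed form for a charged cylinder wall:
# Psi(r) = bc * lambda * I0(r/lambda) / I1(R/lambda)
pb_linearized <- function(r, R, lam, bc) {
  bc * lam * besselI(r / lam, 0) / besselI(R / lam, 1)
}

# Thomas algorithm for a tridiagonal system
solve_tridiag <- function(lo, di, up, b) {
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

.continuum_field <- function(r, Psi, alpha, a_solv, cond, pore,
                             residual, iterations, converged) {
  den <- 1 + alpha * (cosh(Psi) - 1)
  c_plus <- cond$C * exp(-Psi) / den
  c_minus <- cond$C * exp(Psi) / den
  # Gauss-law balance: integrated net ionic charge per unit length (e/nm)
  # against the wall charge per unit length
  n0 <- cond$C * pn_constants$N_A * 1e-24
  net <- (c_plus - c_minus) / cond$C * n0       # e nm^-3
  q_liquid <- 2 * pi * trapz(r, net * r)        # e / nm
  q_wall <- pore$rho_s * 2 * pi * (pore$d_mean / 2)
  structure(list(
    r_grid = r, Psi = Psi,
    c_profiles = data.frame(r_nm = r, cation_M = c_plus, anion_M = c_minus),
    alpha = alpha, a_solv = a_solv,
    sigma_bulk = cond$sigma_bulk,
    charge_balance = if (q_wall != 0) abs(q_liquid + q_wall) / abs(q_wall) else 0,
    residual = residual, iterations = iterations, converged = converged
  ), class = "continuum_field")
}

#' @export
print.continuum_field <- function(x, ...) {
  cat(sprintf("radial PB field: %d points, alpha = %.3g, wall Psi = %.3f, axis Psi = %.3f\n",
              length(x$r_grid), x$alpha, x$Psi[length(x$Psi)], x$Psi[1]))
  cat(sprintf("  residual %.2g after %d Newton iterations; charge balance error %.2g\n",
              x$residual, x$iterations, x$charge_balance))
  invisible(x)
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Reduced-order pore conductance
#'
#' Series resistance integral over the bi-conical area profile plus the
#' standard disk access resistance against the aperture diameter at each
#' face, in parallel with the counter-ion surface conduction term
#' `g_surf = sigma_min d = 4 mu+ |rho_s|`:
#' \deqn{g = [R_{acc} + \int dz / (\sigma_{pore} A(z))]^{-1} + 4\mu^+ |\rho_s|}
#' `sigma_pore = D_eff_ratio * sigma_bulk` scales the in-pore conductivity by
#' the effective-to-bulk diffusivity ratio.
#'
#' @param pore A [pore_model()].
#' @param cond An [electrolyte_condition()].
#' @param D_eff_ratio In-pore to bulk diffusivity ratio in `[0, 1]`.
#' @return Conductance (S).
#' @export
reduced_conductance <- function(pore, cond, D_eff_ratio = 1) {
  stopifnot(inherits(pore, "pore_model"), inherits(cond, "electrolyte_condition"))
  if (D_eff_ratio < 0 || D_eff_ratio > 1) stop("D_eff_ratio must be in [0, 1]")
  a <- pore$d_mean / 2 * 1e-9               # waist radius, m
  t <- pore$t_mem * 1e-9
  b <- tan(pore$theta * pi / 180)
  if (a <= 0 || t <= 0) stop("degenerate pore geometry")
  sigma_pore <- cond$sigma_bulk * D_eff_ratio
  # bulk path: two frusta in series, R = 2 * int_0^{t/2} dz / (sigma pi r(z)^2)
  g_bulk <- 0
  if (sigma_pore > 0) {
    R_half <- if (b > 0) {
      (1 / (sigma_pore * pi * b)) * (1 / a - 1 / (a + b * t / 2))
    } else {
      (t / 2) / (sigma_pore * pi * a^2)
    }
    d_ap <- 2 * (a + b * t / 2)             # aperture diameter, m
    R_acc <- 1 / (2 * cond$sigma_bulk * d_ap)
    g_bulk <- 1 / (2 * R_half + 2 * R_acc)
  }
  mu_plus <- .get_ion(cond$cation)$mu_m2_per_Vs
  g_surf <- 4 * mu_plus * abs(pore$rho_s) * pn_constants$e * 1e18
  g_bulk + g_surf
}
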