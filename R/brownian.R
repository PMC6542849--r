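# One-dimensional Brownian-dynamics ion permeation: overdamped Langevin
# trajectories through a potential of mean force with an axial field,
# translocation bookkeeping, PMF and diffusivity estimators, and the
# average / instantaneous current definitions.

#' Brownian-dynamics ion transport
#'
#' Simulates a single ion along the pore axis with the overdamped Langevin
#' update `z <- z + (D/kBT) F(z) dt + sqrt(2 D dt) eta`, where
#' `F = -dW/dz + qE`. With absorbing boundaries the ion is re-injected at the
#' injection point after each absorption, mimicking one-at-a-time permeation;
#' absorptions at the far (+) and near (-) ends are recorded as signed
#' translocation events. Reflecting boundaries give an equilibrium trajectory
#' for PMF and diffusivity estimation.
#'
#' @param W Potential of mean force in kBT: a function of `z` (nm), or `NULL`
#'   for a flat landscape.
#' @param D Diffusivity (nm^2/ns), `> 0`.
#' @param E Axial electric field (V/nm).
#' @param q Ion charge (e).
#' @param box Axial extent `c(z_lo, z_hi)` (nm).
#' @param z_inj Injection/start position (nm); defaults to the box centre.
#' @param dt Time step (ns). The drift step must stay below 10% (and the
#'   diffusive step below 50%) of the resolution scale: the force-grid spacing
#'   when the force varies along the axis, otherwise a twentieth of the box.
#'   Violations are an error naming a stable dt.
#' @param n_steps Number of steps.
#' @param boundary `"absorbing"` (translocation counting) or `"reflecting"`
#'   (equilibrium sampling).
#' @param T Temperature (K).
#' @param n_grid Force-table resolution.
#' @param stride Record every `stride`-th position.
#' @return An object of class `transport_trajectory`: recorded `times` (ns)
#'   and `positions` (nm), an `events` data frame `(entry, exit, direction)`,
#'   and the run parameters.
#' @export
brownian_transport <- function(W = NULL, D = 1, E = 0, q = 1,
                               box = c(-2.5, 2.5), z_inj = mean(box),
                               dt = 1e-4, n_steps = 1e6,
                               boundary = c("absorbing", "reflecting"),
                               T = 298.15, n_grid = 512, stride = 10L) {
  boundary <- match.arg(boundary)
  if (D <= 0) stop("D must be > 0")
  zg <- seq(box[1], box[2], length.out = n_grid)
  h <- zg[2] - zg[1]
  Wg <- if (is.null(W)) rep(0, n_grid) else W(zg)
  if (any(!is.finite(Wg))) stop("W must be finite on the box")
  VT <- thermal_voltage(T)                     # volts
  # reduced force in 1/nm: -dW/dz (W in kBT) + qE/VT
  Fg <- -c(diff(Wg)[1], (Wg[3:n_grid] - Wg[1:(n_grid - 2)]) / 2,
           diff(Wg)[n_grid - 1]) / h + q * E / VT
  drift_step <- max(abs(Fg)) * D * dt
  diff_step <- sqrt(2 * D * dt)
  # resolution a step must not overshoot: the force grid when the force
  # varies (potential features), otherwise a twentieth of the box
  # (boundary resolution)
  scale <- if (diff(range(Fg)) > 0) h else diff(box) / 20
  if (drift_step > 0.1 * scale || diff_step > 0.5 * scale) {
    dt_drift <- if (max(abs(Fg)) > 0) 0.1 * scale / (max(abs(Fg)) * D) else Inf
    dt_diff <- (0.5 * scale)^2 / (2 * D)
    stop(sprintf("unstable time step dt = %.3g ns (drift step %.3g nm, diffusive step %.3g nm vs resolution %.3g nm); use dt <= %.3g ns",
                 dt, drift_step, diff_step, scale, min(dt_drift, dt_diff)))
  }
  res <- langevin_run(as.integer(n_steps), dt, D, Fg, box[1], box[2],
                      z_inj, if (boundary == "absorbing") 0L else 1L,
                      as.integer(stride))
  events <- data.frame(entry = res$entry, exit = res$exit,
                       direction = as.integer(res$direction))
  structure(list(
    times = res$times, positions = res$positions, events = events,
    dt = dt, stride = stride, total_time = n_steps * dt,
    D = D, E = E, q = q, T = T, box = box, z_inj = z_inj,
    boundary = boundary, W_grid = data.frame(z = zg, W = Wg)
  ), class = "transport_trajectory")
}

#' @export
print.transport_trajectory <- function(x, ...) {
  cat(sprintf("Brownian trajectory: %.4g ns (%s boundaries), D = %g nm^2/ns, E = %g V/nm, %d events\n",
              x$total_time, x$boundary, x$D, x$E, nrow(x$events)))
  invisible(x)
}

#' Potential of mean force from an equilibrium trajectory
#'
#' Boltzmann inversion of the stationary position density,
#' `W(z) = -log p(z)` (kBT), anchored to `W(z0) = 0`. Requires a
#' reflecting-boundary, zero-field trajectory; unvisited bins are an error.
#'
#' @param traj A `transport_trajectory`.
#' @param z0 Anchor position (nm); default the density mode (where the mean
#'   force vanishes).
#' @param n_bins Number of position bins.
#' @return A data frame `(z, W)` with `W` in kBT.
#' @export
pmf_from_trajectory <- function(traj, z0 = NULL, n_bins = 50) {
  stopifnot(inherits(traj, "transport_trajectory"))
  if (traj$boundary != "reflecting" || traj$E != 0)
    warning("PMF inversion assumes an equilibrium (reflecting, zero-field) trajectory")
  br <- seq(traj$box[1], traj$box[2], length.out = n_bins + 1)
  counts <- graphics::hist(traj$positions, breaks = br, plot = FALSE)$counts
  if (any(counts == 0)) {
    mid <- (br[-1] + br[-(n_bins + 1)]) / 2
    stop("unvisited position bins at z = ",
         paste(sprintf("%.3g", mid[counts == 0]), collapse = ", "))
  }
  z <- (br[-1] + br[-(n_bins + 1)]) / 2
  W <- -log(counts / sum(counts))
  if (is.null(z0)) z0 <- z[which.min(W)]
  W0 <- stats::approx(z, W, xout = z0, rule = 2)$y
  data.frame(z = z, W = W - W0)
}

#' Diffusivity from the mean square displacement
#'
#' Slope of the MSD over short lags, `D = MSD(t) / (2 t)` for one-dimensional
#' motion (the three-dimensional convention divides by `6 t`). Requires an
#' equilibrium trajectory on a flat landscape; lags are restricted to the
#' linear regime where the wall-affected sample fraction (of order
#' `sqrt(MSD)/L`) stays near the percent level. Record positions densely
#' (small `stride`) so enough lags survive the cut.
#'
#' @param traj A `transport_trajectory`.
#' @param n_lags Number of lags used in the fit.
#' @return Estimated diffusivity (nm^2/ns).
#' @export
msd_diffusivity <- function(traj, n_lags = 20) {
  stopifnot(inherits(traj, "transport_trajectory"))
  z <- traj$positions
  n <- length(z)
  if (n < 10 * n_lags) stop("trajectory too short for MSD estimation")
  dt_rec <- traj$dt * traj$stride
  L <- diff(traj$box)
  lags <- seq_len(n_lags)
  msd <- vapply(lags, function(k) mean((z[(k + 1):n] - z[1:(n - k)])^2), 0)
  # keep lags in the linear regime: the wall-affected fraction of samples is
  # ~ sqrt(msd)/L, so msd < 5e-4 L^2 keeps the boundary bias near 2%
  keep <- msd < 5e-4 * L^2
  if (sum(keep) < 3) keep <- seq_len(3)
  tt <- lags[keep] * dt_rec
  fit <- stats::lm(msd[keep] ~ tt)
  unname(stats::coef(fit)[2]) / 2
}

#' Average ionic current from translocation events
#'
#' `I = n e / t_total`: signed translocation count times the unit charge over
#' the simulation time (1 e/ns = 160.2 pA).
#'
#' @param events Events data frame `(entry, exit, direction)`.
#' @param total_time Total simulated time (ns), `> 0`.
#' @param q Charge per translocation (e).
#' @param signed Use the signed event count (net current); otherwise the
#'   total count.
#' @return Current (pA).
#' @export
average_current <- function(events, total_time, q = 1, signed = TRUE) {
  if (total_time <= 0) stop("total_time must be > 0")
  n <- if (signed) sum(events$direction) else nrow(events)
  n * q * pn_constants$e / (total_time * 1e-9) * 1e12
}

#' Instantaneous ionic current series
#'
#' One rectangular pulse per translocation event of height
#' `e / translocation time` over the event's duration, so the time integral
#' of the series returns exactly `n e`.
#'
#' @param events Events data frame `(entry, exit, direction)`.
#' @param q Charge per translocation (e).
#' @return A data frame `(t_start, t_end, I_pA)`, one row per event.
#' @export
instantaneous_current <- function(events, q = 1) {
  tau <- events$exit - events$entry
  data.frame(t_start = events$entry, t_end = events$exit,
             I_pA = events$direction * q * pn_constants$e / (tau * 1e-9) * 1e12)
}
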