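# Bi-conical pore geometry, occupancy, point-contact conductance,
# surface-charge inference and zero-intercept extrapolation fits.

#' Pore model
#'
#' Describes a bi-conical pore: elliptical waist axes, per-side cone
#' half-angle, membrane thickness and (negative) surface charge density.
#' Cone half-angles outside the observed 4-37 degree range are accepted with
#' a warning.
#'
#' @param d_minor,d_major Waist minor/major axes (nm), `0 < d_minor <= d_major`.
#' @param theta Cone half-angle per side (degrees).
#' @param t_mem Membrane thickness (nm), `> 0`.
#' @param rho_s Surface charge density (e nm^-2), `<= 0`.
#' @param pore_id Optional identifier.
#' @return An object of class `pore_model`.
#' @export
pore_model <- function(d_minor, d_major = d_minor, theta = 10, t_mem = 10,
                       rho_s = 0, pore_id = NULL) {
  if (d_minor <= 0 || d_major <= 0) stop("waist axes must be > 0")
  if (d_minor > d_major) stop("d_minor must be <= d_major")
  if (theta < 0 || theta >= 90) stop("cone half-angle must be in [0, 90)")
  if (theta < 4 || theta > 37)
    warning("cone half-angle ", theta, " degrees is outside the observed 4-37 degree range")
  if (t_mem <= 0) stop("membrane thickness must be > 0")
  if (rho_s > 0) stop("surface charge density must be <= 0")
  d_mean <- mean_waist_diameter(d_minor, d_major, digits = NULL)
  structure(list(
    pore_id = pore_id, d_minor = d_minor, d_major = d_major,
    d_mean = d_mean, theta = theta, t_mem = t_mem, rho_s = rho_s,
    Q_total = rho_s * biconical_wall_area(d_mean, theta, t_mem)
  ), class = "pore_model")
}

#' @export
print.pore_model <- function(x, ...) {
  cat(sprintf("pore %s: waist %.2f x %.2f nm (mean %.2f nm), theta %.1f deg, t %.1f nm, rho_s %.3g e/nm^2\n",
              if (is.null(x$pore_id)) "" else x$pore_id,
              x$d_minor, x$d_major, round(x$d_mean, 2), x$theta, x$t_mem, x$rho_s))
  invisible(x)
}

#' Mean waist diameter
#'
#' Geometric mean of the waist axes, reported rounded to two decimals by
#' default (pass `digits = NULL` for the raw value).
#'
#' @param d_minor,d_major Waist axes (nm), `0 < d_minor <= d_major`.
#' @param digits Decimal places for display rounding (round-half-even), or
#'   `NULL` to skip rounding.
#' @return Mean waist diameter (nm).
#' @export
mean_waist_diameter <- function(d_minor, d_major, digits = 2) {
  if (any(d_minor <= 0) || any(d_major <= 0)) stop("waist axes must be > 0")
  if (any(d_minor > d_major)) stop("d_minor must be <= d_major")
  d <- sqrt(d_minor * d_major)
  if (is.null(digits)) d else round(d, digits)
}

#' Bi-conical pore volume
#'
#' Volume of two equal conical frusta of height `t_mem/2` meeting at a waist
#' of radius `d_mean/2`, with the wall radius growing as
#' `r(z) = d_mean/2 + z tan(theta)`. At `theta = 0` this reduces exactly to
#' the cylinder `pi d^2 t / 4`.
#'
#' @param d_mean Mean waist diameter (nm), `> 0`.
#' @param theta Cone half-angle per side (degrees), in `[0, 90)`.
#' @param t_mem Membrane thickness (nm), `> 0`.
#' @return Pore volume (nm^3).
#' @export
biconical_volume <- function(d_mean, theta, t_mem) {
  if (any(d_mean <= 0) || any(t_mem <= 0)) stop("d_mean and t_mem must be > 0")
  if (any(theta < 0) || any(theta >= 90)) stop("cone half-angle must be in [0, 90)")
  h <- t_mem / 2
  r0 <- d_mean / 2
  r1 <- r0 + h * tan(theta * pi / 180)
  # frustum: pi h (r0^2 + r0 r1 + r1^2) / 3, two per pore
  2 * pi * h * (r0^2 + r0 * r1 + r1^2) / 3
}

# lateral wall area of the two frusta (for total surface charge)
biconical_wall_area <- function(d_mean, theta, t_mem) {
  h <- t_mem / 2
  r0 <- d_mean / 2
  r1 <- r0 + h * tan(theta * pi / 180)
  slant <- sqrt((r1 - r0)^2 + h^2)
  2 * pi * (r0 + r1) * slant
}

#' Expected ion occupancy of a pore
#'
#' Expected number of cations in the pore volume at bulk concentration `C`,
#' `N = C NA V`.
#'
#' @param V_pore Pore volume (nm^3), `>= 0`.
#' @param C Molar concentration (M), `>= 0`.
#' @return Expected cation count (dimensionless).
#' @export
expected_ion_count <- function(V_pore, C) {
  if (any(V_pore < 0) || any(C < 0)) stop("V_pore and C must be >= 0")
  # C [mol/L] * NA [1/mol] * V [nm^3] * 1e-24 [L/nm^3]
  C * pn_constants$N_A * V_pore * 1e-24
}

#' Point-contact conductance
#'
#' Conductance of an electrolytic point contact: an opening of diameter `d`
#' in a vanishingly thin membrane conducts `g = sigma d`.
#'
#' @param sigma Electrolyte conductivity (S m^-1), `>= 0`.
#' @param d_mean Pore diameter (nm), `>= 0`.
#' @return Conductance (S).
#' @export
point_contact_conductance <- function(sigma, d_mean) {
  if (any(sigma < 0) || any(d_mean < 0)) stop("sigma and d_mean must be >= 0")
  sigma * d_mean * 1e-9
}

#' Surface charge density from the minimum conductivity
#'
#' Inverts `sigma_min = 4 mu+ |rho_s| / d`, returning the (negative) surface
#' charge density.
#'
#' @param sigma_min Minimum conductivity (S m^-1), `> 0` (0 allowed, giving 0).
#' @param mu_plus Cation mobility (m^2 V^-1 s^-1), `> 0`.
#' @param d_mean Pore diameter (nm), `> 0`.
#' @return Surface charge density (e nm^-2), `<= 0`.
#' @export
surface_charge_from_min_conductivity <- function(sigma_min, mu_plus, d_mean) {
  if (any(sigma_min < 0)) stop("sigma_min must be >= 0")
  if (any(mu_plus <= 0) || any(d_mean <= 0)) stop("mu_plus and d_mean must be > 0")
  # |rho_s| [C/m^2] = sigma_min * d / (4 mu+); convert to e/nm^2
  rho_C_m2 <- sigma_min * (d_mean * 1e-9) / (4 * mu_plus)
  -rho_C_m2 / pn_constants$e * 1e-18
}

#' Minimum conductivity from surface charge
#'
#' Forward relation `sigma_min = 4 mu+ |rho_s| / d`.
#'
#' @param rho_s Surface charge density (e nm^-2), `<= 0`.
#' @inheritParams surface_charge_from_min_conductivity
#' @return Conductivity (S m^-1).
#' @export
min_conductivity_from_surface_charge <- function(rho_s, mu_plus, d_mean) {
  if (any(rho_s > 0)) stop("rho_s must be <= 0")
  if (any(mu_plus <= 0) || any(d_mean <= 0)) stop("mu_plus and d_mean must be > 0")
  4 * mu_plus * (abs(rho_s) * pn_constants$e * 1e18) / (d_mean * 1e-9)
}

# Noiseless inputs are legitimate here (synthetic oracles); keep stats's
# "essentially perfect fit" warning from spamming while letting others pass.
.quiet_perfect <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

# Weighted least-squares line with x-axis intercept and its standard error.
# Shared by the conductance, diffusivity and threshold-current extrapolations.
fit_x_intercept <- function(x, y, weights = NULL, xlab = "x", ylab = "y",
                            min_points = 3) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (!is.null(weights)) weights <- weights[ok]
  if (length(x) < min_points)
    stop("insufficient data: need at least ", min_points, " points, got ", length(x))
  if (length(unique(x)) < 2) stop("need at least two distinct ", xlab, " values")
  fit <- if (is.null(weights)) stats::lm(y ~ x) else stats::lm(y ~ x, weights = weights)
  b <- stats::coef(fit)
  V <- .quiet_perfect(stats::vcov(fit))
  slope <- unname(b[2]); intercept <- unname(b[1])
  flagged <- !is.finite(slope) || slope <= 0
  x0 <- -intercept / slope
  # delta method for var(-b0/b1)
  g <- c(-1 / slope, intercept / slope^2)
  se_x0 <- sqrt(max(0, drop(t(g) %*% V %*% g)))
  r2 <- .quiet_perfect(summary(fit)$r.squared)
  structure(list(
    x_intercept = x0, se_x_intercept = se_x0,
    slope = slope, se_slope = sqrt(V[2, 2]),
    intercept = intercept, se_intercept = sqrt(V[1, 1]),
    r_squared = r2, n = length(x), flagged = flagged,
    xlab = xlab, ylab = ylab, x = x, y = y, weights = weights,
    lm = fit
  ), class = "intercept_fit")
}

#' @export
print.intercept_fit <- function(x, ...) {
  cat(sprintf("weighted line %s ~ %s (n = %d): slope %.4g +/- %.2g, R^2 = %.3f\n",
              x$ylab, x$xlab, x$n, x$slope, x$se_slope, x$r_squared))
  cat(sprintf("  zero-%s %s-intercept: %.4g +/- %.2g%s\n",
              x$ylab, x$xlab, x$x_intercept, x$se_x_intercept,
              if (x$flagged) "  [flagged: nonpositive slope, extrapolation unreliable]" else ""))
  invisible(x)
}

#' @export
coef.intercept_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
plot.intercept_fit <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = x$xlab, ylab = x$ylab,
                 xlim = range(c(x$x, x$x_intercept)), ...)
  graphics::abline(x$intercept, x$slope, lty = 2)
  graphics::points(x$x_intercept, 0, pch = 4)
  invisible(x)
}

#' Zero-conductance diameter extrapolation
#'
#' Weighted least-squares line through (diameter, conductance) points; the
#' diameter at which the fitted line crosses zero conductance estimates the
#' de-hydrated ion size.
#'
#' @param d_mean Pore mean diameters (nm), at least 3 distinct values.
#' @param g Conductances (S or nS; the intercept is unit-free in `d`).
#' @param weights Optional fit weights.
#' @return An `intercept_fit` object; `$x_intercept` is the diameter (nm).
#' @export
fit_zero_conductance_diameter <- function(d_mean, g, weights = NULL) {
  fit_x_intercept(d_mean, g, weights, xlab = "diameter_nm", ylab = "conductance")
}

#' Zero-diffusivity diameter extrapolation
#'
#' As [fit_zero_conductance_diameter()] with effective in-pore diffusivities
#' on the ordinate.
#'
#' @param d_mean Pore mean diameters (nm).
#' @param D_eff Effective diffusivities (nm^2 ns^-1).
#' @param weights Optional fit weights.
#' @return An `intercept_fit` object.
#' @export
fit_zero_diffusivity_diameter <- function(d_mean, D_eff, weights = NULL) {
  fit_x_intercept(d_mean, D_eff, weights, xlab = "diameter_nm", ylab = "diffusivity")
}

#' Read or write a pore manifest
#'
#' Pores are exchanged as CSV rows with columns
#' `pore_id, d_minor_nm, d_major_nm, theta_deg, t_mem_nm, rho_s_e_per_nm2`.
#'
#' @param path File path.
#' @return `read_pore_manifest` returns a list of `pore_model` objects.
#' @export
read_pore_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    pore_model(df$d_minor_nm[i], df$d_major_nm[i], df$theta_deg[i],
               df$t_mem_nm[i], df$rho_s_e_per_nm2[i], pore_id = df$pore_id[i]))
}

#' @param pores List of `pore_model` objects.
#' @rdname read_pore_manifest
#' @export
write_pore_manifest <- function(pores, path) {
  df <- do.call(rbind, lapply(pores, function(p) data.frame(
    pore_id = if (is.null(p$pore_id)) NA else p$pore_id,
    d_minor_nm = p$d_minor, d_major_nm = p$d_major,
    theta_deg = p$theta, t_mem_nm = p$t_mem, rho_s_e_per_nm2 = p$rho_s)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
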