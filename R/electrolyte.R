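# Ion and electrolyte property models: registries, ionic strength, activity
# coefficients (extended Debye-Hueckel / Truesdell-Jones), Debye screening,
# Stokes mobility, Einstein diffusivity and an ideal-dilution conductivity.

# Extended Debye-Hueckel constants at 25 C.  B is applied as
# 0.3281 per-Angstrom per-sqrt(M) with the hydrated size a0 converted nm -> A.
.A_DH <- 0.5085   # M^(-1/2)
.B_DH <- 0.3281   # A^(-1) M^(-1/2)

# Built-in ion registry.
# a0 (hydrated-size activity parameter, nm) and b (1/M) for the cations follow
# the standard semi-empirical activity tabulation for these species; Cl- uses
# the conventional a0 = 0.3 nm with no linear term (salt-level gamma is taken
# from the cation, so Cl- parameters are never used downstream).
# De-hydrated diameters (nm): crystallographic estimates; Li+, Cs+, Cl- from
# Shannon effective ionic radii (x2).
# Limiting mobilities mu (m^2/V/s) from molar ionic conductivities at 25 C,
# mu_i = lambda_i / (|z_i| F); diffusivities D (nm^2/ns) via Nernst-Einstein.
.ion_table <- data.frame(
  name          = c("Li", "Na", "K", "Cs", "Mg", "Cl"),
  z             = c(1L, 1L, 1L, 1L, 2L, -1L),
  d_dehydrated_nm = c(0.152, 0.234, 0.298, 0.334, 0.144, 0.362),
  a0_nm         = c(0.38, 0.36, 0.33, 0.33, 0.43, 0.30),
  b_per_M       = c(0.2, 0.06, 0.01, 0.01, 0.21, 0.0),
  mu_m2_per_Vs  = c(4.01e-8, 5.19e-8, 7.62e-8, 8.01e-8, 5.49e-8, 7.91e-8),
  D_nm2_per_ns  = c(1.03, 1.33, 1.96, 2.06, 0.706, 2.03),
  stringsAsFactors = FALSE
)

.salt_table <- data.frame(
  salt     = c("NaCl", "KCl", "LiCl", "CsCl", "MgCl2"),
  cation   = c("Na", "K", "Li", "Cs", "Mg"),
  anion    = "Cl",
  n_anion  = c(1L, 1L, 1L, 1L, 2L),
  group    = c(1L, 1L, 1L, 1L, 2L),
  stringsAsFactors = FALSE
)

#' Ion registry
#'
#' Returns the registry of ion species used by the electrolyte models: valence,
#' de-hydrated diameter, the hydrated-size activity parameter `a0` and the
#' Truesdell-Jones linear coefficient `b`, limiting electrophoretic mobility
#' and bulk diffusivity.
#'
#' @param path Optional path to a tab-delimited registry file with columns
#'   `name, z, d_dehydrated_nm, a0_nm, b_per_M, mu_m2_per_Vs, D_nm2_per_ns`;
#'   overrides the built-in table.
#' @return A data frame, one row per ion.
#' @export
ion_registry <- function(path = NULL) {
  if (is.null(path)) return(.ion_table)
  reg <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- names(.ion_table)
  if (!all(need %in% names(reg)))
    stop("ion registry file must have columns: ", paste(need, collapse = ", "))
  if (any(reg$a0_nm <= 0) || any(reg$d_dehydrated_nm <= 0) || any(reg$b_per_M < 0))
    stop("invalid registry: a0 and d_dehydrated must be > 0, b >= 0")
  reg[, need]
}

#' Salt registry
#'
#' Supported electrolytes with their constituent ions and stoichiometry.
#' @return A data frame, one row per salt.
#' @export
salt_registry <- function() .salt_table

.get_ion <- function(name, registry = ion_registry()) {
  i <- match(name, registry$name)
  if (is.na(i)) stop("unknown ion: ", name)
  registry[i, ]
}

.get_salt <- function(salt) {
  i <- match(salt, .salt_table$salt)
  if (is.na(i)) stop("unknown salt: ", salt)
  .salt_table[i, ]
}

#' Ionic strength of a dissolved salt
#'
#' For the 1:1 (group I) salts the ionic strength equals the concentration;
#' for MgCl2 the divalent cation and doubled anion count give `I = 3 C`.
#'
#' @param C Molar concentration (M), `>= 0`.
#' @param salt Salt identifier (see [salt_registry()]).
#' @return Ionic strength (M).
#' @export
ionic_strength <- function(C, salt) {
  if (any(C < 0)) stop("concentration must be >= 0")
  s <- .get_salt(salt)
  if (s$group == 2L) 3 * C else C
}

#' Activity coefficient of an electrolyte
#'
#' Semi-empirical single-parameter-set activity coefficient,
#' `log10(gamma) = -A z^2 sqrt(I) / (1 + B a0 sqrt(I)) + b I`,
#' where the `b I` term is present only for the Truesdell-Jones (`"TJ"`)
#' variant and absent for extended Debye-Hueckel (`"EDH"`). The cation's
#' tabulated `a0` and `b` parameterize the salt. Constants are fixed at 25 C.
#'
#' @param C Molar concentration (M) in `[0, 2]`.
#' @param salt Salt identifier.
#' @param model `"TJ"` (default) or `"EDH"`.
#' @return Activity coefficient (dimensionless).
#' @export
activity_coefficient <- function(C, salt, model = c("TJ", "EDH")) {
  model <- match.arg(model)
  if (any(C < 0)) stop("concentration must be >= 0")
  s <- .get_salt(salt)
  ion <- .get_ion(s$cation)
  I <- ionic_strength(C, salt)
  sI <- sqrt(I)
  lg <- -.A_DH * ion$z^2 * sI / (1 + .B_DH * (10 * ion$a0_nm) * sI)
  if (model == "TJ") lg <- lg + ion$b_per_M * I
  10^lg
}

#' Electrolyte activity
#'
#' The effective reacting concentration `a = gamma * C`.
#'
#' @inheritParams activity_coefficient
#' @return Activity (M).
#' @export
activity <- function(C, salt, model = c("TJ", "EDH")) {
  activity_coefficient(C, salt, model) * C
}

#' Stokes mobility of an ion
#'
#' Hydrodynamic estimate `mu = z e / (3 pi eta d)` for a sphere of diameter
#' `d` in a solvent of viscosity `eta`.
#'
#' @param z Integer valence.
#' @param eta Solvent viscosity (Pa s), `> 0`.
#' @param d_i Ion diameter (m), `> 0`.
#' @return Electrophoretic mobility (m^2 V^-1 s^-1).
#' @export
stokes_mobility <- function(z, eta, d_i) {
  if (any(eta <= 0) || any(d_i <= 0)) stop("eta and d_i must be > 0")
  z * pn_constants$e / (3 * pi * eta * d_i)
}

#' Einstein diffusivity from mobility
#'
#' `D = kB T mu / e`.
#'
#' @param mu Electrophoretic mobility (m^2 V^-1 s^-1).
#' @param T Absolute temperature (K), `> 0`.
#' @return Diffusivity (m^2 s^-1).
#' @export
einstein_diffusivity <- function(mu, T = 298.15) {
  if (any(T <= 0)) stop("temperature must be > 0")
  pn_constants$kB * T * mu / pn_constants$e
}

#' Debye screening length
#'
#' `lambda_D = sqrt(eps_r eps0 kB T / (2 NA e^2 I))` with the ionic strength
#' `I` converted M -> mol m^-3.
#'
#' @param I_strength Ionic strength (M), `> 0`.
#' @param T Absolute temperature (K).
#' @param epsilon_r Relative permittivity of the solvent.
#' @return Debye length (nm).
#' @export
debye_length <- function(I_strength, T = 298.15, epsilon_r = 78.4) {
  if (any(I_strength <= 0)) stop("ionic strength must be > 0")
  num <- epsilon_r * pn_constants$eps0 * pn_constants$kB * T
  den <- 2 * pn_constants$N_A * pn_constants$e^2 * I_strength * 1000
  sqrt(num / den) * 1e9
}

#' Bulk electrolyte conductivity (ideal dilution)
#'
#' Kohlrausch sum `sigma = F sum_i |z_i| c_i mu_i` over the salt's ions with
#' their limiting mobilities; linear in concentration, so it is the
#' infinite-dilution estimate extrapolated to `C`.
#'
#' @param salt Salt identifier.
#' @param C Molar concentration (M), `>= 0`.
#' @return Conductivity (S m^-1).
#' @export
bulk_conductivity <- function(salt, C) {
  if (any(C < 0)) stop("concentration must be >= 0")
  s <- .get_salt(salt)
  cat_ion <- .get_ion(s$cation)
  an_ion <- .get_ion(s$anion)
  c_cat <- 1000 * C              # mol m^-3
  c_an <- 1000 * C * s$n_anion
  pn_constants$F * (abs(cat_ion$z) * c_cat * cat_ion$mu_m2_per_Vs +
                    abs(an_ion$z) * c_an * an_ion$mu_m2_per_Vs)
}

#' Electrolyte condition
#'
#' Bundles a salt at one concentration with its derived quantities: ionic
#' strength, activity coefficient and activity, Debye length and the
#' ideal-dilution bulk conductivity.
#'
#' @param salt Salt identifier.
#' @param C Molar concentration (M).
#' @param model Activity model, `"TJ"` or `"EDH"`.
#' @param T Absolute temperature (K).
#' @param eta Solvent viscosity (Pa s).
#' @param epsilon_r Relative permittivity.
#' @return An object of class `electrolyte_condition`.
#' @export
electrolyte_condition <- function(salt, C, model = "TJ", T = 298.15,
                                  eta = 0.89e-3, epsilon_r = 78.4) {
  if (C < 0) stop("concentration must be >= 0")
  s <- .get_salt(salt)
  I <- ionic_strength(C, salt)
  gamma <- activity_coefficient(C, salt, model)
  out <- list(
    salt = salt, cation = s$cation, C = C, model = model,
    I_strength = I, gamma = gamma, a = gamma * C,
    T = T, eta = eta, epsilon_r = epsilon_r,
    lambda_D = if (I > 0) debye_length(I, T, epsilon_r) else Inf,
    A_dh = .A_DH, B_dh = .B_DH,
    sigma_bulk = bulk_conductivity(salt, C)
  )
  class(out) <- "electrolyte_condition"
  out
}

#' @export
print.electrolyte_condition <- function(x, ...) {
  cat(sprintf("%s %.4g M (%s): I = %.4g M, gamma = %.3f, a = %.4g M\n",
              x$salt, x$C, x$model, x$I_strength, x$gamma, x$a))
  cat(sprintf("  lambda_D = %.3g nm, sigma_bulk = %.3g S/m (T = %.2f K)\n",
              x$lambda_D, x$sigma_bulk, x$T))
  invisible(x)
}
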