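---
title: "Methods: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porenoise)
```

This vignette records every model implemented by `porenoise`, the
parameter values it ships with, and the numerical decisions behind the
implementation, so that results can be audited without reading the source.

# 1. Electrolyte models

## Ionic strength and activity

For a salt at molar concentration $C$, the ionic strength is
$I = \tfrac12 \sum_i c_i z_i^2$: $I = C$ for the 1:1 salts (LiCl, NaCl,
KCl, CsCl) and $I = 3C$ for MgCl$_2$ (the only 2:1 salt in the registry).

The single-ion activity coefficient of the cation follows the
Truesdell–Jones (TJ) form,

$$\log_{10}\gamma = -\frac{A z^2 \sqrt{I}}{1 + B\, a_0 \sqrt{I}} + b\, I,$$

with $A = 0.5085\ \mathrm{M^{-1/2}}$ and
$B = 0.3281\ \mathrm{\unicode{x212B}^{-1} M^{-1/2}}$ at 25&nbsp;°C. The
extended Debye–Hückel (EDH) model is the same expression with $b = 0$, so
the two differ by exactly $10^{bI}$ — an identity the test suite checks for
every salt. The effective diameter $a_0$ is tabulated in nm and converted
to ångström ($\times 10$) inside the formula; with this convention
$B\,a_0$ for Na$^+$ is $0.3281 \times 3.6 = 1.181\ \mathrm{M^{-1/2}}$,
which reproduces the standard tabulated $\gamma_{\mathrm{Na}}(0.5\,\mathrm M)
\approx 0.68$. The activity used throughout is $a = \gamma C$.

Scope note: for LiCl the TJ salting-in term makes $\gamma > 1$ above
roughly 1.2&nbsp;M. The package's study designs stay at or below 1&nbsp;M,
and the invariant $\gamma \in (0, 1]$ is asserted only on $[0, 1]$&nbsp;M.

## Ion registry

`ion_registry()` tabulates, per ion: charge $z$; de-hydrated diameter
$d$ (nm); TJ parameters $a_0$ (nm) and $b$ (M$^{-1}$); electrophoretic
mobility $\mu$ (m$^2$/V·s); and diffusivity $D$ (nm$^2$/ns).

| ion | $z$ | $d$ (nm) | $a_0$ (nm) | $b$ (1/M) | $\mu$ (m²/V·s) | $D$ (nm²/ns) |
|-----|----:|---------:|-----------:|----------:|---------------:|-------------:|
| Li  | 1 | 0.152 | 0.38 | 0.20 | 4.01e-8 | 1.03 |
| Na  | 1 | 0.234 | 0.36 | 0.06 | 5.19e-8 | 1.33 |
| K   | 1 | 0.298 | 0.33 | 0.01 | 7.62e-8 | 1.96 |
| Cs  | 1 | 0.334 | 0.33 | 0.01 | 8.01e-8 | 2.06 |
| Mg  | 2 | 0.144 | 0.43 | 0.21 | 5.49e-8 | 0.706 |
| Cl  | -1 | 0.362 | 0.30 | 0.00 | 7.91e-8 | 2.03 |

Mobility and diffusivity are mutually consistent through the Einstein
relation $D = k_B T \mu / e$ (verified to 1% for Na$^+$ in the tests). The
registry can be overridden with a TSV file of the same columns; files with
missing columns, non-positive diameters, or unknown ions are rejected.

## Derived bulk quantities

* Debye length: $\lambda_D = \sqrt{\varepsilon \varepsilon_0 k_B T /
  (2 N_A e^2 I)}$, which gives the familiar $0.304/\sqrt{I}$ nm at
  25&nbsp;°C ($\varepsilon = 78.4$).
* Bulk conductivity (Kohlrausch): $\sigma = F \sum_i |z_i| c_i \mu_i$ with
  stoichiometric $c_i$ (two chlorides per MgCl$_2$).
* Stokes mobility $\mu = e /(3\pi\eta d_h)$ and Einstein diffusivity are
  available as standalone closed forms for hydrodynamic-radius estimates.

`electrolyte_condition(salt, C)` bundles $I$, $\gamma$, $a$, $\lambda_D$
and $\sigma$ into one classed object for downstream stages.

# 2. Pore geometry and transport

## Bi-conical pore model

A pore is modeled as two conical frusta joined at the waist: minor (waist)
diameter $d_\text{minor}$, cone half-angle $\theta$ and membrane thickness
$t_\text{mem}$. The volume is the sum of the two frusta,

$$V = 2 \cdot \frac{\pi h}{12}\left(d_\text{minor}^2 +
  d_\text{minor} d_\text{major} + d_\text{major}^2\right),
  \qquad h = t_\text{mem}/2,\quad
  d_\text{major} = d_\text{minor} + t_\text{mem}\tan\theta .$$

Reference values (checked against numerical quadrature of the revolution
integral in the tests): $d_\text{minor} = 0.35$ nm, $\theta = 5°$,
$t_\text{mem} = 10$ nm gives 5.4&nbsp;nm³; $0.97$ nm, $20°$, $10$ nm gives
69.8&nbsp;nm³.

The expected ion occupancy of that volume at concentration $C$ is
$N = C N_A V \times 10^{-24}$ (V in nm³, $C$ in mol/L): about 0.4 ions for
the small pore at 125 mM, and 21 for the large pore at 500 mM. These small
numbers are what make cooperative-motion noise observable.

## Point-contact conductance and double extrapolation

For a waist much smaller than the membrane thickness the pore behaves as an
electrolytic point contact: $g = \sigma d$, with $\sigma$ the local
conductivity and $d$ the waist diameter. Across pores of different sizes,
$g(d)$ is linear with an $x$-intercept at the diameter below which the ion
no longer fits — an independent estimate of the de-hydrated ion size.
`fit_zero_conductance_diameter` (and `fit_zero_diffusivity_diameter` for
simulated waist diffusivities) perform this extrapolation with standard
errors from the linear fit, flagging intercepts whose 2-SE interval
excludes the physical range. `run_conductance_sizing` applies it per salt
and averages across ions.

## Surface charge and reduced conductance

`surface_charge_from_min_conductivity` inverts the observed conductivity
floor at low salt into an effective wall charge density.
`reduced_conductance` combines bulk and surface contributions:
$g = \sigma_\text{bulk}\, d\, r_D + g_\text{surf}$ with
$g_\text{surf} = 4 \mu |\rho_s| e \times 10^{18}$ (checked exactly in the
limit where the effective-diffusivity ratio $r_D$ is 0), where $r_D$
accounts for reduced mobility in the confined waist.

# 3. Steric-modified Poisson–Boltzmann solver

`modified_pb_radial` solves the radially symmetric dimensionless PB
equation with Bikerman steric saturation inside a cylindrical pore of
radius $R$, charged wall boundary condition
$\Psi'(R) = e \sigma_s / (\varepsilon\varepsilon_0 k_B T) \times 10^{-9}$
(nm$^{-1}$) and symmetry $\Psi'(0) = 0$:

$$\frac{1}{r}\frac{d}{dr}\!\left(r \frac{d\Psi}{dr}\right)
 = \frac{1}{\lambda_D^2}\,
   \frac{\sinh\Psi}{1 + 2\nu \sinh^2(\Psi/2)},\qquad
 \nu = 2 a_\text{solv}^3 N_A C \times 10^{-24}.$$

Numerics:

* Second-order finite differences on a uniform grid (default
  `n_grid = 2000`), damped Newton iteration with an analytic Jacobian and a
  tridiagonal (Thomas) solve.
* **Convergence criterion.** Iteration stops when either the residual
  sup-norm or the Newton-step sup-norm falls below `tol` (default 1e-8).
  The step criterion exists because the residual is assembled with a
  $1/h^2$ factor that amplifies float rounding: at fine grids the residual
  has a floor near $10^{-8}$ even when the solution is converged to
  machine precision. Accepting a vanishing Newton step is the standard
  resolution.
* In the Debye–Hückel limit the solution must match the linearized form
  $\Psi = \text{bc}\,\lambda_D I_0(r/\lambda_D)/I_1(R/\lambda_D)$; the test
  suite checks this to 1%, and checks the full nonlinear solution against an
  independent shooting-method oracle (`deSolve::lsoda` + `uniroot`) to a
  sup-norm below $10^{-6}$. Observed convergence is second order:
  sup-norm errors of 5.4e-9 / 1.3e-9 / 2.7e-10 at `n_grid` 2000 / 4000 /
  8000.
* Global charge balance (wall charge vs integrated space charge) holds to
  $10^{-3}$ relative; steric saturation is monotone in $a_\text{solv}$.

# 4. Noise spectra

## Trace handling

`current_trace(i, fs, ...)` validates a current record (finite values,
positive sampling rate, warning below a configurable duration).
`expunge_settling` drops the first `t_settle` seconds, where capacitive
settling after a bias step contaminates the low-frequency spectrum. In the
default `analysis_config` `t_settle = 1` s; synthetic traces are generated
already settled, so the pipeline examples set `t_settle = 0`.

## Welch periodogram

`compute_psd` is a self-contained Welch estimator (no suitable
spectral-estimation package with the required conventions was available in
the target environment):

* Hann window, 50% overlap, per-segment mean removal.
* Segment length $L = 2^{\lceil \log_2(f_s / \texttt{df\_max}) \rceil}$ so
  that the frequency resolution is at least `df_max` (default 0.1 Hz).
* One-sided density in pA²/Hz, window-power normalized; the Nyquist bin is
  halved so that the integral of the PSD equals the variance (Parseval,
  verified to 1% and with a planted sinusoid landing in the right bin).
* Averaging is done on $\log P$ with the bias correction
  $\psi(m) - \log m$ (digamma), which removes the downward bias of the
  mean of log-$\chi^2$ periodogram ordinates; the white-noise level is
  then recovered without the $\approx -2.5$ dB offset a naive log-mean
  would produce.

## Spectral decomposition

`fit_decomposition` fits $S_I(f) = S_{1/f}/f + S_0 + S_1 f$:

1. $S_0$: geometric mean of the PSD over the white band (default 1–5 kHz).
   "Mean logarithmic PSD" is interpreted as the geometric mean; this
   interpretation is asserted in a dedicated test.
2. $S_{1/f}$: slope-constrained (exactly $-1$) weighted least squares on
   the positive excess $P - S_0$ over the pink band (default 0.1–100 Hz),
   with weights $w = f^{-1/2}$ so the lowest decade dominates 10:1 over
   the highest (asserted literally in a test). The crossover
   $f_\times = S_{1/f}/S_0$ is reported as a fixed point.
3. Pink presence is decided by AICc comparison of the two-component model
   against white-only, not by a hand-set amplitude threshold.
4. $S_1$ (dielectric rise) is fit only when the 5–50 kHz log–log slope
   exceeds 0.2; otherwise it is reported as 0 with `rise_present = FALSE`.
5. `fit_free_beta` refits the low band with a free exponent $\beta$ and
   flags traces outside $\beta \in [0.5, 1.6]$, where the $1/f$-slope
   constraint of step 2 would be unreliable.

The band edges and estimator choices above are *analysis-configuration
defaults* (all overridable through `analysis_config`), not physical claims.

# 5. Correlation thresholds and ion sizing

## Ensemble variance of correlated carriers

For $N$ carriers each contributing current variance $\sigma_1^2$, with
pairwise correlation $\xi$,

$$\mathrm{Var}\!\left(\sum_i I_i\right)
 = N \sigma_1^2 + N(N-1)\,\xi\,\sigma_1^2 ,$$

so the normalized noise power $\mathrm{Var}/I_0^2$ falls as $1/N$ when
$\xi = 0$ and is flat in $N$ when $\xi = 1$. `ensemble_variance` is tested
against a brute-force double-sum covariance oracle for $N = 1..20$ and
$\xi \in \{0, 0.25, 0.5, 1\}$.

## Threshold fitting

`fit_threshold` works in $(x, y) = (\log_{10} I_0^2,\ \log_{10}
S_{1/f}/I_0^2)$, where uncorrelated shot-like noise is a line of slope
$-1$ and the cooperative regime is a plateau:

* Branch 1: slope fixed at $-1$, intercept $c_1$ fit (equivalently
  $\sigma_<$ at $I_0 = 1$ pA). Branch 2: plateau $c_2$ ($\sigma_>$).
* The split point is chosen by scanning all contiguous partitions with at
  least two points per branch; the threshold is the fixed-point
  intersection $I_T = \sqrt{10^{\,c_1 - c_2}}$.
* Presence is decided by AICc (piecewise, $k = 3$, vs single line,
  $k = 1$), and additionally requires $I_T$ inside the observed $I_0$
  range — an extrapolated intersection is reported as "no threshold".
* Data requirements: at least 6 points spanning at least 1.5 decades in
  $I_0$; violations raise informative errors.

## Double extrapolation to the ion diameter

Per pore, thresholds $I_T(a)$ across concentrations are extrapolated
linearly in activity to $a = 0$ (`zero_activity_threshold`). The
zero-activity thresholds of several pores then define a line in pore
diameter whose $x$-intercept is the de-hydrated ion diameter
(`ion_diameter_from_thresholds`). Both fits carry standard errors and
$R^2$; pores with fewer than 3 usable activities are dropped with a
warning, and a pore with no detected threshold at a given condition simply
contributes no point at that condition (it is not imputed). If all pores
drop, the pipeline stops with an error rather than reporting a
low-confidence number.

When per-point uncertainties are unavailable or degenerate, fits fall
back to uniform weights rather than failing.

# 6. Synthetic-data generator

`experiment_plan` + `gen_experiment` plant a known ion diameter and
generate the complete study the analysis pipeline expects.

## Planted laws

* Conductance: point contact, $g = \sigma_\text{bulk}(C)\, d$.
* Threshold: $I_T(a, d) = s_\text{slope}\,(d - d_\text{ion,true})\,
  (1 + k_\text{activity}\, a)$. The linear dependence on diameter and
  activity is a *modeling choice* of the generator — it is the simplest
  law with the right zero crossing and monotonicity, chosen so that the
  double extrapolation is exact in the noiseless limit. It is not a claim
  about real pores.
* Noise: each trace is white ($S_0$) plus pink with amplitude $S_{1/f}$
  log-blended between the sub-threshold branch
  $\sigma_< = c_0 N\,\sigma_1^2$ and the plateau
  $\sigma_> I_0^2 = (\sigma_</I_T^2)\, I_0^2$, with a logistic crossover
  of width `xi_width` (default 0.025) in $\log_{10} I_0$ — i.e. the
  generator realizes exactly the piecewise law the analysis fits, with a
  smooth rather than kinked transition.
* Pink noise is synthesized in the frequency domain with
  $1/f^{\beta}$-shaped amplitudes ($\beta = 1$ by default) and random
  phases; white noise is i.i.d. Gaussian.

## Default study design and rationale

Per salt: 5 pores (waists 0.35, 0.47, 0.52, 0.72, 0.82 nm), 4
concentrations (0.125–1 M), and 14 biases log-spaced over 0.002–0.6 V;
$f_s = 12.8$ kHz, $2^{17}$ samples (≈10.2 s) per trace. The bias range is
log-spaced so that $I_0^2$ spans > 1.5 decades at every condition (the
`fit_threshold` requirement), and its lower end (2 mV) is set so that the
smallest currents sit below the planted threshold even for MgCl$_2$, whose
roughly 2× higher conductivity otherwise pushes $\min I_0$ above $I_T$ for
small pores and makes the threshold unbracketable. Traces are generated
settled (no capacitive transient), so pipeline examples run with
`t_settle = 0`.

## Reproducibility contract

* `gen_experiment` is pure given the plan: each trace uses the derived
  seed `(plan$seed * 10007 + i) mod .Machine$integer.max`, so traces are
  bit-identical across runs and insensitive to generation order, and the
  caller's RNG state is restored on exit.
* `write_experiment` emits two-column (time, current) text files plus a
  manifest CSV; analyzing the written files agrees with analyzing the
  in-memory experiment to text-I/O precision (1e-3 relative), since the
  sampling rate is re-derived from the time column.

# 7. Brownian dynamics

`brownian_transport` integrates overdamped Langevin dynamics for a single
ion on a 1-D potential of mean force $W(z)$ (kBT units) with an applied
field, using an Rcpp stepper driven by R's RNG (`norm_rand`), so
`set.seed()` governs trajectories:

$$z_{t+\Delta t} = z_t + \frac{D}{k_BT}F(z_t)\,\Delta t +
  \sqrt{2 D \Delta t}\,\eta_t .$$

* Boundaries: *absorbing* records a signed translocation event and
  re-injects at the center; *reflecting* mirrors properly
  ($z \to 2 z_\text{hi} - z$).
* **Stability guard.** The step is rejected up front if the deterministic
  drift exceeds $0.1\times$ or the diffusive step $0.5\times$ a resolution
  scale: the force-grid spacing $h$ when the force varies, otherwise
  (flat landscapes) box/20. The error message names a stable `dt`.
* `pmf_from_trajectory` recovers $W(z)$ as $-\log$ histogram; recovery to
  0.25 kBT needs enough barrier-crossing events (the test integrates
  ≈1000 ns for a 1.5 kBT well).
* `msd_diffusivity` estimates $D$ from the MSD slope with denominator
  $2t$ (1-D). Lags are truncated where $\mathrm{MSD} > 5\times10^{-4}
  L^2$ ($L$ = box length): beyond that, confinement biases the slope by
  roughly $\sqrt{\mathrm{MSD}}/L \sim 2\%$. If no lag passes, the first 3
  lags are used.
* `average_current` converts signed events to pA:
  $e\,(n_+ - n_-)/t_\text{total}$; 10 net events in 100 ns is
  16.02177 pA (tested exactly). Charge conservation
  ($\sum$ signed events = net charge) is asserted on every run.
* Rate sanity: escape rates over a barrier agree within a factor 1.5 with
  a mean-first-passage-time finite-difference oracle, and decrease with
  barrier height.

Field-mirror symmetry ($E \to -E$) holds distributionally, not per draw
(noise is not negated), so it is tested statistically
($|n_+ + n_-'| < 4\sqrt{n_\text{tot}}$).

# 8. Pipeline and configuration

`analysis_config` collects every tunable (bands, `df_max`, `t_settle`,
activity model, weighting policy, AICc margins, data-requirement
thresholds) with validation and exact round-tripping. `run_ion_sizing`
accepts either an in-memory experiment or a manifest CSV path
(`trace_path, pore_id, salt, C_M, V_bias, fs`), runs
trace → PSD → decomposition → threshold → zero-activity →
zero-diameter, and returns an `ion_size_report` with per-trace,
per-threshold, per-pore and per-ion tables. It is deterministic for fixed
inputs and validates manifests with explicit error messages (missing
columns, unreadable trace files).

# 9. Interpretation conventions and limitations

Choices that could be made more than one way, and how this package makes
them:

* $B$ is taken as $0.3281$ Å$^{-1}$M$^{-1/2}$ with $a_0$ tabulated in nm
  and converted internally (so $B a_0 \approx 1.2$ M$^{-1/2}$ for Na$^+$).
* MgCl$_2$ differs from the 1:1 salts only through $I = 3C$, $z = 2$ in
  the activity formula, and stoichiometric conductivity; no ion-pairing
  correction is applied.
* "Mean logarithmic PSD" for the white level means the geometric mean.
* Pores without a detectable threshold at a condition contribute no point;
  they are never imputed.
* The point-contact law uses the waist (aperture) diameter; access
  resistance is absorbed into the effective $\sigma$.
* The noise-band edges and estimator settings are configuration defaults,
  not physical constants.

Out of scope: electro-osmotic flow, Grotthuss proton transport, binary
acquisition formats, 3-D simulation. All I/O is plain text.
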