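# porenoise

Measuring de-hydrated ion sizes from sub-nanopore current recordings.

A sub-nanopore — a pore with a waist below 1 nm in a thin solid-state
membrane — acts as an electrolytic point contact whose conductance scales
linearly with its diameter, `g = σ·d`. When the open-pore current `I0` is
raised past a threshold `I_T`, the low-frequency (pink, `1/f`) current noise
stops falling as `1/I0²` and becomes current-independent: the few ions
occupying the waist start moving cooperatively. Extrapolating that threshold
to zero electrolyte activity, and then the zero-activity threshold to zero
pore diameter, yields an estimate of the *de-hydrated* ion diameter — the
bare-ion size, without its water shell. `porenoise` implements the full
chain, a reduced-order transport model, a steric-modified Poisson-Boltzmann
solver, a Brownian-dynamics stand-in for molecular simulation, and a
synthetic-data generator with planted ground truth for end-to-end
validation.

## What is in the box

| Area | Functions |
| --- | --- |
| Electrolytes | `ion_registry`, `salt_registry`, `ionic_strength`, `activity_coefficient` (Truesdell-Jones / extended Debye-Hückel), `activity`, `debye_length`, `bulk_conductivity`, `stokes_mobility`, `einstein_diffusivity`, `electrolyte_condition` |
| Pore & transport | `pore_model`, `biconical_volume`, `expected_ion_count`, `point_contact_conductance`, `surface_charge_from_min_conductivity`, `reduced_conductance`, `modified_pb_radial` (steric/Bikerman PB), `fit_zero_conductance_diameter`, `fit_zero_diffusivity_diameter` |
| Noise spectra | `current_trace`, `expunge_settling`, `compute_psd` (Welch), `fit_decomposition` (`S_I = S_1f/f + S_0 + S_1·f`), `fit_free_beta` |
| Correlation thresholds | `ensemble_variance`, `normalized_noise_power`, `fit_threshold`, `zero_activity_threshold`, `ion_diameter_from_thresholds` |
| Synthetic data | `gen_pink_noise`, `gen_white_noise`, `gen_correlated_carriers`, `experiment_plan`, `gen_experiment`, `write_experiment` |
| Brownian dynamics | `brownian_transport` (Rcpp Langevin stepper), `pmf_from_trajectory`, `msd_diffusivity`, `average_current`, `instantaneous_current` |
| Pipeline | `analysis_config`, `run_ion_sizing`, `run_conductance_sizing` |

Fit stages return classed S3 objects (`psd`, `spectral_decomposition`,
`threshold_fit`, `intercept_fit`, `ion_size_report`, …) with `print`,
`coef`, `plot` and `summary` methods where natural.

## Worked example

Generate a synthetic study with a planted ion diameter and recover it:

```r
library(porenoise)

plan <- experiment_plan("NaCl", d_ion_true = 0.22, seed = 42)
experiment <- gen_experiment(plan)   # 280 traces: 5 pores x 4 conc x 14 biases
report <- run_ion_sizing(experiment, analysis_config(t_settle = 0))
report
#> ion-size report (correlated-noise thresholds)
#>   traces: 280; threshold fits: 20 (20 with threshold); pores sized: 5
#>   NaCl (Na+): d_ion = 0.216 +/- 0.007 nm (R^2 = 0.996, 5 pores)
```

Each stage is usable on its own:

```r
cond <- electrolyte_condition("NaCl", 0.25)
cond
#> NaCl 0.25 M (TJ): I = 0.25 M, gamma = 0.716, a = 0.1791 M
#>   lambda_D = 0.608 nm, sigma_bulk = 3.16 S/m (T = 298.15 K)

biconical_volume(0.35, 5, 10)          # 5.37 nm^3
expected_ion_count(5.37, 0.125)        # ~0.4 ions in the pore

tr  <- experiment$traces[[200]]
dec <- fit_decomposition(compute_psd(tr))
coef(dec)                              # S_1f, S_0, S_1
```

A single-ion Brownian-dynamics run through a 1.5 kBT barrier:

```r
W <- function(z) 1.5 * exp(-z^2 / (2 * 0.5^2))
set.seed(1)
traj <- brownian_transport(W = W, D = 1.33, E = 0.1, box = c(-2.5, 2.5),
                           n_grid = 64, dt = 5e-4, n_steps = 1e6)
average_current(traj$events, traj$total_time)   # pA
```

## Scope

No GUI, no live acquisition, no ABF parsing: traces are exchanged as
two-column text plus a manifest CSV (`trace_path, pore_id, salt, C_M,
V_bias, fs`). Electro-osmotic flow and Grotthuss proton transport are out
of scope.
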