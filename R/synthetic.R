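# Synthetic data: pink/white noise traces via spectral synthesis, exactly
# correlated carrier ensembles, and full multi-condition experiments with a
# planted ion diameter.

# run expr with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate pink (1/f^beta) Gaussian noise
#'
#' Spectral synthesis: Fourier amplitudes drawn with expected one-sided PSD
#' `S1Hz * f^(-beta)`, random phases, zeroed DC. The same seed yields a
#' bit-identical trace.
#'
#' @param n_samples Trace length (powers of two are fastest).
#' @param fs Sampling rate (Hz).
#' @param S1Hz PSD amplitude at 1 Hz (pA^2/Hz), `>= 0`.
#' @param beta Spectral exponent in `[0, 2]`.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return Numeric vector of `n_samples` currents (pA), zero mean in
#'   expectation.
#' @export
gen_pink_noise <- function(n_samples, fs, S1Hz, beta = 1, seed = NULL) {
  if (S1Hz < 0) stop("S1Hz must be >= 0")
  if (beta < 0 || beta > 2) stop("beta must be in [0, 2]")
  if (S1Hz == 0) return(numeric(n_samples))
  with_seed(seed, {
    n <- n_samples
    nf <- n %/% 2
    f <- (1:nf) * fs / n
    # E|X_k|^2 = S(f) fs n / 2 so that the periodogram 2|X|^2/(fs n) = S(f)
    sd_k <- sqrt(S1Hz * f^(-beta) * fs * n / 4)
    re <- stats::rnorm(nf) * sd_k
    im <- stats::rnorm(nf) * sd_k
    X <- complex(real = re, imaginary = im)
    if (n %% 2 == 0) X[nf] <- complex(real = sqrt(2) * re[nf], imaginary = 0)
    full <- complex(length.out = n)
    full[2:(nf + 1)] <- X
    full[n:(n - nf + 2)] <- Conj(X[seq_len(nf - 1)])
    Re(stats::fft(full, inverse = TRUE)) / n
  })
}

#' Generate white Gaussian noise
#'
#' Samples with one-sided PSD level `S0`, i.e. `sd = sqrt(S0 fs / 2)`.
#'
#' @inheritParams gen_pink_noise
#' @param S0 One-sided PSD level (pA^2/Hz), `>= 0`.
#' @return Numeric vector of `n_samples` currents (pA).
#' @export
gen_white_noise <- function(n_samples, fs, S0, seed = NULL) {
  if (S0 < 0) stop("S0 must be >= 0")
  if (S0 == 0) return(numeric(n_samples))
  with_seed(seed, stats::rnorm(n_samples, sd = sqrt(S0 * fs / 2)))
}

#' Generate a correlated-carrier ensemble trace
#'
#' Each carrier current is `i_n(t) = i_single + sqrt(xi) s(t) +
#' sqrt(1 - xi) e_n(t)` with `s` and `e_n` independent zero-mean white
#' processes of variance `var_single`, so every pair of carriers correlates
#' at exactly `xi` and the summed trace has variance
#' `var_single [N + N(N-1) xi]` in expectation.
#'
#' @param N Carrier count, integer `>= 1`.
#' @param i_single Single-carrier mean current (pA).
#' @param var_single Single-carrier variance (pA^2).
#' @param xi Pairwise correlation in `[0, 1]`.
#' @param n_samples Trace length.
#' @param fs Sampling rate (Hz).
#' @param seed Optional seed.
#' @param return_carriers If `TRUE`, also return the `N x n_samples` matrix
#'   of per-carrier currents.
#' @return The summed trace (pA), or a list `(trace, carriers)` when
#'   `return_carriers = TRUE`.
#' @export
gen_correlated_carriers <- function(N, i_single, var_single, xi, n_samples, fs,
                                    seed = NULL, return_carriers = FALSE) {
  if (N < 1 || N != round(N)) stop("N must be an integer >= 1")
  if (xi < 0 || xi > 1) stop("xi must be in [0, 1]")
  if (var_single < 0) stop("var_single must be >= 0")
  with_seed(seed, {
    sdv <- sqrt(var_single)
    s <- stats::rnorm(n_samples, sd = sdv)
    if (return_carriers) {
      E <- matrix(stats::rnorm(N * n_samples, sd = sdv), nrow = N)
      carriers <- i_single + sqrt(xi) * rep(1, N) %o% s + sqrt(1 - xi) * E
      list(trace = colSums(carriers), carriers = carriers)
    } else {
      u <- stats::rnorm(n_samples, sd = sdv)     # == sum of e_n / sqrt(N)
      N * i_single + N * sqrt(xi) * s + sqrt((1 - xi) * N) * u
    }
  })
}

#' Experiment plan for the synthetic ion-sizing study
#'
#' Defines the conditions of a planted-truth experiment: one salt measured
#' across pores and concentrations at several biases, with the threshold
#' current following `I_T = s_slope (d - d_ion_true)(1 + k_activity a)` —
#' vanishing at the planted ion diameter, increasing with pore diameter and
#' with activity — and the carrier correlation switching 0 -> 1 across the
#' threshold as a narrow logistic in `log10 I0` (width ~0.1 decade).
#'
#' @param salt Salt identifier.
#' @param d_ion_true Planted ion diameter (nm), `< min(diameters)`.
#' @param diameters Pore mean waist diameters (nm).
#' @param concentrations Molar concentrations (M).
#' @param voltages Bias voltages (V).
#' @param theta,t_mem Pore cone half-angle (deg) and membrane thickness (nm).
#' @param s_slope Diameter sensitivity of the threshold (pA/nm).
#' @param k_activity Activity sensitivity (1/M).
#' @param S0 White noise floor (pA^2/Hz).
#' @param var_single Single-carrier variance (pA^2).
#' @param c0 Pink-amplitude scale per carrier (1/Hz): below threshold
#'   `S_1f = c0 N var_single` (uncorrelated sum), above it grows to
#'   `c0 N var_single (I0 / I_T)^2` (the correlated `N^2` limit expressed
#'   through the plateau `sigma_> = sigma_< / I_T^2`).
#' @param beta Pink exponent of the synthesized traces.
#' @param fs Sampling rate (Hz).
#' @param n_samples Samples per trace.
#' @param xi_width Logistic width of the correlation switch (decades of I0).
#' @param activity_model Activity model used for the planted law.
#' @param seed Integer seed recorded in every output.
#' @return An object of class `experiment_plan`.
#' @export
experiment_plan <- function(salt, d_ion_true,
                            diameters = c(0.35, 0.47, 0.52, 0.72, 0.82),
                            concentrations = c(0.125, 0.25, 0.5, 1),
                            voltages = exp(seq(log(0.002), log(0.6), length.out = 14)),
                            theta = 10, t_mem = 10,
                            s_slope = 300, k_activity = 1,
                            S0 = 1e-4, var_single = 1, c0 = 0.01,
                            beta = 1, fs = 12800, n_samples = 2^17,
                            xi_width = 0.025, activity_model = "TJ",
                            seed = 1L) {
  if (length(diameters) == 0 || length(concentrations) == 0 || length(voltages) == 0)
    stop("diameters, concentrations and voltages must be non-empty")
  if (d_ion_true >= min(diameters))
    stop("planted d_ion_true must be smaller than every pore diameter")
  .get_salt(salt)
  structure(list(
    salt = salt, d_ion_true = d_ion_true, diameters = diameters,
    concentrations = concentrations, voltages = voltages,
    theta = theta, t_mem = t_mem, s_slope = s_slope, k_activity = k_activity,
    S0 = S0, var_single = var_single, c0 = c0, beta = beta,
    fs = fs, n_samples = n_samples, xi_width = xi_width,
    activity_model = activity_model, seed = as.integer(seed)
  ), class = "experiment_plan")
}

#' Generate a synthetic ion-sizing experiment
#'
#' Produces one voltage-clamp trace per (diameter, concentration, voltage)
#' condition of the plan. The mean current follows the point-contact law
#' `I0 = sigma(C) d V`; the carrier count is the expected pore occupancy;
#' the pink amplitude follows the correlated-carrier model around the planted
#' threshold law (see [experiment_plan()]). Output is a pure function of
#' `(plan, seed)` and the manifest embeds the per-trace seeds.
#'
#' @param plan An [experiment_plan()].
#' @return An object of class `noise_experiment`: a list of
#'   [current_trace()]s plus a manifest data frame with the planted truth.
#' @export
gen_experiment <- function(plan) {
  stopifnot(inherits(plan, "experiment_plan"))
  grid <- expand.grid(V = plan$voltages, C = plan$concentrations,
                      d = plan$diameters, KEEP.OUT.ATTRS = FALSE)
  traces <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    d <- grid$d[i]; C <- grid$C[i]; V <- grid$V[i]
    cond <- electrolyte_condition(plan$salt, C, model = plan$activity_model)
    g <- point_contact_conductance(cond$sigma_bulk, d)          # S
    I0 <- g * V * 1e12                                          # pA
    N <- expected_ion_count(biconical_volume(d, plan$theta, plan$t_mem), C)
    I_T <- plan$s_slope * (d - plan$d_ion_true) * (1 + plan$k_activity * cond$a)
    sigma_lt <- plan$c0 * N * plan$var_single
    sigma_gt <- sigma_lt / I_T^2
    if (I0 > 0) {
      xi_eff <- stats::plogis((log10(I0) - log10(I_T)) / plan$xi_width)
      S1f <- 10^((1 - xi_eff) * log10(sigma_lt) + xi_eff * log10(sigma_gt * I0^2))
    } else {
      xi_eff <- 0
      S1f <- sigma_lt
    }
    tr_seed <- (plan$seed * 10007L + i) %% .Machine$integer.max
    x <- I0 +
      gen_pink_noise(plan$n_samples, plan$fs, S1f, plan$beta, seed = tr_seed) +
      gen_white_noise(plan$n_samples, plan$fs, plan$S0, seed = tr_seed + 1L)
    pore_id <- sprintf("pore_d%0.2f", d)
    trace_id <- sprintf("%s_%s_C%g_V%.4f", plan$salt, pore_id, C, V)
    traces[[i]] <- current_trace(x, plan$fs, v_bias = V,
                                 trace_id = trace_id, settled = TRUE,
                                 warn_duration = FALSE)
    rows[[i]] <- data.frame(
      trace_id = trace_id, pore_id = pore_id, salt = plan$salt,
      d_mean_nm = d, C_M = C, a_M = cond$a, V_bias = V,
      I0_true_pA = I0, N_carriers = N, I_T_true_pA = I_T,
      S1f_true = S1f, S0_true = plan$S0, xi_true = xi_eff,
      seed = tr_seed, stringsAsFactors = FALSE
    )
  }
  manifest <- do.call(rbind, rows)
  structure(list(traces = stats::setNames(traces, manifest$trace_id),
                 manifest = manifest, plan = plan),
            class = "noise_experiment")
}

#' @export
print.noise_experiment <- function(x, ...) {
  cat(sprintf("synthetic noise experiment: %s, %d traces (%d pores x %d concentrations x %d biases), planted d_ion = %.2f nm, seed %d\n",
              x$plan$salt, nrow(x$manifest), length(x$plan$diameters),
              length(x$plan$concentrations), length(x$plan$voltages),
              x$plan$d_ion_true, x$plan$seed))
  invisible(x)
}

#' Write a synthetic experiment to disk
#'
#' Emits one two-column text trace file per condition plus a manifest CSV
#' with columns `trace_path, pore_id, salt, C_M, V_bias, fs` and the planted
#' truth columns.
#'
#' @param experiment A `noise_experiment`.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "noise_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  man <- experiment$manifest
  man$trace_path <- file.path(dir, paste0(man$trace_id, ".txt"))
  man$fs <- experiment$plan$fs
  for (i in seq_len(nrow(man)))
    write_trace_text(experiment$traces[[man$trace_id[i]]], man$trace_path[i])
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, path, row.names = FALSE)
  invisible(path)
}
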