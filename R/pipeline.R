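# Orchestration: configuration, the four-step ion-sizing pipeline
# (expunge -> PSD -> decomposition -> threshold fit -> zero-activity
# extrapolation -> diameter extrapolation) and conductance-based sizing.

#' Analysis configuration
#'
#' Collects the tunable options of the ion-sizing pipeline. Round-trips
#' losslessly through `unclass()`/[analysis_config()].
#'
#' @param df_max PSD frequency resolution bound (Hz).
#' @param s0_band White-level band (Hz).
#' @param pink_fmax_init Initial pink-fit upper edge (Hz).
#' @param beta_band Free-exponent diagnostic band (Hz).
#' @param tol Fixed-point tolerance of the piecewise fits.
#' @param max_iter Iteration budget of the piecewise fits.
#' @param activity_model `"TJ"` or `"EDH"` for the activity abscissa.
#' @param weights_policy `"uniform"` or `"inverse_variance"` weights for the
#'   linear extrapolations (inverse-variance falls back to uniform when no
#'   variance estimates are available).
#' @param t_settle Settling seconds expunged from unsettled traces.
#' @param min_activities Minimum distinct activities per pore (pores below
#'   this are dropped with a warning).
#' @param seed Seed for resampling diagnostics (unused by the deterministic
#'   pipeline itself).
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(df_max = 0.1, s0_band = c(1000, 5000),
                            pink_fmax_init = 100, beta_band = c(0.1, 100),
                            tol = 1e-3, max_iter = 50,
                            activity_model = c("TJ", "EDH"),
                            weights_policy = c("uniform", "inverse_variance"),
                            t_settle = 15, min_activities = 3L, seed = NULL) {
  stopifnot(df_max > 0, tol > 0, max_iter > 0, t_settle >= 0)
  structure(list(
    df_max = df_max, s0_band = s0_band, pink_fmax_init = pink_fmax_init,
    beta_band = beta_band, tol = tol, max_iter = max_iter,
    activity_model = match.arg(activity_model),
    weights_policy = match.arg(weights_policy),
    t_settle = t_settle, min_activities = as.integer(min_activities),
    seed = seed
  ), class = "analysis_config")
}

# resolve a dataset argument into (traces list, manifest data.frame)
.resolve_dataset <- function(dataset) {
  if (inherits(dataset, "noise_experiment"))
    return(list(traces = dataset$traces, manifest = dataset$manifest))
  if (is.character(dataset) && length(dataset) == 1)
    dataset <- utils::read.csv(dataset, stringsAsFactors = FALSE)
  if (is.data.frame(dataset)) {
    need <- c("trace_path", "pore_id", "salt", "C_M", "V_bias", "fs")
    if (!all(need %in% names(dataset)))
      stop("manifest must have columns: ", paste(need, collapse = ", "))
    traces <- list()
    for (i in seq_len(nrow(dataset))) {
      if (!file.exists(dataset$trace_path[i]))
        stop("unreadable trace file: ", dataset$trace_path[i])
      tr <- read_trace_text(dataset$trace_path[i],
                            v_bias = dataset$V_bias[i],
                            warn_duration = FALSE)
      tr$trace_id <- if ("trace_id" %in% names(dataset)) dataset$trace_id[i]
                     else basename(dataset$trace_path[i])
      traces[[tr$trace_id]] <- tr
    }
    man <- dataset
    if (!"trace_id" %in% names(man)) man$trace_id <- names(traces)
    if (!"d_mean_nm" %in% names(man))
      stop("manifest must carry the pore mean diameter as d_mean_nm")
    return(list(traces = traces, manifest = man))
  }
  stop("dataset must be a noise_experiment, a manifest data frame or a manifest CSV path")
}

#' Run the ion-sizing pipeline
#'
#' Executes the full chain on a dataset of traces: settle expunge, PSD,
#' pink/white decomposition, per-(pore, concentration) threshold fit across
#' biases, per-pore zero-activity extrapolation of `I_T` (pores with fewer
#' than `min_activities` usable thresholds are dropped with a warning), and
#' the final zero-threshold diameter extrapolation per ion. Deterministic
#' given inputs and configuration.
#'
#' @param dataset A [gen_experiment()] result, a manifest data frame, or a
#'   manifest CSV path (columns `trace_path, pore_id, salt, C_M, V_bias, fs`,
#'   plus `d_mean_nm`).
#' @param config An [analysis_config()].
#' @return An object of class `ion_size_report` with per-trace, per-threshold,
#'   per-pore and per-ion tables.
#' @export
run_ion_sizing <- function(dataset, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  ds <- .resolve_dataset(dataset)
  man <- ds$manifest

  # per-trace decomposition
  per_trace <- do.call(rbind, lapply(seq_len(nrow(man)), function(i) {
    tr <- ds$traces[[man$trace_id[i]]]
    if (!isTRUE(tr$settled) && config$t_settle > 0)
      tr <- expunge_settling(tr, config$t_settle)
    spec <- compute_psd(tr, df_max = config$df_max)
    dec <- fit_decomposition(spec, s0_band = config$s0_band,
                             pink_fmax_init = config$pink_fmax_init,
                             beta_band = config$beta_band,
                             tol = config$tol, max_iter = config$max_iter)
    data.frame(trace_id = man$trace_id[i], pore_id = man$pore_id[i],
               salt = man$salt[i], d_mean_nm = man$d_mean_nm[i],
               C_M = man$C_M[i],
               a_M = activity(man$C_M[i], man$salt[i], config$activity_model),
               V_bias = man$V_bias[i], I0_pA = tr$I0,
               S1f = dec$S_1f, S0 = dec$S_0, beta_free = dec$beta_free,
               pink_present = dec$pink_present, stringsAsFactors = FALSE)
  }))

  # threshold fit per (pore, salt, concentration) across biases
  keys <- unique(per_trace[, c("pore_id", "salt", "C_M")])
  per_threshold <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sub <- per_trace[per_trace$pore_id == keys$pore_id[i] &
                     per_trace$salt == keys$salt[i] &
                     per_trace$C_M == keys$C_M[i], ]
    tf <- tryCatch(fit_threshold(sub$I0_pA, sub$S1f),
                   error = function(e) NULL)
    data.frame(pore_id = keys$pore_id[i], salt = keys$salt[i],
               C_M = keys$C_M[i], a_M = sub$a_M[1],
               d_mean_nm = sub$d_mean_nm[1],
               I_T_pA = if (is.null(tf) || !tf$present) NA_real_ else tf$I_T,
               sigma_lt = if (is.null(tf)) NA_real_ else tf$sigma_lt,
               sigma_gt = if (is.null(tf)) NA_real_ else tf$sigma_gt,
               present = !is.null(tf) && tf$present,
               n_points = nrow(sub), stringsAsFactors = FALSE)
  }))

  # zero-activity extrapolation per (pore, salt); pores lacking >= 3 usable
  # thresholds are dropped
  pkeys <- unique(per_threshold[, c("pore_id", "salt")])
  per_pore <- do.call(rbind, lapply(seq_len(nrow(pkeys)), function(i) {
    sub <- per_threshold[per_threshold$pore_id == pkeys$pore_id[i] &
                         per_threshold$salt == pkeys$salt[i] &
                         per_threshold$present, ]
    if (length(unique(sub$a_M)) < config$min_activities) {
      warning(sprintf("pore %s (%s): only %d usable activities (< %d), dropped",
                      pkeys$pore_id[i], pkeys$salt[i],
                      length(unique(sub$a_M)), config$min_activities))
      return(NULL)
    }
    za <- zero_activity_threshold(sub$a_M, sub$I_T_pA)
    data.frame(pore_id = pkeys$pore_id[i], salt = pkeys$salt[i],
               d_mean_nm = sub$d_mean_nm[1],
               I_T0_pA = za$I_T0, se_I_T0 = za$se_I_T0,
               slope_pA_per_M = za$slope, r_squared = za$r_squared,
               n_activities = za$n, stringsAsFactors = FALSE)
  }))
  if (is.null(per_pore) || nrow(per_pore) == 0)
    stop("all pores dropped: no pore has enough usable thresholds")

  # diameter extrapolation per ion
  per_ion <- do.call(rbind, lapply(unique(per_pore$salt), function(s) {
    sub <- per_pore[per_pore$salt == s, ]
    wts <- if (config$weights_policy == "inverse_variance" &&
               all(is.finite(sub$se_I_T0)) && all(sub$se_I_T0 > 0))
      1 / sub$se_I_T0^2 else NULL
    fit <- ion_diameter_from_thresholds(sub$d_mean_nm, sub$I_T0_pA, weights = wts)
    data.frame(salt = s, cation = .get_salt(s)$cation,
               d_ion_nm = fit$x_intercept, se_d_ion_nm = fit$se_x_intercept,
               slope_pA_per_nm = fit$slope, r_squared = fit$r_squared,
               n_pores = fit$n, flagged = fit$flagged, stringsAsFactors = FALSE)
  }))

  structure(list(per_trace = per_trace, per_threshold = per_threshold,
                 per_pore = per_pore, per_ion = per_ion, config = config),
            class = "ion_size_report")
}

#' @export
print.ion_size_report <- function(x, ...) {
  cat("ion-size report (correlated-noise thresholds)\n")
  cat(sprintf("  traces: %d; threshold fits: %d (%d with threshold); pores sized: %d\n",
              nrow(x$per_trace), nrow(x$per_threshold),
              sum(x$per_threshold$present), nrow(x$per_pore)))
  for (i in seq_len(nrow(x$per_ion)))
    cat(sprintf("  %s (%s+): d_ion = %.3f +/- %.3f nm (R^2 = %.3f, %d pores)%s\n",
                x$per_ion$salt[i], x$per_ion$cation[i], x$per_ion$d_ion_nm[i],
                x$per_ion$se_d_ion_nm[i], x$per_ion$r_squared[i],
                x$per_ion$n_pores[i],
                if (x$per_ion$flagged[i]) " [flagged]" else ""))
  invisible(x)
}

#' @export
summary.ion_size_report <- function(object, ...) {
  cat("per-ion diameters:\n"); print(object$per_ion)
  cat("\nper-pore zero-activity thresholds:\n"); print(object$per_pore)
  invisible(object)
}

#' Conductance-based ion sizing
#'
#' For each ion, fits conductance against pore diameter at fixed
#' concentration and extrapolates to zero conductance; the diameter
#' intercepts estimate de-hydrated ion sizes and their cross-ion mean is
#' reported.
#'
#' @param table Data frame with columns `salt, d_mean_nm, g` (conductance, nS
#'   or S) and optionally `weights`.
#' @param config An [analysis_config()] (reserved; weights policy only).
#' @return An object of class `conductance_size_report` with the per-ion
#'   intercept table and the cross-ion mean.
#' @export
run_conductance_sizing <- function(table, config = analysis_config()) {
  need <- c("salt", "d_mean_nm", "g")
  if (!all(need %in% names(table)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  per_ion <- do.call(rbind, lapply(unique(table$salt), function(s) {
    sub <- table[table$salt == s, ]
    if (length(unique(sub$d_mean_nm)) < 3) {
      warning(sprintf("%s: fewer than 3 pores, skipped", s))
      return(NULL)
    }
    wts <- if ("weights" %in% names(sub)) sub$weights else NULL
    fit <- fit_zero_conductance_diameter(sub$d_mean_nm, sub$g, weights = wts)
    data.frame(salt = s, cation = .get_salt(s)$cation,
               d_intercept_nm = fit$x_intercept,
               se_d_intercept_nm = fit$se_x_intercept,
               slope = fit$slope, r_squared = fit$r_squared,
               n = fit$n, flagged = fit$flagged, stringsAsFactors = FALSE)
  }))
  if (is.null(per_ion)) stop("no ion had enough pores to fit")
  structure(list(per_ion = per_ion,
                 mean_d_nm = mean(per_ion$d_intercept_nm)),
            class = "conductance_size_report")
}

#' @export
print.conductance_size_report <- function(x, ...) {
  cat("zero-conductance diameter intercepts:\n")
  for (i in seq_len(nrow(x$per_ion)))
    cat(sprintf("  %s (%s+): %.3f +/- %.3f nm (R^2 = %.3f)\n",
                x$per_ion$salt[i], x$per_ion$cation[i],
                x$per_ion$d_intercept_nm[i], x$per_ion$se_d_intercept_nm[i],
                x$per_ion$r_squared[i]))
  cat(sprintf("  cross-ion mean: %.2f nm\n", round(x$mean_d_nm, 2)))
  invisible(x)
}
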