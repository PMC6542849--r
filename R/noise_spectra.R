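# Current traces, Welch PSD estimation, and decomposition of the spectrum
# into pink (1/f), white and dielectric components.

#' Voltage-clamp current trace
#'
#' One recording: current samples (pA), sampling rate, bias voltage and
#' optional condition/pore metadata. The mean open-pore current `I0` is
#' computed from the samples.
#'
#' @param samples Current samples (pA).
#' @param fs Sampling rate (Hz), `> 0`.
#' @param v_bias Applied bias (V).
#' @param condition Optional [electrolyte_condition()].
#' @param pore Optional [pore_model()].
#' @param trace_id Optional identifier.
#' @param settled If `TRUE`, the trace contains no post-step settling
#'   transient (e.g. synthetic traces) and the settling expunge is a no-op
#'   in the pipeline.
#' @param warn_duration Warn when the duration falls outside the 60-300 s
#'   range typical of pipeline recordings.
#' @return An object of class `current_trace`.
#' @export
current_trace <- function(samples, fs, v_bias = NA_real_, condition = NULL,
                          pore = NULL, trace_id = NULL, settled = FALSE,
                          warn_duration = TRUE) {
  if (fs <= 0) stop("sampling rate must be > 0")
  duration <- length(samples) / fs
  if (warn_duration && (duration < 60 || duration > 300))
    warning(sprintf("trace duration %.3g s is outside the typical 60-300 s range", duration))
  structure(list(
    samples = as.numeric(samples), fs = fs, v_bias = v_bias,
    I0 = mean(samples), condition = condition, pore = pore,
    trace_id = trace_id, settled = settled, t_start_offset = 0
  ), class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("current trace %s: %d samples at %g Hz (%.3g s), I0 = %.4g pA, V = %g V\n",
              if (is.null(x$trace_id)) "" else x$trace_id,
              length(x$samples), x$fs, length(x$samples) / x$fs, x$I0, x$v_bias))
  invisible(x)
}

#' Remove the post-step settling interval
#'
#' Drops the first `t_settle` seconds of a trace (capacitive settling after a
#' voltage change). The removed offset is recorded in the trace metadata.
#'
#' @param trace A [current_trace()].
#' @param t_settle Seconds to expunge (default 15).
#' @return The shortened `current_trace`.
#' @export
expunge_settling <- function(trace, t_settle = 15) {
  stopifnot(inherits(trace, "current_trace"))
  duration <- length(trace$samples) / trace$fs
  if (t_settle == 0) return(trace)
  if (duration <= t_settle)
    stop(sprintf("trace (%.3g s) is not longer than the settling interval (%g s)",
                 duration, t_settle))
  n_drop <- round(t_settle * trace$fs)
  trace$samples <- trace$samples[-seq_len(n_drop)]
  trace$t_start_offset <- trace$t_start_offset + t_settle
  trace$I0 <- mean(trace$samples)
  trace
}

#' One-sided power spectral density (Welch estimate)
#'
#' Averaged modified periodograms: Hann window, 50% overlap, per-segment mean
#' removal. The segment length is the smallest power of two whose frequency
#' resolution `fs / L` does not exceed `df_max`; a trace shorter than one
#' segment is an error naming the minimum length.
#'
#' @param trace A [current_trace()] or numeric vector.
#' @param fs Sampling rate (Hz); taken from the trace if omitted.
#' @param df_max Maximum frequency spacing (Hz). Default 0.1.
#' @return An object of class `psd` with fields `freq` (Hz), `psd`
#'   (pA^2 Hz^-1), `df`, `n_segments`, `fs`.
#' @export
compute_psd <- function(trace, fs = NULL, df_max = 0.1) {
  if (inherits(trace, "current_trace")) {
    x <- trace$samples
    fs <- trace$fs
  } else {
    x <- as.numeric(trace)
    if (is.null(fs)) stop("fs required for a bare numeric trace")
  }
  n <- length(x)
  L <- 2^ceiling(log2(fs / df_max))
  if (n < L)
    stop(sprintf("trace too short for %.3g Hz resolution at fs = %g Hz: need >= %d samples, got %d",
                 df_max, fs, L, n))
  step <- L %/% 2
  n_seg <- 1 + (n - L) %/% step
  w <- 0.5 * (1 - cos(2 * pi * seq_len(L) / L))   # Hann
  U <- sum(w^2)
  nf <- L %/% 2
  acc <- numeric(nf)
  for (s in seq_len(n_seg)) {
    seg <- x[((s - 1) * step + 1):((s - 1) * step + L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)
    acc <- acc + (Mod(X[2:(nf + 1)])^2)
  }
  pxx <- 2 * acc / (n_seg * fs * U)
  pxx[nf] <- pxx[nf] / 2                          # Nyquist bin is not doubled
  freq <- (1:nf) * fs / L
  structure(list(freq = freq, psd = pxx, df = fs / L,
                 n_segments = n_seg, fs = fs, window = "hann", overlap = 0.5),
            class = "psd")
}

#' @export
print.psd <- function(x, ...) {
  cat(sprintf("one-sided PSD: %d bins, %.3g-%.4g Hz (df = %.3g Hz), %d Welch segments\n",
              length(x$freq), min(x$freq), max(x$freq), x$df, x$n_segments))
  invisible(x)
}

#' @export
plot.psd <- function(x, ...) {
  graphics::plot(x$freq, x$psd, log = "xy", type = "l",
                 xlab = "frequency (Hz)", ylab = expression(S[I] ~ (pA^2 / Hz)), ...)
  invisible(x)
}

# mean-log bias of an m-segment Welch bin: E[log Phat] = log P + psi(m) - log m
.log_psd_bias <- function(m) digamma(m) - log(m)

#' Decompose a current-noise spectrum
#'
#' Splits the PSD into `S_I = S_1f / f + S_0 + S_1 f`:
#' \itemize{
#'   \item `S_0` is the geometric mean ("mean logarithmic PSD") over the
#'     1-5 kHz band, where pink noise is not evident;
#'   \item `S_1f` is the 1 Hz intercept of a forced-slope (-1) log-log fit of
#'     the white-subtracted excess PSD, weighted `w(f) = (f / 1 Hz)^(-1/2)`
#'     (an order of magnitude down every two decades, so a 100 Hz bin carries
#'     a tenth of the weight of a 1 Hz bin);
#'   \item the pink-fit band's upper edge is iterated to a fixed point of the
#'     piecewise crossover `f_cross = S_1f / S_0`;
#'   \item the two-component model must beat a white-only model under a
#'     small-sample-corrected information criterion, otherwise `S_1f = 0`;
#'   \item the dielectric slope `S_1` is fitted only when the 5-50 kHz band
#'     rises with frequency, else recorded absent (`NA`).
#' }
#' Log-domain averages are corrected for the chi-squared mean-log bias of the
#' Welch estimate.
#'
#' @param spectrum A `psd` object from [compute_psd()].
#' @param s0_band White-level band (Hz), default `c(1000, 5000)`.
#' @param pink_fmax_init Initial upper edge of the pink-fit band (Hz).
#' @param beta_band Band for the free-exponent diagnostic fit (Hz).
#' @param tol Relative fixed-point tolerance on the crossover.
#' @param max_iter Iteration budget for the piecewise fit.
#' @return An object of class `spectral_decomposition` with `S_1f`, `S_0`,
#'   `S_1`, `beta_free`, `f_cross`, `pink_present`, convergence flags and the
#'   input spectrum.
#' @export
fit_decomposition <- function(spectrum, s0_band = c(1000, 5000),
                              pink_fmax_init = 100, beta_band = c(0.1, 100),
                              tol = 1e-3, max_iter = 50) {
  stopifnot(inherits(spectrum, "psd"))
  f <- spectrum$freq; p <- spectrum$psd
  m <- spectrum$n_segments
  bias <- .log_psd_bias(m)

  in_s0 <- f >= s0_band[1] & f <= s0_band[2]
  if (!any(in_s0))
    stop(sprintf("no PSD bins in the %g-%g Hz white-level band", s0_band[1], s0_band[2]))
  S0 <- exp(mean(log(p[in_s0])) - bias)

  fmin <- min(f)
  f_hi <- min(pink_fmax_init, s0_band[1])
  S1f <- NA_real_; f_cross <- NA_real_
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    band <- f >= fmin & f <= f_hi
    excess <- p[band] - S0
    fb <- f[band]
    pos <- excess > 0
    if (sum(pos) < 3) { S1f <- 0; break }
    wgt <- fb[pos]^(-0.5)
    # forced slope -1: log10 S1f = weighted mean of log10(excess * f)
    S1f <- exp(sum(wgt * log(excess[pos] * fb[pos])) / sum(wgt) - bias)
    f_cross_new <- S1f / S0
    f_hi_new <- min(max(f_cross_new, fmin + 3 * spectrum$df), s0_band[1])
    if (!is.na(f_cross) && abs(f_cross_new - f_cross) < tol * f_cross) {
      f_cross <- f_cross_new
      converged <- TRUE
      break
    }
    f_cross <- f_cross_new
    f_hi <- f_hi_new
  }

  # two-component vs white-only model, weighted log residuals, AICc
  sel <- f >= fmin & f <= s0_band[2]
  wgt <- f[sel]^(-0.5)
  ly <- log10(p[sel])
  rss2 <- if (!is.na(S1f) && S1f > 0)
    sum(wgt * (ly - log10(S1f / f[sel] + S0))^2) else Inf
  rss1 <- sum(wgt * (ly - log10(S0))^2)
  nn <- sum(sel)
  aicc <- function(rss, k) nn * log(rss / nn) + 2 * k + 2 * k * (k + 1) / (nn - k - 1)
  pink_present <- is.finite(rss2) && aicc(rss2, 2) < aicc(rss1, 1)
  if (!pink_present) { S1f <- 0; f_cross <- NA_real_ }

  # dielectric term: only if the 5-50 kHz band rises with frequency
  S1 <- NA_real_
  hi <- f >= 5000 & f <= 50000
  if (sum(hi) >= 5) {
    sl <- stats::coef(stats::lm(log10(p[hi]) ~ log10(f[hi])))[2]
    if (is.finite(sl) && sl > 0.2) {
      co <- stats::coef(stats::lm(p[hi] ~ f[hi]))
      if (co[2] > 0) S1 <- unname(co[2])
    }
  }

  beta_free <- tryCatch(fit_free_beta(spectrum, beta_band), error = function(e) NA_real_)
  beta_flagged <- is.finite(beta_free) && (beta_free < 0.5 || beta_free > 1.6)

  residual <- if (pink_present) rss2 else rss1
  structure(list(
    S_1f = S1f, S_0 = S0, S_1 = S1,
    beta_free = beta_free, beta_flagged = beta_flagged,
    f_cross = f_cross, pink_present = pink_present,
    residual = residual, converged = converged || !pink_present,
    n_segments = m, spectrum = spectrum
  ), class = "spectral_decomposition")
}

#' @export
print.spectral_decomposition <- function(x, ...) {
  cat(sprintf("spectral decomposition: S_1f(1 Hz) = %.4g, S_0 = %.4g pA^2/Hz%s\n",
              x$S_1f, x$S_0,
              if (is.na(x$S_1)) ", S_1 absent" else sprintf(", S_1 = %.3g pA^2/Hz^2", x$S_1)))
  cat(sprintf("  pink %s; f_cross = %.4g Hz; free beta = %.2f%s%s\n",
              if (x$pink_present) "present" else "absent",
              x$f_cross, x$beta_free,
              if (x$beta_flagged) " [flagged]" else "",
              if (!x$converged) " [piecewise fit not converged]" else ""))
  invisible(x)
}

#' @export
coef.spectral_decomposition <- function(object, ...) {
  c(S_1f = object$S_1f, S_0 = object$S_0, S_1 = object$S_1)
}

#' Free spectral exponent
#'
#' Unweighted log-log slope magnitude of the PSD over a band;
#' `S ~ f^(-beta)`.
#'
#' @param spectrum A `psd` object.
#' @param band Frequency band (Hz), default `c(0.1, 100)`.
#' @return The exponent `beta` (dimensionless).
#' @export
fit_free_beta <- function(spectrum, band = c(0.1, 100)) {
  stopifnot(inherits(spectrum, "psd"))
  sel <- spectrum$freq >= band[1] & spectrum$freq <= band[2]
  if (sum(sel) < 2) stop("no PSD bins in the requested band")
  -unname(stats::coef(stats::lm(log10(spectrum$psd[sel]) ~ log10(spectrum$freq[sel])))[2])
}

#' Trace and spectrum text I/O
#'
#' Traces are exchanged as two-column delimited text `(time_s, current_pA)`;
#' spectra as `(freq_Hz, psd_pA2_per_Hz)`.
#'
#' @param path File path.
#' @param v_bias,trace_id Metadata passed to [current_trace()].
#' @param ... Passed to [current_trace()].
#' @return `read_trace_text` returns a `current_trace`.
#' @export
read_trace_text <- function(path, v_bias = NA_real_, trace_id = NULL, ...) {
  df <- utils::read.table(path, header = TRUE)
  fs <- 1 / stats::median(diff(df[[1]]))
  current_trace(df[[2]], fs = fs, v_bias = v_bias, trace_id = trace_id, ...)
}

#' @param trace A `current_trace`.
#' @rdname read_trace_text
#' @export
write_trace_text <- function(trace, path) {
  t <- seq_along(trace$samples) / trace$fs
  utils::write.table(data.frame(time_s = t, current_pA = trace$samples),
                     path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param spectrum A `psd`.
#' @rdname read_trace_text
#' @export
write_psd_text <- function(spectrum, path) {
  utils::write.table(data.frame(freq_Hz = spectrum$freq,
                                psd_pA2_per_Hz = spectrum$psd),
                     path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
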