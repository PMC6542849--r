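# Correlated-carrier statistics and the threshold-detection / two-stage
# extrapolation chain: (I0^2, S_1f/I0^2) piecewise fit -> I_T, sigma_<,
# sigma_> -> zero-activity I_T0 -> zero-threshold ion diameter.

#' Variance of a sum of correlated single-carrier currents
#'
#' For `N` carriers with per-carrier current variance `var_single` and average
#' pairwise spectral correlation `xi`, the variance of the summed current is
#' `var_single * [N + N (N - 1) xi]`: the sum of all covariances. `xi = 0`
#' gives `N var_single` (uncorrelated), `xi = 1` gives `N^2 var_single`
#' (fully correlated).
#'
#' @param N Carrier count, integer `>= 1`.
#' @param var_single Single-carrier current variance (pA^2), `>= 0`.
#' @param xi Average pairwise correlation in `[0, 1]`.
#' @return Ensemble variance (pA^2).
#' @export
ensemble_variance <- function(N, var_single, xi) {
  if (any(N < 1) || any(N != round(N))) stop("N must be an integer >= 1")
  if (any(var_single < 0)) stop("var_single must be >= 0")
  if (any(xi < 0) || any(xi > 1)) stop("xi must be in [0, 1]")
  var_single * (N + N * (N - 1) * xi)
}

#' Normalized noise power of a carrier ensemble
#'
#' `Var(sum i_n) / <I>^2` with `<I> = N i_single`. At `xi = 0` this is
#' proportional to `1/N` (falls as `N/I0^2`); at `xi = 1` it is independent
#' of `N` (the correlated plateau).
#'
#' @param N Carrier count.
#' @param i_single Single-carrier current (pA), nonzero.
#' @param var_single Single-carrier variance (pA^2).
#' @param xi Average pairwise correlation in `[0, 1]`.
#' @return Dimensionless normalized noise power.
#' @export
normalized_noise_power <- function(N, i_single, var_single, xi) {
  if (any(i_single == 0)) stop("zero mean current")
  ensemble_variance(N, var_single, xi) / (N * i_single)^2
}

#' Threshold-current fit on normalized pink noise
#'
#' Piecewise fit in log-log coordinates of `(I0^2, S_1f / I0^2)`: below
#' threshold a forced power law of slope -1 (constant `S_1f`, the
#' uncorrelated-carrier branch) and above threshold a current-independent
#' level (`S_1f` proportional to `I0^2`, the correlated branch). The split is
#' chosen by scanning contiguous partitions for minimum (weighted) squared
#' residual, then the branch intersection is iterated to a fixed point.
#' `sigma_lt` is the power-law branch evaluated at `I0 = 1 pA`; `sigma_gt`
#' the plateau level; the two-branch model must beat the best single-branch
#' model under a small-sample-corrected information criterion, otherwise
#' `present = FALSE` and the better single-branch fit is reported.
#'
#' @param I0 Open-pore currents (pA), at least 6 points spanning >= 1.5
#'   decades.
#' @param S1f Pink amplitudes at 1 Hz (pA^2/Hz).
#' @param weights Optional fit weights (default uniform).
#' @param tol Relative fixed-point tolerance on the intersection.
#' @param max_iter Iteration budget.
#' @return An object of class `threshold_fit` with `I_T` (pA, or `NA`),
#'   `sigma_lt`, `sigma_gt` (1/Hz), `zeta_free` (free below-threshold slope
#'   diagnostic), and `present`.
#' @export
fit_threshold <- function(I0, S1f, weights = NULL, tol = 1e-3, max_iter = 50) {
  ok <- is.finite(I0) & is.finite(S1f) & I0 > 0 & S1f > 0
  I0 <- I0[ok]; S1f <- S1f[ok]
  if (!is.null(weights)) weights <- weights[ok]
  n <- length(I0)
  if (n < 6) stop("need at least 6 points, got ", n)
  span <- log10(max(I0) / min(I0))
  if (span < 1.5)
    stop(sprintf("I0 must span at least 1.5 decades (got %.2f)", span))
  o <- order(I0)
  I0 <- I0[o]; S1f <- S1f[o]
  w <- if (is.null(weights)) rep(1, n) else weights[o]
  x <- log10(I0^2)              # abscissa: I0^2
  y <- log10(S1f / I0^2)        # ordinate: normalized pink noise

  # branch 1 (slope -1 in x): y = log10(sigma_lt) - x  =>  y + x constant
  # branch 2 (plateau):       y = log10(sigma_gt)
  fit_split <- function(lower) {   # logical: TRUE -> branch 1
    c1 <- if (any(lower)) sum(w[lower] * (y[lower] + x[lower])) / sum(w[lower]) else NA
    c2 <- if (any(!lower)) sum(w[!lower] * y[!lower]) / sum(w[!lower]) else NA
    rss <- 0
    if (any(lower)) rss <- rss + sum(w[lower] * (y[lower] + x[lower] - c1)^2)
    if (any(!lower)) rss <- rss + sum(w[!lower] * (y[!lower] - c2)^2)
    list(c1 = c1, c2 = c2, rss = rss)
  }

  # exhaustive scan over contiguous splits (>= 2 points per branch)
  best <- NULL; best_k <- NA
  for (k in 2:(n - 2)) {
    fk <- fit_split(seq_len(n) <= k)
    if (is.null(best) || fk$rss < best$rss) { best <- fk; best_k <- k }
  }

  # iterate the intersection to a fixed point
  converged <- FALSE
  x_star <- best$c1 - best$c2
  for (it in seq_len(max_iter)) {
    lower <- x < x_star
    if (sum(lower) < 2 || sum(!lower) < 2) break
    ft <- fit_split(lower)
    x_new <- ft$c1 - ft$c2
    best <- ft
    if (abs(x_new - x_star) < tol * max(abs(x_star), 1e-12)) {
      x_star <- x_new; converged <- TRUE; break
    }
    x_star <- x_new
  }
  I_T <- sqrt(10^x_star)
  sigma_lt <- 10^best$c1
  sigma_gt <- 10^best$c2

  # single-branch alternatives
  all1 <- fit_split(rep(TRUE, n))
  all2 <- fit_split(rep(FALSE, n))
  aicc <- function(rss, k) {
    if (n - k - 1 <= 0) return(Inf)
    n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  }
  a_two <- aicc(best$rss, 3)     # two levels + change point
  a_one <- min(aicc(all1$rss, 1), aicc(all2$rss, 1))
  present <- a_two < a_one && I_T >= min(I0) && I_T <= max(I0)

  # free-slope diagnostic on the below-threshold points
  lower <- x < x_star
  zeta_free <- if (sum(lower) >= 3)
    unname(stats::coef(stats::lm(y[lower] ~ x[lower], weights = w[lower]))[2])
  else NA_real_

  if (!present) {
    single_is_powerlaw <- aicc(all1$rss, 1) <= aicc(all2$rss, 1)
    sigma_lt <- if (single_is_powerlaw) 10^all1$c1 else NA_real_
    sigma_gt <- if (single_is_powerlaw) NA_real_ else 10^all2$c2
    I_T <- NA_real_
  }
  structure(list(
    I_T = I_T, sigma_lt = sigma_lt, sigma_gt = sigma_gt,
    present = present, zeta_free = zeta_free,
    n = n, converged = converged, rss = best$rss,
    I0 = I0, S1f = S1f, weights = w
  ), class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, ...) {
  if (x$present) {
    cat(sprintf("threshold fit (n = %d): I_T = %.4g pA, sigma_< = %.4g /Hz, sigma_> = %.4g /Hz\n",
                x$n, x$I_T, x$sigma_lt, x$sigma_gt))
  } else {
    cat(sprintf("threshold fit (n = %d): no threshold evident (single-branch model preferred)\n", x$n))
  }
  cat(sprintf("  free below-threshold slope zeta = %.3f%s\n",
              x$zeta_free, if (!x$converged && x$present) " [intersection not converged]" else ""))
  invisible(x)
}

#' @export
plot.threshold_fit <- function(x, ...) {
  graphics::plot(x$I0^2, x$S1f / x$I0^2, log = "xy",
                 xlab = expression(I[0]^2 ~ (pA^2)),
                 ylab = expression(S[1 / f] / I[0]^2 ~ (Hz^-1)), ...)
  if (x$present) graphics::abline(v = x$I_T^2, lty = 3)
  invisible(x)
}

#' Zero-activity threshold current
#'
#' Weighted least-squares line of threshold currents against electrolyte
#' activity; the intercept at `a = 0` is `I_T0`, the threshold at infinite
#' dilution. At least 3 distinct activities are required.
#'
#' @param a Activities (M).
#' @param I_T Threshold currents (pA).
#' @param weights Optional fit weights.
#' @return A list with `I_T0`, `se_I_T0`, `slope`, `se_slope`, `r_squared`,
#'   `n` and the underlying `lm` fit.
#' @export
zero_activity_threshold <- function(a, I_T, weights = NULL) {
  ok <- is.finite(a) & is.finite(I_T)
  a <- a[ok]; I_T <- I_T[ok]
  if (!is.null(weights)) weights <- weights[ok]
  if (length(unique(a)) < 3)
    stop("need thresholds at n >= 3 distinct activities, got ", length(unique(a)))
  fit <- if (is.null(weights)) stats::lm(I_T ~ a) else stats::lm(I_T ~ a, weights = weights)
  b <- stats::coef(fit); V <- .quiet_perfect(stats::vcov(fit))
  list(I_T0 = unname(b[1]), se_I_T0 = sqrt(V[1, 1]),
       slope = unname(b[2]), se_slope = sqrt(V[2, 2]),
       r_squared = .quiet_perfect(summary(fit)$r.squared), n = length(a),
       lm = fit)
}

#' Ion diameter from zero-activity thresholds
#'
#' Weighted linear fit of `I_T0` against pore diameter over a short range;
#' the diameter at which the fitted threshold crosses zero is the limiting
#' pore size at which correlated ionic noise would appear at any current —
#' a measure of the de-hydrated ion diameter.
#'
#' @param d_mean Pore mean diameters (nm), >= 3 distinct values.
#' @param I_T0 Zero-activity thresholds (pA).
#' @param weights Optional fit weights.
#' @return An `intercept_fit`; `$x_intercept` is the ion diameter (nm).
#' @export
ion_diameter_from_thresholds <- function(d_mean, I_T0, weights = NULL) {
  fit_x_intercept(d_mean, I_T0, weights, xlab = "diameter_nm", ylab = "I_T0_pA")
}
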