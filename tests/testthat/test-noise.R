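test_that("current_trace validates and computes I0; settling expunge works", {
  tr <- current_trace(rep(5, 1000), fs = 10, v_bias = 0.1)   # 100 s
  expect_equal(tr$I0, 5)
  expect_warning(current_trace(1:10, fs = 10), "60-300")
  expect_error(current_trace(1:10, fs = 0), "> 0")

  x <- c(rep(100, 200), rep(5, 800))   # 20 s settling at fs = 10
  tr2 <- current_trace(x, fs = 10)
  tr3 <- expunge_settling(tr2, t_settle = 20)
  expect_equal(length(tr3$samples), 800)
  expect_equal(tr3$I0, 5)
  expect_equal(tr3$t_start_offset, 20)
  expect_identical(expunge_settling(tr2, 0), tr2)
  expect_error(expunge_settling(tr2, 200), "not longer")
})

test_that("Welch PSD recovers a white level within 5% and scales as b^2", {
  set.seed(101)
  fs <- 10000
  x <- rnorm(fs * 70, sd = 2)
  tr <- current_trace(x, fs = fs)
  ps <- compute_psd(tr, df_max = 1)
  level <- 2 * 4 / fs                      # 2 sigma^2 / fs one-sided
  expect_equal(mean(ps$psd), level, tolerance = 0.05)
  # scale equivariance
  tr2 <- current_trace(3 * x, fs = fs, warn_duration = FALSE)
  ps2 <- compute_psd(tr2, df_max = 1)
  expect_equal(ps2$psd, 9 * ps$psd, tolerance = 1e-10)
})

test_that("PSD satisfies Parseval within 1% and finds a planted sinusoid", {
  set.seed(102)
  fs <- 5000
  n <- fs * 80
  t <- (1:n) / fs
  x <- rnorm(n) + 4 * sin(2 * pi * 100 * t)
  ps <- compute_psd(x, fs = fs, df_max = 0.5)
  # Parseval: integral of the one-sided PSD ~ variance of the trace
  expect_equal(sum(ps$psd) * ps$df, var(x), tolerance = 0.01)
  # sinusoid power concentrates at 100 Hz
  expect_equal(ps$freq[which.max(ps$psd)], 100, tolerance = 0.01)
})

test_that("PSD errors on short traces naming the minimum length", {
  expect_error(compute_psd(rnorm(100), fs = 1000, df_max = 0.1),
               "need >= ")
  expect_error(compute_psd(rnorm(100)), "fs required")
})

test_that("decomposition recovers planted pink + white components", {
  set.seed(103)
  fs <- 12800; n <- 2^20
  x <- 50 + gen_pink_noise(n, fs, S1Hz = 1e-2, beta = 1) +
    gen_white_noise(n, fs, S0 = 1e-4)
  dec <- fit_decomposition(compute_psd(x, fs = fs))
  expect_true(dec$pink_present)
  expect_equal(dec$S_1f, 1e-2, tolerance = 0.15)
  expect_equal(dec$S_0, 1e-4, tolerance = 0.15)
  expect_equal(dec$f_cross, dec$S_1f / dec$S_0, tolerance = 1e-3)
  expect_true(dec$converged)
})

test_that("decomposition reports S_1f = 0 on pure white noise", {
  set.seed(104)
  fs <- 12800
  x <- 50 + gen_white_noise(2^20, fs, S0 = 1e-4)
  dec <- fit_decomposition(compute_psd(x, fs = fs))
  expect_false(dec$pink_present)
  expect_equal(dec$S_1f, 0)
  expect_equal(dec$S_0, 1e-4, tolerance = 0.1)
})

test_that("the pink fit weight drops tenfold per two decades", {
  # w(f) = f^(-1/2): documented weighting scheme, checked literally
  w <- function(f) f^(-0.5)
  expect_equal(w(1) / w(100), 10, tolerance = 1e-12)
  expect_equal(w(10) / w(1000), 10, tolerance = 1e-12)
})

test_that("dielectric slope S_1 is reported only when the PSD rises", {
  fs <- 200000
  set.seed(105)
  n <- 2^21
  S1 <- 1e-8
  # synthesize a rising spectrum: white plus f-proportional component
  f_half <- (1:(n %/% 2)) * fs / n
  sd_k <- sqrt((1e-4 + S1 * f_half) * fs * n / 4)
  re <- rnorm(n %/% 2) * sd_k; im <- rnorm(n %/% 2) * sd_k
  X <- complex(real = re, imaginary = im)
  full <- complex(length.out = n)
  full[2:(n %/% 2 + 1)] <- X
  full[n:(n %/% 2 + 2)] <- Conj(X[seq_len(n %/% 2 - 1)])
  x <- Re(fft(full, inverse = TRUE)) / n
  dec <- fit_decomposition(compute_psd(x, fs = fs, df_max = 10))
  expect_false(is.na(dec$S_1))
  expect_equal(dec$S_1, S1, tolerance = 0.25)
  # and absent for flat spectra
  set.seed(106)
  dec2 <- fit_decomposition(compute_psd(gen_white_noise(2^20, 200000, 1e-4),
                                        fs = 200000, df_max = 10))
  expect_true(is.na(dec2$S_1))
})

test_that("free beta diagnostic flags exponents outside [0.5, 1.6]", {
  set.seed(107)
  fs <- 12800
  x <- gen_pink_noise(2^20, fs, S1Hz = 1e-2, beta = 1)
  dec <- fit_decomposition(compute_psd(x, fs = fs))
  expect_false(dec$beta_flagged)
  x2 <- gen_pink_noise(2^20, fs, S1Hz = 1e-2, beta = 2)
  beta2 <- fit_free_beta(compute_psd(x2, fs = fs))
  expect_gt(beta2, 1.6)
})

test_that("decomposition is idempotent and deterministic", {
  set.seed(108)
  x <- 10 + gen_pink_noise(2^18, 12800, 1e-2) + gen_white_noise(2^18, 12800, 1e-4)
  ps <- compute_psd(x, fs = 12800)
  d1 <- fit_decomposition(ps)
  d2 <- fit_decomposition(ps)
  expect_identical(coef(d1), coef(d2))
})

test_that("trace and PSD text round-trips preserve the data", {
  set.seed(109)
  tr <- current_trace(rnorm(5000, 10), fs = 50, trace_id = "t",
                      warn_duration = FALSE)
  f <- tempfile(fileext = ".txt")
  write_trace_text(tr, f)
  back <- read_trace_text(f, warn_duration = FALSE)
  expect_equal(back$samples, tr$samples, tolerance = 1e-9)
  expect_equal(back$fs, 50, tolerance = 1e-6)
  ps <- compute_psd(tr, df_max = 1)
  f2 <- tempfile(fileext = ".txt")
  write_psd_text(ps, f2)
  tab <- read.table(f2, header = TRUE)
  expect_equal(tab$freq_Hz, ps$freq, tolerance = 1e-9)
  expect_equal(tab$psd_pA2_per_Hz, ps$psd, tolerance = 1e-9)
})
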