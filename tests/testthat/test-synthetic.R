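test_that("pink noise generation is seeded, zero-mean and beta-checked", {
  x1 <- gen_pink_noise(2^14, 12800, 1e-2, seed = 7)
  x2 <- gen_pink_noise(2^14, 12800, 1e-2, seed = 7)
  expect_identical(x1, x2)
  x3 <- gen_pink_noise(2^14, 12800, 1e-2, seed = 8)
  expect_false(identical(x1, x3))
  # zeroed DC bin makes the synthesized trace exactly zero-mean
  expect_equal(mean(x1), 0, tolerance = 1e-12)
  expect_identical(gen_pink_noise(100, 12800, 0), numeric(100))
  expect_error(gen_pink_noise(100, 12800, 1e-2, beta = 3), "\\[0, 2\\]")
  expect_error(gen_pink_noise(100, 12800, -1), ">= 0")
})

test_that("generated noise matches its target spectrum", {
  set.seed(301)
  fs <- 12800
  x <- gen_pink_noise(2^20, fs, S1Hz = 1e-2, beta = 1)
  ps <- compute_psd(x, fs = fs)
  sel <- ps$freq >= 1 & ps$freq <= 50
  lvl <- exp(mean(log(ps$psd[sel] * ps$freq[sel])))
  expect_equal(lvl, 1e-2, tolerance = 0.2)
  w <- gen_white_noise(2^18, fs, S0 = 1e-4, seed = 9)
  expect_equal(var(w), 1e-4 * fs / 2, tolerance = 0.05)
})

test_that("seeding restores the caller's RNG state", {
  set.seed(123)
  before <- .Random.seed
  invisible(gen_pink_noise(1024, 1000, 1e-2, seed = 55))
  expect_identical(.Random.seed, before)
})

test_that("correlated carriers have the exact ensemble statistics", {
  set.seed(302)
  n <- 2e5
  for (xi in c(0, 0.5, 1)) {
    tr <- gen_correlated_carriers(N = 8, i_single = 2, var_single = 1.5,
                                  xi = xi, n_samples = n, fs = 1000)
    expect_equal(mean(tr), 16, tolerance = 0.02)
    expect_equal(var(tr), ensemble_variance(8, 1.5, xi), tolerance = 0.05)
  }
  # per-carrier pairwise correlation equals xi
  out <- gen_correlated_carriers(N = 4, i_single = 0, var_single = 1, xi = 0.5,
                                 n_samples = n, fs = 1000, seed = 12,
                                 return_carriers = TRUE)
  cm <- cor(t(out$carriers))
  off <- cm[upper.tri(cm)]
  expect_equal(mean(off), 0.5, tolerance = 0.05)
  expect_equal(colSums(out$carriers), out$trace)
  expect_error(gen_correlated_carriers(0, 1, 1, 0.5, 10, 1), ">= 1")
})

test_that("experiment_plan validates the planted geometry", {
  expect_error(experiment_plan("NaCl", d_ion_true = 0.5,
                               diameters = c(0.35, 0.45)), "smaller")
  expect_error(experiment_plan("XYZ", d_ion_true = 0.1), "unknown salt")
  plan <- experiment_plan("KCl", d_ion_true = 0.25, seed = 3)
  expect_s3_class(plan, "experiment_plan")
  expect_equal(plan$seed, 3L)
})

test_that("gen_experiment is a pure function of the plan", {
  plan <- experiment_plan("NaCl", d_ion_true = 0.22,
                          diameters = c(0.4, 0.6),
                          concentrations = c(0.25, 0.5),
                          voltages = c(0.1, 0.3),
                          n_samples = 2^12, seed = 17)
  e1 <- gen_experiment(plan)
  e2 <- gen_experiment(plan)
  expect_identical(e1$manifest, e2$manifest)
  expect_identical(e1$traces[[1]]$samples, e2$traces[[1]]$samples)
  expect_equal(nrow(e1$manifest), 8)
  # planted law recorded in the manifest
  m <- e1$manifest
  cond <- electrolyte_condition("NaCl", 0.25)
  expect_equal(m$I_T_true_pA[m$C_M == 0.25][1],
               300 * (0.4 - 0.22) * (1 + cond$a), tolerance = 1e-9)
  # mean current follows the point-contact law
  expect_equal(m$I0_true_pA,
               bulk_conductivity("NaCl", m$C_M) * m$d_mean_nm * 1e-9 *
                 m$V_bias * 1e12, tolerance = 1e-9)
})

test_that("write_experiment emits readable traces and a complete manifest", {
  plan <- experiment_plan("NaCl", d_ion_true = 0.22,
                          diameters = 0.4, concentrations = 0.25,
                          voltages = c(0.1, 0.3), n_samples = 2^10, seed = 5)
  ex <- gen_experiment(plan)
  dir <- tempfile()
  path <- write_experiment(ex, dir)
  man <- read.csv(path)
  expect_true(all(c("trace_path", "pore_id", "salt", "C_M", "V_bias", "fs")
                  %in% names(man)))
  expect_true(all(file.exists(man$trace_path)))
  back <- read_trace_text(man$trace_path[1], warn_duration = FALSE)
  expect_equal(back$samples, ex$traces[[man$trace_id[1]]]$samples,
               tolerance = 1e-9)
})
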