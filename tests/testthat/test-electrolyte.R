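test_that("registry tabulates the five cations and chloride", {
  reg <- ion_registry()
  expect_setequal(reg$name, c("Li", "Na", "K", "Cs", "Mg", "Cl"))
  expect_equal(reg$a0_nm[reg$name == "Li"], 0.38)
  expect_equal(reg$a0_nm[reg$name == "Mg"], 0.43)
  expect_equal(reg$b_per_M[reg$name == "Na"], 0.06)
  expect_equal(reg$d_dehydrated_nm[reg$name == "K"], 0.298)
  expect_equal(reg$z[reg$name == "Mg"], 2L)
})

test_that("registry file override round-trips the built-in table", {
  path <- system.file("extdata", "ion_registry.tsv", package = "porenoise")
  expect_true(nzchar(path))
  reg <- ion_registry(path)
  expect_equal(reg, ion_registry(), tolerance = 1e-12)
})

test_that("invalid registry files are rejected", {
  bad <- data.frame(name = "X", z = 1, d_dehydrated_nm = -1, a0_nm = 0.3,
                    b_per_M = 0, mu_m2_per_Vs = 1e-8, D_nm2_per_ns = 1)
  f <- tempfile(fileext = ".tsv")
  write.table(bad, f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(ion_registry(f), "invalid registry")
  expect_error(suppressWarnings(ion_registry(tempfile())),
               "cannot open|No such file")
})

test_that("ionic strength is C for 1:1 salts and 3C for MgCl2", {
  expect_equal(ionic_strength(0.5, "NaCl"), 0.5)
  expect_equal(ionic_strength(0.5, "KCl"), 0.5)
  expect_equal(ionic_strength(0.5, "MgCl2"), 1.5)
  expect_error(ionic_strength(-1, "NaCl"), ">= 0")
  expect_error(ionic_strength(0.5, "CaCl2"), "unknown salt")
})

test_that("TJ and EDH differ by exactly 10^(b I)", {
  sr <- salt_registry()
  reg <- ion_registry()
  for (i in seq_len(nrow(sr))) {
    salt <- sr$salt[i]
    b <- reg$b_per_M[reg$name == sr$cation[i]]
    C <- c(0.01, 0.1, 0.5, 1)
    I <- ionic_strength(C, salt)
    expect_equal(activity_coefficient(C, salt, "TJ"),
                 activity_coefficient(C, salt, "EDH") * 10^(b * I),
                 tolerance = 1e-12, info = salt)
  }
})

test_that("activity coefficient reproduces the extended DH closed form", {
  # independent recomputation at 0.5 M NaCl
  A <- 0.5085; B <- 0.3281
  sI <- sqrt(0.5)
  g_edh <- 10^(-A * sI / (1 + B * 3.6 * sI))
  g_tj <- g_edh * 10^(0.06 * 0.5)
  expect_equal(activity_coefficient(0.5, "NaCl", "EDH"), g_edh, tolerance = 1e-12)
  expect_equal(activity_coefficient(0.5, "NaCl", "TJ"), g_tj, tolerance = 1e-12)
  expect_equal(activity_coefficient(0.5, "NaCl"), 0.682, tolerance = 2e-3)
})

test_that("gamma lies in (0, 1] below 1 M and activity increases with C", {
  C <- seq(0.001, 1, length.out = 50)
  for (salt in salt_registry()$salt) {
    for (model in c("TJ", "EDH")) {
      g <- activity_coefficient(C, salt, model)
      expect_true(all(g > 0 & g <= 1), info = paste(salt, model))
      a <- activity(C, salt, model)
      expect_true(all(diff(a) > 0), info = paste(salt, model))
    }
  }
  expect_equal(activity_coefficient(0, "NaCl"), 1)
})

test_that("Stokes mobility and Einstein diffusivity follow the closed forms", {
  e <- 1.602176634e-19; kB <- 1.380649e-23
  mu <- stokes_mobility(1, 0.89e-3, 0.3e-9)
  expect_equal(mu, e / (3 * pi * 0.89e-3 * 0.3e-9), tolerance = 1e-12)
  expect_equal(einstein_diffusivity(mu, 298.15), kB * 298.15 * mu / e,
               tolerance = 1e-12)
  # registry consistency: D = kB T mu / e reproduces the tabulated Na+ value
  reg <- ion_registry()
  muNa <- reg$mu_m2_per_Vs[reg$name == "Na"]
  expect_equal(einstein_diffusivity(muNa) * 1e18 / 1e9,  # m^2/s -> nm^2/ns
               reg$D_nm2_per_ns[reg$name == "Na"], tolerance = 0.01)
  expect_error(stokes_mobility(1, 0, 1e-9), "> 0")
  expect_error(einstein_diffusivity(1e-8, T = -1), "> 0")
})

test_that("Debye length matches 0.304/sqrt(I) nm for 1:1 salts at 25 C", {
  expect_equal(debye_length(0.1), 0.962, tolerance = 2e-3)
  expect_equal(debye_length(1), 0.304, tolerance = 2e-3)
  expect_true(debye_length(0.01) > debye_length(0.1))
  expect_error(debye_length(0), "> 0")
})

test_that("bulk conductivity is the Kohlrausch mobility sum", {
  F <- 96485.33212
  reg <- ion_registry()
  muNa <- reg$mu_m2_per_Vs[reg$name == "Na"]
  muCl <- reg$mu_m2_per_Vs[reg$name == "Cl"]
  expect_equal(bulk_conductivity("NaCl", 0.25),
               F * 250 * (muNa + muCl), tolerance = 1e-12)
  # MgCl2 stoichiometry: |z| c mu for Mg2+ plus two chlorides
  muMg <- reg$mu_m2_per_Vs[reg$name == "Mg"]
  expect_equal(bulk_conductivity("MgCl2", 0.1),
               F * (2 * 100 * muMg + 200 * muCl), tolerance = 1e-12)
  expect_equal(bulk_conductivity("NaCl", 0), 0)
})

test_that("electrolyte_condition bundles consistent derived quantities", {
  cond <- electrolyte_condition("MgCl2", 0.2)
  expect_s3_class(cond, "electrolyte_condition")
  expect_equal(cond$I_strength, 0.6)
  expect_equal(cond$gamma, activity_coefficient(0.2, "MgCl2"))
  expect_equal(cond$a, cond$gamma * 0.2)
  expect_equal(cond$lambda_D, debye_length(0.6))
  expect_equal(cond$sigma_bulk, bulk_conductivity("MgCl2", 0.2))
  expect_output(print(cond), "MgCl2")
})
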