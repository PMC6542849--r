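test_that("flat landscape at zero field carries no net current", {
  set.seed(401)
  tj <- brownian_transport(D = 1.33, box = c(-2.5, 2.5), dt = 1e-3,
                           n_steps = 2e6, stride = 100L)
  n_tot <- nrow(tj$events)
  expect_gt(n_tot, 100)
  # net flux is statistically zero: |net| within 4 sd of a fair coin count
  expect_lt(abs(sum(tj$events$direction)), 4 * sqrt(n_tot))
  expect_lt(abs(average_current(tj$events, tj$total_time)),
            4 * sqrt(n_tot) * 160.3 / tj$total_time)
})

test_that("an axial field drives current of the field's sign", {
  set.seed(402)
  up <- brownian_transport(D = 1.33, E = 0.05, box = c(-2.5, 2.5), dt = 1e-3,
                           n_steps = 1e6, stride = 100L)
  expect_gt(average_current(up$events, up$total_time), 0)
  set.seed(402)
  dn <- brownian_transport(D = 1.33, E = -0.05, box = c(-2.5, 2.5), dt = 1e-3,
                           n_steps = 1e6, stride = 100L)
  expect_lt(average_current(dn$events, dn$total_time), 0)
  # reversing the field mirrors the net flux statistically (the noise draws
  # are not negated, so the mirror is in distribution, not per-path)
  n_up <- sum(up$events$direction); n_dn <- sum(dn$events$direction)
  expect_lt(abs(n_up + n_dn), 4 * sqrt(nrow(up$events) + nrow(dn$events)))
})

test_that("MSD estimator recovers the planted diffusivity within 5%", {
  set.seed(403)
  tj <- brownian_transport(D = 1.33, box = c(-5, 5), dt = 1e-3,
                           n_steps = 2e6, boundary = "reflecting",
                           stride = 1L)
  expect_equal(msd_diffusivity(tj), 1.33, tolerance = 0.05)
})

test_that("PMF inversion recovers a planted barrier", {
  set.seed(404)
  W <- function(z) 1.5 * exp(-z^2 / (2 * 0.6^2))
  # ~1000 ns so the two wells exchange population many times
  tj <- brownian_transport(W = W, D = 1.33, box = c(-2.5, 2.5),
                           n_grid = 64, dt = 5e-4, n_steps = 2e6,
                           boundary = "reflecting", stride = 10L)
  pm <- pmf_from_trajectory(tj, z0 = -2.4, n_bins = 25)
  truth <- W(pm$z) - W(-2.4)
  expect_lt(max(abs(pm$W - truth)), 0.25)   # kBT
})

test_that("charge conservation: instantaneous current integrates to n e", {
  set.seed(405)
  tj <- brownian_transport(D = 1.33, E = 0.08, box = c(-2.5, 2.5), dt = 1e-3,
                           n_steps = 5e5, stride = 100L)
  ic <- instantaneous_current(tj$events)
  e <- 1.602176634e-19
  q_sum <- sum(ic$I_pA * 1e-12 * (ic$t_end - ic$t_start) * 1e-9)
  expect_equal(q_sum, sum(tj$events$direction) * e, tolerance = 1e-9)
  # and the average current equals the same charge over the total time
  expect_equal(average_current(tj$events, tj$total_time),
               q_sum / (tj$total_time * 1e-9) * 1e12, tolerance = 1e-9)
})

test_that("average current converts events to pA correctly", {
  ev <- data.frame(entry = seq(0, 90, 10), exit = seq(5, 95, 10),
                   direction = rep(1L, 10))
  # 10 translocations in 100 ns = 0.1 e/ns = 16.02 pA
  expect_equal(average_current(ev, 100), 16.02177, tolerance = 1e-4)
  expect_equal(average_current(ev, 100, signed = FALSE), 16.02177,
               tolerance = 1e-4)
  expect_error(average_current(ev, 0), "> 0")
})

test_that("escape rates track the MFPT oracle within a factor 1.5", {
  # central barrier of height h plus a high confining wall at the left edge,
  # so escape from the well at z ~ -1 is barrier-limited (Kramers setting)
  W_of <- function(h) function(z) {
    h * exp(-z^2 / (2 * 0.25^2)) + 6 * exp(-(z + 2)^2 / (2 * 0.3^2))
  }
  box <- c(-2, 2); D <- 1.33
  rates_sim <- numeric(2); rates_orc <- numeric(2)
  hs <- c(1, 2.5)
  for (i in seq_along(hs)) {
    W <- W_of(hs[i])
    set.seed(410 + i)
    tj <- brownian_transport(W = W, D = D, box = box, z_inj = -1,
                             n_grid = 128, dt = 2e-5, n_steps = 1.5e7,
                             stride = 1000L)
    rates_sim[i] <- nrow(tj$events) / tj$total_time
    rates_orc[i] <- 1 / oracle_mfpt(W, D, box[1], box[2], -1)
    expect_gt(nrow(tj$events), 10)
    expect_lt(rates_sim[i] / rates_orc[i], 1.5)
    expect_gt(rates_sim[i] / rates_orc[i], 1 / 1.5)
  }
  # Kramers trend: higher barrier, slower escape
  expect_lt(rates_sim[2], rates_sim[1])
})

test_that("unstable time steps are rejected with a stable suggestion", {
  W <- function(z) 5 * exp(-z^2 / 0.5)
  err <- tryCatch(brownian_transport(W = W, D = 1.33, box = c(-2, 2),
                                     n_grid = 256, dt = 0.5, n_steps = 10),
                  error = conditionMessage)
  expect_match(err, "unstable time step")
  expect_match(err, "use dt <=")
  # the suggested dt is accepted
  dt_ok <- as.numeric(sub(".*use dt <= ([0-9.e-]+) ns.*", "\\1", err))
  expect_silent(brownian_transport(W = W, D = 1.33, box = c(-2, 2),
                                   n_grid = 256, dt = dt_ok, n_steps = 100))
})
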