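test_that("a noiseless logistic occupancy returns its midpoint exactly", {
  # synthetic occupancy: many samples per force bin with S fractions on an
  # exact two-state curve centred at 65
  f <- rep(seq(61, 69, 0.25), each = 400)
  p <- two_state_ps(f, 65, 10.8)
  st <- ifelse(stats::ave(seq_along(f), f, FUN = seq_along) <= 400 * p,
               "S", "B")
  states <- data.frame(force = f, state = st, cycle = rep(1:4, length.out = length(f)))
  est <- estimate_ftr(states, n_boot = 0)
  expect_equal(est$F_tr_hat, 65, tolerance = 0.02)
})

test_that("occupancy that never crosses one half is an error", {
  states <- data.frame(force = rep(seq(56, 60, 0.25), each = 50),
                       state = "B", cycle = 1)
  expect_error(estimate_ftr(states, n_boot = 0), "no midpoint")
})

test_that("transition force is recovered within 0.2 pN at full depth", {
  fx <- unmodified_fixture()
  est <- estimate_ftr(fx$det$states, n_boot = 0)
  expect_lt(abs(est$F_tr_hat - fx$construct$F_tr), 0.2)
})

test_that("mean transition extension matches constants and presets", {
  ev <- data.frame(cycle = rep(1:5, 4), time = 1:20, direction = "BtoS",
                   force = 63.7, delta_x = 10.8)
  class(ev) <- c("event_log", "data.frame")
  expect_equal(mean_transition_extension(ev)$dX_hat, 10.8)
  expect_error(mean_transition_extension(ev[1:5, ]), "at least")
  fx <- unmodified_fixture()
  est <- mean_transition_extension(fx$det$events)
  expect_lt(abs(est$dX_hat - 10.8) / 10.8, 0.03)
})

test_that("jump work reproduces the equilibrium free energy", {
  kbt <- boltzmann_energy()
  ev1 <- data.frame(cycle = rep(1, 10), time = 1:10, direction = "BtoS",
                    force = 63.7, delta_x = 10.8)
  class(ev1) <- c("event_log", "data.frame")
  G1 <- transition_free_energy(ev1, kbt)$G_BS
  expect_equal(G1, 63.7 * 10.8 / kbt, tolerance = 1e-12)
  expect_lt(abs(G1 - 168.0) / 168.0, 0.003)   # the measured table value
  ev0 <- ev1; ev0$delta_x <- 0
  expect_equal(transition_free_energy(ev0, kbt)$G_BS, 0)
  expect_error(transition_free_energy(ev1[0, ], kbt), "empty")
  # recovery from the simulated dataset
  fx <- unmodified_fixture()
  G <- transition_free_energy(fx$det$events, kbt)$G_BS
  truth <- fx$construct$F_tr * fx$construct$dX_tr / kbt
  expect_lt(abs(G - truth) / truth, 0.02)
})

test_that("Bennett acceptance ratio solves the two-sided estimator", {
  # degenerate delta distributions reduce to the common work
  expect_equal(bar_free_energy(168, 168), 168, tolerance = 1e-6)
  # Crooks-symmetric Gaussian oracle: forward N(dG + s^2/2, s^2),
  # reverse N(dG - s^2/2, s^2)
  set.seed(10)
  s <- 2; dG <- 150; n <- 1e4
  wf <- rnorm(n, dG + s^2 / 2, s)
  wr <- rnorm(n, dG - s^2 / 2, s)
  expect_equal(bar_free_energy(wf, wr), dG, tolerance = 0.1)
  expect_error(bar_free_energy(numeric(), 1), "non-empty")
})

test_that("BAR on simulated hopping sits at or just below the mean work", {
  fx <- unmodified_fixture()
  kbt <- boltzmann_energy()
  ev <- fx$det$events
  G_mean <- transition_free_energy(ev, kbt)$G_BS
  wf <- ev$force[ev$direction == "BtoS"] * ev$delta_x[ev$direction == "BtoS"] / kbt
  wr <- ev$force[ev$direction == "StoB"] * ev$delta_x[ev$direction == "StoB"] / kbt
  G_bar <- bar_free_energy(wf, wr)
  expect_lte(G_bar, G_mean + 1e-6)
  expect_lt(G_mean - G_bar, 2)
})

test_that("per-bp quantities follow n = dX/x_BS and g = G/n", {
  pb <- per_bp_quantities(10.8, 168.0)
  expect_equal(pb$n_hat, 10.8 / 0.23)
  expect_equal(168.0 / 47.2, 3.56, tolerance = 0.005)
  expect_equal(per_bp_quantities(13.8, 100)$n_hat, 60, tolerance = 1e-12)
  expect_error(per_bp_quantities(0, 100), "undefined|positive")
  expect_error(per_bp_quantities(10, 100, x_BS = 0), "positive")
})

test_that("stabilisation free energies reproduce the measured table", {
  g_ref <- 168.0 / 47.2
  expect_equal(stabilization_dG(168.0, 47.2, g_ref), 0, tolerance = 1e-12)
  # modified duplexes against their printed values, within printed SEMs
  expect_lt(abs(stabilization_dG(157.9, 43.5, g_ref) - 3.04), 0.62)
  expect_lt(abs(stabilization_dG(149.5, 41.0, g_ref) - 3.69), 0.58)
  expect_lt(abs(stabilization_dG(147.2, 40.1, g_ref) - 4.41), 0.57)
  expect_lt(abs(stabilization_dG(142.7, 38.5, g_ref) - 5.39), 0.55)
})

test_that("the fraying slope is recovered and vanishes without fraying", {
  fx <- unmodified_fixture()
  fr <- extension_force_regression(fx$det$events)
  expect_lt(abs(fr$fray_slope_hat - 1.0), 0.15)
  # no fraying: slope consistent with zero
  cm0 <- construct_model("nofray", 63.7, 10.8, k_tr = 5, fray_slope = 0)
  sim0 <- simulate_cycle(cm0, ramp_protocol(n_cycles = 30), seed = 9)
  tr0 <- add_noise(sim0$trace, 0.2)
  det0 <- detect_dataset(tr0)
  fr0 <- extension_force_regression(det0$events)
  expect_lt(abs(fr0$fray_slope_hat), 3 * fr0$se + 0.05)
  # degenerate input: no force spread
  ev <- data.frame(cycle = 1, time = 1:40, direction = "BtoS",
                   force = 63.7, delta_x = 10.8)
  class(ev) <- c("event_log", "data.frame")
  expect_error(extension_force_regression(ev), "force spread")
})

test_that("the g consistency triangle closes on simulated data", {
  fx <- unmodified_fixture()
  eq <- equilibrium_analysis(fx$det, n_boot = 0)
  g_from_ftr <- eq$F_tr_hat * 0.23 / boltzmann_energy()
  expect_lt(abs(eq$g_hat - g_from_ftr) / g_from_ftr, 0.02)
  expect_lte(eq$n_hat, 60)
})
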