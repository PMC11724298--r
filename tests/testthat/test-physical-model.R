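test_that("thermal energy follows kB*T and rejects nonphysical temperatures", {
  expect_equal(boltzmann_energy(23), 0.0138065 * 296.15)
  expect_equal(boltzmann_energy(23), 4.089, tolerance = 1e-3)
  expect_error(boltzmann_energy(-273.15), "absolute zero|nonphysical")
  expect_error(boltzmann_energy(-300), "absolute zero|nonphysical")
  # 1 kBT at 25 C in kcal/mol, from first principles:
  # pN nm = 1e-21 J; times Avogadro, over 4184 J/kcal
  kcal_per_kbt <- boltzmann_energy(25) * 1e-21 * 6.02214076e23 / 4184
  expect_equal(kcal_per_kbt, bs_constants()$kcal_per_kBT, tolerance = 0.01)
})

test_that("two-state occupancy has the right midpoint, slope and limits", {
  expect_identical(two_state_ps(63.7, 63.7, 10.8), 0.5)
  kbt <- boltzmann_energy()
  expect_equal(two_state_ps(63.7 + kbt / 10.8, 63.7, 10.8),
               1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(two_state_ps(1e6, 63.7, 10.8), 1.0)
  expect_equal(two_state_ps(-1e6, 63.7, 10.8), 0.0)
  f <- seq(55, 72, 0.1)
  expect_true(all(diff(two_state_ps(f, 63.7, 10.8)) >= 0))
  expect_error(two_state_ps(60, 63.7, -1), "positive")
})

test_that("Bell-Evans rates cross at F_tr with exponential force dependence", {
  kbt <- boltzmann_energy()
  expect_equal(bell_evans_rate(63.7, 5, 63.7, 6.4, "BtoS"), 5)
  expect_equal(bell_evans_rate(63.7, 5, 63.7, 4.2, "StoB"), 5)
  # e-fold every kbt/x_ts (~0.64 pN for the measured 6.4 nm distance)
  efold <- kbt / 6.4
  expect_equal(bell_evans_rate(63.7 + efold, 5, 63.7, 6.4, "BtoS"),
               5 * exp(1), tolerance = 1e-12)
  expect_equal(bell_evans_rate(63.7 + kbt / 4.2, 5, 63.7, 4.2, "StoB"),
               5 / exp(1), tolerance = 1e-12)
  f <- seq(60, 68, 0.5)
  expect_true(all(diff(bell_evans_rate(f, 5, 63.7, 6.4, "BtoS")) > 0))
  expect_true(all(diff(bell_evans_rate(f, 5, 63.7, 4.2, "StoB")) < 0))
  expect_error(bell_evans_rate(63, 5, 63.7, -1, "BtoS"), "positive")
})

test_that("frayed extension shrinks 1 nm per pN and floors at zero", {
  cm <- construct_model("u", 63.7, 10.8, 5)
  expect_equal(frayed_extension(63.7, cm), 10.8)
  expect_equal(frayed_extension(64.7, cm), 9.8)
  expect_equal(frayed_extension(1e3, cm), 0)
  f <- seq(56, 70, 0.5)
  dx <- frayed_extension(f, cm)
  pos <- dx > 0
  expect_equal(diff(dx[pos]) / 0.5, rep(-cm$fray_slope, sum(pos) - 1))
})

test_that("branch geometry separates the states by the frayed extension", {
  cm <- construct_model("u", 63.7, 10.8, 5)
  f <- seq(55, 72, 0.5)
  gap <- branch_distance(f, "S", cm) - branch_distance(f, "B", cm)
  expect_equal(gap, frayed_extension(f, cm), tolerance = 1e-9)
  # anchor: force at the branch's own distance returns the same force
  d <- branch_distance(f, "B", cm)
  expect_equal(branch_force(d, "B", cm), f, tolerance = 1e-9)
  dS <- branch_distance(f, "S", cm)
  expect_equal(branch_force(dS, "S", cm), f, tolerance = 1e-9)
  # force strictly increasing in the recorded distance on both branches
  expect_true(all(diff(branch_force(seq(600, 720, 1), "B", cm)) > 0))
  expect_true(all(diff(branch_force(seq(600, 720, 1), "S", cm)) > 0))
  expect_error(branch_force(650, "Q", cm), "unknown state")
  expect_error(construct_model("u", 63.7, 10.8, 5, b_branch = c(-1, 0)),
               "stiffness")
})

test_that("kinetic and thermodynamic parameterisations satisfy detailed balance", {
  cm <- construct_model("u", 63.7, 10.8, 5)
  kbt <- boltzmann_energy()
  f <- seq(58, 70, 0.25)
  kf <- bell_evans_rate(f, cm$k_tr, cm$F_tr, cm$X_b_ts, "BtoS", kbt)
  kr <- bell_evans_rate(f, cm$k_tr, cm$F_tr, cm$X_s_ts, "StoB", kbt)
  expect_equal(kf / (kf + kr), two_state_ps(f, cm$F_tr, cm$dX_tr, kbt),
               tolerance = 1e-12)
})

test_that("per-bp free energy from F_tr agrees with the measured value", {
  g_direct <- 63.7 * 0.23 / boltzmann_energy()
  expect_equal(g_direct, 3.58, tolerance = 0.01)
  expect_lt(abs(g_direct - 3.56) / 3.56, 0.02)
})

test_that("construct invariants are enforced and presets are consistent", {
  expect_error(construct_model("x", 63.7, 10.8, 5, X_b_ts = 6.4, X_s_ts = 4.2),
               "detailed balance")
  cm <- construct_model("x", 63.7, 10.6, 5, X_b_ts = 6.4, X_s_ts = 4.2)
  expect_equal(cm$X_b_ts + cm$X_s_ts, cm$dX_tr, tolerance = 1e-12)
  expect_error(construct_model("x", -1, 10.8, 5), "positive")
  expect_error(construct_model("x", 63.7, 10.8, -2), "nonnegative")
  for (nm in c("Unmodified", "1tC", "2tC", "2tC-Stack", "3tC",
               "Unmodified-Int", "Unmodified-Low")) {
    cm <- construct_preset(nm)
    expect_s3_class(cm, "construct_model")
    expect_equal(cm$X_b_ts + cm$X_s_ts, cm$dX_tr, tolerance = 1e-9)
    expect_true(cm$F_tr > 55 && cm$F_tr < 72)
  }
  expect_error(construct_preset("nope"), "unknown preset")
})

test_that("constructs serialise to JSON and back losslessly", {
  cm <- construct_preset("Unmodified")
  path <- tempfile(fileext = ".json")
  constructs_to_json(list(cm), path)
  back <- constructs_from_json(path)[[1]]
  expect_equal(back[names(back) != "name"], cm[names(cm) != "name"],
               tolerance = 1e-12)
  expect_identical(back$name, cm$name)
})

test_that("pure functions return identical output on identical input", {
  a <- two_state_ps(64.2, 63.7, 10.8)
  b <- two_state_ps(64.2, 63.7, 10.8)
  expect_identical(a, b)
  cm <- construct_model("u", 63.7, 10.8, 5)
  expect_identical(frayed_extension(64.1, cm), frayed_extension(64.1, cm))
})
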