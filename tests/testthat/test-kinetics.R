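test_that("transition-force densities normalise and peak at F_tr", {
  set.seed(1)
  ev <- data.frame(cycle = 1, time = seq_len(200),
                   direction = rep(c("BtoS", "StoB"), 100),
                   force = runif(200, 60, 66), delta_x = 10)
  class(ev) <- c("event_log", "data.frame")
  dens <- force_densities(ev)
  trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  expect_equal(trapz(dens$force, dens$dens_BtoS), 1, tolerance = 1e-6)
  expect_equal(trapz(dens$force, dens$dens_StoB), 1, tolerance = 1e-6)
  expect_error(force_densities(ev[1:10, ]), "at least")
  # simulated hopping: both densities peak near the transition force,
  # the forward one just above it and the reverse one just below
  fx <- unmodified_fixture()
  d2 <- force_densities(fx$det$events)
  peak_f <- d2$force[which.max(d2$dens_BtoS)]
  peak_r <- d2$force[which.max(d2$dens_StoB)]
  expect_lt(abs(peak_f - 63.7), 1)
  expect_lt(abs(peak_r - 63.7), 1)
  expect_gt(peak_f, peak_r)
})

test_that("the product-limit estimator matches the hand-computed case", {
  dw <- data.frame(state = "B",
                   entry_force = c(55, 55, 55),
                   exit_force = c(62, 63, 64),
                   entry_time = c(0, 0, 0), exit_time = c(1.4, 1.6, 1.8),
                   exit_kind = "transition", ramp = "stretch", cycle = 1:3)
  class(dw) <- c("dwell_table", "data.frame")
  surv <- survival_curves(dw, F_tr = 63.7, min_dwells = 1)
  km <- surv$B$km
  expect_equal(km$surv[km$force == 62], 2 / 3)
  expect_equal(km$surv[km$force == 63], 1 / 3)
  expect_equal(km$surv[km$force == 64], 0)
  # all censored: survival stays at one
  dw2 <- dw
  dw2$exit_kind <- "censored"
  s2 <- survival_curves(dw2, F_tr = 63.7, min_dwells = 1)
  expect_true(all(s2$B$km$surv == 1))
})

test_that("constant-hazard dwells reproduce the analytic survival and rate", {
  # exponential escape at fixed rate k under loading rate r:
  # S(F) = exp(-k (F - F0) / r) and a flat reconstructed k(F)
  k_true <- 5; r <- 5; F0 <- 55; Fmax <- 72
  set.seed(20)
  n <- 4000
  exit <- F0 + r * rexp(n, k_true)
  cens <- exit > Fmax
  exit[cens] <- Fmax
  dw <- data.frame(state = "B", entry_force = F0, exit_force = exit,
                   entry_time = 0, exit_time = (exit - F0) / r,
                   exit_kind = ifelse(cens, "censored", "transition"),
                   ramp = "stretch", cycle = seq_len(n))
  class(dw) <- c("dwell_table", "data.frame")
  surv <- survival_curves(dw, F_tr = 63.7, min_dwells = 1)
  km <- surv$B$km
  grid <- km$force[km$force < 60 & km$surv > 0.02]
  expect_lt(max(abs(log(km$surv[km$force %in% grid]) -
                      (-k_true * (grid - F0) / r))), 0.15)
  rates <- rates_from_survival(surv, loading_rate = r)
  rb <- rates[rates$direction == "BtoS" & rates$d >= 20, ]
  # flat within the Poisson error of each bin, and the pooled estimate
  # within 10% of the truth
  expect_true(all(abs(rb$k - k_true) < 3 * k_true / sqrt(rb$d) + 0.05))
  pooled <- sum(rb$k * rb$d) / sum(rb$d)
  expect_lt(abs(pooled - k_true) / k_true, 0.10)
  slope <- coef(lm(k ~ force, rb, weights = rb$d))[2]
  expect_lt(abs(slope), 0.2)
})

test_that("exact Bell-Evans rate tables are fitted to numerical precision", {
  kbt <- boltzmann_energy()
  f <- seq(62, 66, 0.25)
  rates <- rbind(
    data.frame(force = f, direction = "BtoS",
               k = bell_evans_rate(f, 5, 63.7, 6.4, "BtoS"),
               se_log_k = 0.1, d = 50),
    data.frame(force = f, direction = "StoB",
               k = bell_evans_rate(f, 5, 63.7, 4.2, "StoB"),
               se_log_k = 0.1, d = 50))
  be <- fit_bell_evans(rates, 63.7)
  expect_equal(be$X_b_ts_hat, 6.4, tolerance = 1e-3)
  expect_equal(be$X_s_ts_hat, 4.2, tolerance = 1e-3)
  expect_equal(be$F_cross, 63.7, tolerance = 1e-6)
  expect_equal(be$k_at_ftr, 5, tolerance = 1e-3)
  expect_equal(be$ts_fraction, 100 * 6.4 / 10.6, tolerance = 0.1)
  expect_false(be$non_two_state)
  # swapped slopes are flagged
  swapped <- rates
  swapped$direction <- ifelse(rates$direction == "BtoS", "StoB", "BtoS")
  expect_warning(fit_bell_evans(swapped, 63.7), "non-two-state")
})

test_that("ground-truth dwells recover the transition-state distances", {
  fx <- small_fixture()
  dw <- truth_dwells(fx$sim)
  surv <- survival_curves(dw, F_tr = fx$construct$F_tr)
  rates <- rates_from_survival(surv, loading_rate(fx$protocol))
  be <- fit_bell_evans(rates, fx$construct$F_tr)
  expect_lt(abs(be$X_b_ts_hat - fx$construct$X_b_ts) / fx$construct$X_b_ts, 0.10)
  expect_lt(abs(be$X_s_ts_hat - fx$construct$X_s_ts) / fx$construct$X_s_ts, 0.10)
  expect_lt(abs(be$F_cross - fx$construct$F_tr), 0.5)
  expect_lt(abs(be$k_at_ftr - fx$construct$k_tr) / fx$construct$k_tr, 0.25)
})

test_that("transition counts average over cycles including empty ones", {
  ev <- data.frame(cycle = c(1, 1, 2), time = 1:3,
                   direction = c("BtoS", "StoB", "BtoS"),
                   force = 63.7, delta_x = 10.8)
  class(ev) <- c("event_log", "data.frame")
  cnt <- transition_counts(ev, n_cycles = 4)
  expect_equal(cnt$N, 3 / 4)
  empty <- ev[0, ]
  expect_equal(transition_counts(empty)$N, 0)
  # the generator's event count matches the study's per-cycle average
  fx <- unmodified_fixture()
  cnt2 <- transition_counts(fx$sim$events, n_cycles = 176)
  expect_lt(abs(cnt2$N - 25), max(3 * cnt2$sem, 1.5))
  expect_lt(abs(cnt2$peak_force - 63.7), 1)
})

test_that("a more modified duplex hops more often", {
  fx <- small_fixture()
  cm3 <- construct_preset("3tC")
  sim3 <- simulate_cycle(cm3, fx$protocol, seed = 2)
  N_u <- nrow(fx$sim$events) / 40
  N_3 <- nrow(sim3$events) / 40
  expect_gt(N_3, N_u)
})

test_that("the per-bp barrier follows from the count scaling", {
  # two-construct reduction
  two <- barrier_per_bp(c(47.2, 38.5), c(25, 65))
  expect_equal(two$g_ts, log(65 / 25) / (47.2 - 38.5), tolerance = 1e-12)
  expect_equal(round(two$g_ts, 2), 0.11)
  # five constructs measured at the same salt and pulling rate
  tab <- preset_table()[1:5, ]
  fit <- barrier_per_bp(tab$n, tab$N)
  expect_equal(round(fit$g_ts, 2), 0.11)
  expect_equal(barrier_per_bp(c(40, 45), c(30, 30))$g_ts, 0)
  expect_error(barrier_per_bp(c(40, 40), c(30, 50)), "equal")
})

test_that("the attempt rate exponentiates the extensive barrier", {
  expect_equal(attempt_rate(1, 47, 0.1)$k0_BS, exp(4.7), tolerance = 1e-12)
  expect_gt(attempt_rate(1, 47, 0.1)$k0_BS, 100)
  expect_lt(attempt_rate(1, 47, 0.1)$k0_BS, 1000)
  expect_gt(attempt_rate(10, 47, 0.1)$k0_BS, 1000 - 1)
  expect_equal(attempt_rate(7, 47, 0)$k0_BS, 7)
  expect_equal(attempt_rate(1, 1e4, 0.5)$k0_BS, Inf)
  expect_equal(attempt_rate(1, 1e4, 0.5)$log10_k0_BS, 5000 / log(10))
})

test_that("rates and occupancy tell a consistent equilibrium story", {
  fx <- small_fixture()
  eq <- estimate_ftr(fx$det$states, n_boot = 0)
  dw <- truth_dwells(fx$sim)
  surv <- survival_curves(dw, F_tr = eq$F_tr_hat)
  rates <- rates_from_survival(surv, loading_rate(fx$protocol))
  # on bins where both directions are measured, k_f/(k_f + k_r) tracks the
  # occupancy within 10%
  shared <- intersect(rates$force[rates$direction == "BtoS"],
                      rates$force[rates$direction == "StoB"])
  shared <- shared[abs(shared - eq$F_tr_hat) <= 1]
  kf <- rates$k[rates$direction == "BtoS"][match(shared, rates$force[rates$direction == "BtoS"])]
  kr <- rates$k[rates$direction == "StoB"][match(shared, rates$force[rates$direction == "StoB"])]
  p_kin <- kf / (kf + kr)
  dX_hat <- mean_transition_extension(fx$det$events)$dX_hat
  p_occ <- two_state_ps(shared, eq$F_tr_hat, dX_hat)
  expect_lt(mean(abs(p_kin - p_occ)), 0.10)
  expect_lt(max(abs(p_kin - p_occ)), 0.20)
})

test_that("per-bp transition-state distances are construct independent", {
  tab <- preset_table()[1:5, ]
  x_b <- tab$X_b_ts / tab$n_kin
  x_s <- tab$X_s_ts / tab$n_kin
  expect_lt(diff(range(x_b)), 0.01 + 1e-9)
  expect_lt(diff(range(x_s)), 0.01 + 1e-9)
  expect_equal(round(mean(x_b), 2), 0.14)
  expect_equal(round(mean(x_s), 2), 0.09)
})
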