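# Shared simulated fixtures, built once per test run and memoised.
# All fixtures use fixed seeds so every run sees identical data.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# Slow-hopping construct: every dwell is long compared to the 1 kHz
# recording, so the detector can be held to exact closure against the
# generator's event log.
slow_construct <- function(k_tr = 2)
  construct_model("slow", F_tr = 63.7, dX_tr = 10.8, k_tr = k_tr,
                  ts_fraction = 6.4 / 10.6)

# Study-condition fixture: the Unmodified preset at the default protocol,
# full 176 cycles, 0.2 pN noise. This is the parameter-recovery dataset.
unmodified_fixture <- function() {
  fixture("unmodified176", function() {
    cm <- construct_preset("Unmodified")
    pr <- ramp_protocol(n_cycles = 176)
    set.seed(1)
    sim <- simulate_cycle(cm, pr)
    trace <- add_noise(sim$trace, pr$noise_sigma_F)
    det <- detect_dataset(trace)
    list(construct = cm, protocol = pr, sim = sim, trace = trace,
         det = det)
  })
}

# Smaller noisy fixture for cheaper checks.
small_fixture <- function() {
  fixture("unmodified40", function() {
    cm <- construct_preset("Unmodified")
    pr <- ramp_protocol(n_cycles = 40)
    set.seed(2)
    sim <- simulate_cycle(cm, pr)
    trace <- add_noise(sim$trace, pr$noise_sigma_F)
    det <- detect_dataset(trace)
    list(construct = cm, protocol = pr, sim = sim, trace = trace,
         det = det)
  })
}

# Build a dwell table from the generator's own event log (no detection),
# used as the ground-truth route through the survival machinery.
truth_dwells <- function(sim) {
  halves <- segment_cycles(sim$trace)
  dw <- lapply(halves, function(h) {
    evh <- sim$events[sim$events$time >= min(h$time) &
                        sim$events$time <= max(h$time), ]
    class(evh) <- c("event_log", "data.frame")
    extract_dwells(h, evh)
  })
  out <- do.call(rbind, dw)
  class(out) <- c("dwell_table", "data.frame")
  out
}
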