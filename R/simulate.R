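#' Simulate stretch/release force-distance cycles
#'
#' Kinetic Monte Carlo generator of the optical-tweezers protocol: the trap
#' moves at constant velocity so the force ramps between `F_min` and `F_max`
#' at loading rate `K_trap * velocity`; at every substep the occupied state
#' may hop with probability `1 - exp(-k(F) dt)`, with Bell-Evans rates
#' pivoted at the transition force. A B-to-S switch at force F drops the
#' force by `K_eff * frayed_extension(F)`; an S-to-B switch raises it by the
#' same amount. Each cycle starts in the B state at `F_min` and the state
#' carries over from the stretch to the release half-cycle.
#'
#' The returned trace is noise-free; add measurement noise with
#' [add_noise()] (done automatically by [simulate_dataset()]).
#'
#' @param construct a [construct_model()].
#' @param protocol a [ramp_protocol()]; `F_tr` must lie inside its force
#'   window.
#' @param n_cycles number of stretch+release cycles; defaults to the
#'   protocol's.
#' @param seed optional integer seed (`set.seed` is called if supplied).
#' @param dt simulation substep, s. Default 1e-4 (10x finer than the 1 kHz
#'   recording). Refused if hopping rates within +-1 pN of `F_tr` are not
#'   resolved (`k dt > 0.1`).
#' @param record_truth keep the ground-truth state per sample.
#' @return a list with `trace` (class `fdc_trace`: time, trap_position,
#'   force, cycle_id, direction, truth_state) and `events` (class
#'   `event_log`: cycle, time, direction, force, delta_x) recording every
#'   switch at substep resolution.
#' @examples
#' cm <- construct_model("demo", 63.7, 10.8, 2)
#' sim <- simulate_cycle(cm, ramp_protocol(n_cycles = 1), seed = 1)
#' nrow(sim$events)
#' @export
simulate_cycle <- function(construct, protocol, n_cycles = protocol$n_cycles,
                           seed = NULL, dt = 1e-4, record_truth = TRUE) {
  stopifnot(inherits(construct, "construct_model"),
            inherits(protocol, "ramp_protocol"))
  if (construct$F_tr <= protocol$F_min || construct$F_tr >= protocol$F_max)
    stop("`F_tr` must lie inside the ramp window [F_min, F_max]")
  k_window <- construct$k_tr *
    exp(max(construct$X_b_ts, construct$X_s_ts) * 1 / boltzmann_energy())
  if (k_window * dt > 0.1)
    stop("substep too coarse: k*dt > 0.1 within the hopping window; reduce `dt`")
  if (!is.null(seed)) set.seed(seed)

  r <- loading_rate(protocol)
  K_eff <- construct$b_branch[1]
  sample_every <- round(1 / (protocol$sample_rate * dt))
  if (sample_every < 1)
    stop("`dt` must not be coarser than the sampling interval")

  raw <- .sim_cycles_cpp(
    n_cycles = as.integer(n_cycles),
    F_min = protocol$F_min, F_max = protocol$F_max,
    rate_load = r, K_eff = K_eff, branch_d0 = construct$b_branch[2],
    F_tr = construct$F_tr, dX_tr = construct$dX_tr,
    fray_slope = construct$fray_slope,
    X_b_ts = construct$X_b_ts, X_s_ts = construct$X_s_ts,
    k_tr = construct$k_tr, kbt = boltzmann_energy(),
    dt = dt, sample_every = as.integer(sample_every),
    record_truth = record_truth)

  s <- raw$samples
  trace <- data.frame(
    time = s$time, trap_position = s$trap_position, force = s$force,
    cycle_id = s$cycle,
    direction = ifelse(s$direction > 0, "stretch", "release"),
    stringsAsFactors = FALSE)
  if (record_truth) trace$truth_state <- ifelse(s$state > 0, "S", "B")
  attr(trace, "protocol") <- protocol
  attr(trace, "construct") <- construct$name
  class(trace) <- c("fdc_trace", "data.frame")

  e <- raw$events
  events <- data.frame(
    cycle = e$cycle, time = e$time,
    direction = ifelse(e$direction > 0, "BtoS", "StoB"),
    force = e$force, force_after = e$force_after,
    delta_x = e$delta_x, stringsAsFactors = FALSE)
  class(events) <- c("event_log", "data.frame")
  list(trace = trace, events = events)
}

#' Simulate a multi-construct dataset
#'
#' Runs [simulate_cycle()] for each construct, adds Gaussian force noise at
#' the protocol's `noise_sigma_F`, and stamps per-construct metadata. All
#' randomness flows from the one root seed, so the same seed reproduces the
#' dataset exactly.
#'
#' @param constructs a [construct_model()] or list of them.
#' @param protocol a [ramp_protocol()].
#' @param n_cycles cycles per construct; a single count or one per
#'   construct. Defaults to the protocol's.
#' @param seed integer root seed (required: simulation runs must be
#'   reproducible).
#' @return named list (by construct) of `list(trace, events)`.
#' @export
simulate_dataset <- function(constructs, protocol,
                             n_cycles = protocol$n_cycles, seed) {
  if (inherits(constructs, "construct_model")) constructs <- list(constructs)
  if (length(constructs) == 0) stop("empty construct list")
  if (missing(seed) || is.null(seed)) stop("`seed` is required for simulation")
  n_cycles <- rep_len(n_cycles, length(constructs))
  set.seed(as.integer(seed))
  out <- vector("list", length(constructs))
  names(out) <- vapply(constructs, `[[`, "", "name")
  for (i in seq_along(constructs)) {
    sim <- simulate_cycle(constructs[[i]], protocol, n_cycles = n_cycles[i])
    sim$trace <- add_noise(sim$trace, protocol$noise_sigma_F)
    out[[i]] <- sim
  }
  out
}

#' Add Gaussian measurement noise to the force channel
#'
#' @param trace an `fdc_trace`.
#' @param sigma_F standard deviation of the i.i.d. Gaussian force noise, pN.
#' @return the trace with perturbed force; ground-truth columns untouched.
#' @export
add_noise <- function(trace, sigma_F) {
  stopifnot(inherits(trace, "fdc_trace"))
  if (!is.numeric(sigma_F) || sigma_F < 0) stop("`sigma_F` must be >= 0")
  if (sigma_F > 0) trace$force <- trace$force + rnorm(nrow(trace), 0, sigma_F)
  trace
}

#' Force-clamp simulation
#'
#' Holds the force fixed (trap velocity zero) and lets the duplex hop
#' between B and S; the long-run fraction of time in S converges to the
#' two-state occupancy [two_state_ps()], which makes this the detailed
#' balance check of the generator.
#'
#' @param construct a [construct_model()].
#' @param F clamp force, pN.
#' @param duration simulated time, s.
#' @param seed optional integer seed.
#' @param dt substep, s.
#' @return list with `fraction_S`, `n_switch`, and the sampled `time` /
#'   `state` series.
#' @export
simulate_clamp <- function(construct, F, duration, seed = NULL, dt = 1e-4) {
  stopifnot(inherits(construct, "construct_model"))
  if (duration <= 0) stop("`duration` must be positive")
  if (!is.null(seed)) set.seed(seed)
  raw <- .sim_clamp_cpp(F = F, duration = duration,
                        F_tr = construct$F_tr,
                        X_b_ts = construct$X_b_ts, X_s_ts = construct$X_s_ts,
                        k_tr = construct$k_tr, kbt = boltzmann_energy(),
                        dt = dt, sample_every = 10L)
  list(time = raw$time, state = ifelse(raw$state > 0, "S", "B"),
       fraction_S = raw$fraction_S, n_switch = raw$n_switch)
}

#' @export
print.fdc_trace <- function(x, ...) {
  cat(sprintf("<fdc_trace> %d samples | %d cycle(s) | construct %s\n",
              nrow(x), length(unique(x$cycle_id)),
              attr(x, "construct") %||% "?"))
  NextMethod()
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("<event_log> %d transitions (%d B->S, %d S->B)\n",
              nrow(x), sum(x$direction == "BtoS"), sum(x$direction == "StoB")))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
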