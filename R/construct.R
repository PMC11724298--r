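#' Physical model of one DNA duplex construct
#'
#' Bundles the ground-truth parameters of a duplex undergoing the B-to-S
#' overstretching transition: the equilibrium transition force, the
#' transition extension at that force, the end-fraying slope, the two
#' Bell-Evans transition-state distances, the hopping rate at the transition
#' force, and the elasticity of the B-state force-distance line as recorded
#' by the instrument (trap-to-bead distance coordinate, so the trap
#' compliance is folded in).
#'
#' The transition-state distances must add up to the transition extension
#' (`X_b_ts + X_s_ts = dX_tr`); otherwise the kinetic parameterisation would
#' violate detailed balance against the two-state occupancy. Supply either
#' both distances (their sum is checked to 1e-9) or `ts_fraction`, the
#' fractional position of the barrier along the B-to-S path.
#'
#' @param name label for the construct.
#' @param F_tr equilibrium transition force, pN.
#' @param dX_tr transition extension at `F_tr`, nm.
#' @param k_tr hopping rate at `F_tr`, 1/s (forward and reverse rates cross
#'   there).
#' @param fray_slope shortening of the transition extension per pN of
#'   transition force, nm/pN; progressive end fraying. Default 1.
#' @param ts_fraction position of the transition state as a fraction of
#'   `dX_tr` measured from the B state. Default 6.4/10.6 (~60%).
#' @param X_b_ts,X_s_ts explicit B-to-TS and TS-to-S distances, nm.
#'   Override `ts_fraction`; their sum must equal `dX_tr`.
#' @param b_branch numeric length-2: slope (pN/nm) and zero-force intercept
#'   (nm) of the B-state force-distance line in the trap-distance
#'   coordinate. The slope is the effective stiffness K_eff, approximately
#'   the trap stiffness because the duplex is much stiffer than the trap.
#' @param s_offset extra contour offset of the S branch beyond the frayed
#'   transition extension, nm. Default 0.
#' @return an object of class `construct_model`.
#' @examples
#' cm <- construct_model("demo", F_tr = 63.7, dX_tr = 10.8, k_tr = 5)
#' cm$X_b_ts + cm$X_s_ts == cm$dX_tr
#' @export
construct_model <- function(name, F_tr, dX_tr, k_tr,
                            fray_slope = 1.0,
                            ts_fraction = 6.4 / 10.6,
                            X_b_ts = NULL, X_s_ts = NULL,
                            b_branch = c(0.0998, 0),
                            s_offset = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  for (v in c(F_tr = F_tr, dX_tr = dX_tr)) {
    if (!is.numeric(v) || !is.finite(v) || v <= 0)
      stop("`F_tr` and `dX_tr` must be positive and finite")
  }
  if (!is.numeric(k_tr) || !is.finite(k_tr) || k_tr < 0)
    stop("`k_tr` must be a nonnegative finite rate (0 disables hopping)")
  if (fray_slope < 0) stop("`fray_slope` must be >= 0 (extension shrinks as force rises)")
  if (length(b_branch) != 2L || b_branch[1] <= 0)
    stop("`b_branch` must be c(stiffness > 0, reference distance)")
  if (is.null(X_b_ts) != is.null(X_s_ts))
    stop("supply both `X_b_ts` and `X_s_ts`, or neither")
  if (is.null(X_b_ts)) {
    if (ts_fraction <= 0 || ts_fraction >= 1)
      stop("`ts_fraction` must lie strictly between 0 and 1")
    X_b_ts <- ts_fraction * dX_tr
    X_s_ts <- dX_tr - X_b_ts
  } else {
    if (X_b_ts <= 0 || X_s_ts <= 0)
      stop("transition-state distances must be positive")
    if (abs(X_b_ts + X_s_ts - dX_tr) > 1e-9)
      stop("`X_b_ts` + `X_s_ts` must equal `dX_tr` (detailed balance)")
  }
  structure(
    list(name = name, F_tr = F_tr, dX_tr = dX_tr, k_tr = k_tr,
         fray_slope = fray_slope, X_b_ts = X_b_ts, X_s_ts = X_s_ts,
         b_branch = as.numeric(b_branch), s_offset = s_offset),
    class = "construct_model"
  )
}

#' @export
print.construct_model <- function(x, ...) {
  cat(sprintf("<construct_model> %s\n", x$name))
  cat(sprintf("  F_tr %.2f pN | dX(F_tr) %.2f nm | fray %.2f nm/pN\n",
              x$F_tr, x$dX_tr, x$fray_slope))
  cat(sprintf("  X_B->TS %.3f nm | X_S->TS %.3f nm | k(F_tr) %.3g 1/s\n",
              x$X_b_ts, x$X_s_ts, x$k_tr))
  invisible(x)
}

#' Force-dependent transition extension under end fraying
#'
#' Extension gained in a single B-to-S jump at force `F`. Higher forces fray
#' more base pairs off the duplex ends before the cooperative transition, so
#' the transition extension shrinks linearly, about 1 nm per pN:
#' `dX(F) = dX_tr - fray_slope * (F - F_tr)`, floored at zero.
#'
#' @param F force, pN. Vectorised.
#' @param construct a [construct_model()].
#' @return transition extension, nm (never negative).
#' @examples
#' cm <- construct_model("demo", 63.7, 10.8, 5)
#' frayed_extension(63.7, cm)       # 10.8
#' frayed_extension(64.7, cm)       # 9.8
#' @export
frayed_extension <- function(F, construct) {
  stopifnot(inherits(construct, "construct_model"))
  pmax(0, construct$dX_tr - construct$fray_slope * (F - construct$F_tr))
}

#' Force on the B or S elastic branch
#'
#' Linear force-distance law of each state in the recorded trap-to-bead
#' distance coordinate. The B branch is the line `F = k (d - d0)` with
#' `(k, d0) = b_branch`; the S branch lies farther out by the current frayed
#' transition extension, so at any force in the operating window the
#' horizontal distance between branches equals [frayed_extension()] (plus
#' any fixed `s_offset`).
#'
#' @param distance trap-to-bead distance, nm. Vectorised.
#' @param state `"B"` or `"S"`.
#' @param construct a [construct_model()].
#' @return force, pN.
#' @export
branch_force <- function(distance, state, construct) {
  stopifnot(inherits(construct, "construct_model"))
  if (!state %in% c("B", "S")) stop("unknown state label: ", state)
  k  <- construct$b_branch[1]
  d0 <- construct$b_branch[2]
  if (state == "B") return(k * (distance - d0))
  # S branch: distance = d0 + F/k + dX(F) + s_offset with
  # dX(F) = dX_tr - fray*(F - F_tr); linear solve for F.
  denom <- 1 / k - construct$fray_slope
  num <- distance - d0 - construct$s_offset - construct$dX_tr -
    construct$fray_slope * construct$F_tr
  if (abs(denom) < 1e-12) stop("degenerate S-branch geometry")
  num / denom
}

#' Trap-distance of a branch at a given force
#'
#' Inverse of [branch_force()]: where on the distance axis the B or S branch
#' sits at force `F`.
#'
#' @inheritParams branch_force
#' @param F force, pN. Vectorised.
#' @return trap-to-bead distance, nm.
#' @export
branch_distance <- function(F, state, construct) {
  stopifnot(inherits(construct, "construct_model"))
  if (!state %in% c("B", "S")) stop("unknown state label: ", state)
  k  <- construct$b_branch[1]
  d0 <- construct$b_branch[2]
  d  <- d0 + F / k
  if (state == "S") d <- d + frayed_extension(F, construct) + construct$s_offset
  d
}

#' Constant-velocity force-ramp protocol
#'
#' Describes one stretch/release measurement: the trap moves at constant
#' velocity so the force ramps between `F_min` and `F_max` at loading rate
#' `K_trap * velocity` (the effective stiffness is ~ the trap stiffness).
#' The loading rate is always derived from `K_trap` and `velocity`, never
#' stored separately.
#'
#' @param F_min,F_max force window, pN. Defaults 55 and 72.
#' @param velocity trap velocity, nm/s. Default 50 (the slow
#'   ramp); 200 for the fast ramp.
#' @param K_trap trap stiffness, pN/nm. Default 0.1.
#' @param sample_rate recording frequency, Hz. Default 1000.
#' @param n_cycles number of stretch+release cycles. Default 1.
#' @param noise_sigma_F Gaussian force-noise standard deviation, pN.
#'   Default 0.2.
#' @return an object of class `ramp_protocol`.
#' @export
ramp_protocol <- function(F_min = 55, F_max = 72, velocity = 50,
                          K_trap = 0.1, sample_rate = 1000,
                          n_cycles = 1L, noise_sigma_F = 0.2) {
  if (F_min >= F_max) stop("`F_min` must be below `F_max`")
  for (v in c(velocity = velocity, K_trap = K_trap, sample_rate = sample_rate)) {
    if (!is.numeric(v) || v <= 0)
      stop("`velocity`, `K_trap` and `sample_rate` must be positive")
  }
  if (n_cycles < 1) stop("`n_cycles` must be >= 1")
  if (noise_sigma_F < 0) stop("`noise_sigma_F` must be >= 0")
  structure(
    list(F_min = F_min, F_max = F_max, velocity = velocity, K_trap = K_trap,
         sample_rate = sample_rate, n_cycles = as.integer(n_cycles),
         noise_sigma_F = noise_sigma_F),
    class = "ramp_protocol"
  )
}

#' Loading rate of a ramp protocol
#'
#' @param protocol a [ramp_protocol()].
#' @return force loading rate `K_trap * velocity`, pN/s.
#' @export
loading_rate <- function(protocol) {
  stopifnot(inherits(protocol, "ramp_protocol"))
  protocol$K_trap * protocol$velocity
}

#' @export
print.ramp_protocol <- function(x, ...) {
  cat(sprintf("<ramp_protocol> %g-%g pN | v %g nm/s | K %g pN/nm | %g Hz | %d cycle(s)\n",
              x$F_min, x$F_max, x$velocity, x$K_trap, x$sample_rate, x$n_cycles))
  cat(sprintf("  loading rate %g pN/s | noise sigma %g pN\n",
              loading_rate(x), x$noise_sigma_F))
  invisible(x)
}
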