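#' Two-state occupancy of the S state
#'
#' Equilibrium probability of finding the duplex in the overstretched S state
#' at force `F`, for a cooperative two-state transition with midpoint `F_tr`
#' and transition extension `dX`:
#' \deqn{P_S(F) = \frac{1}{1 + e^{-\Delta X (F - F_{tr}) / k_BT}}}
#' The midpoint is the transition force: `P_S(F_tr) = 0.5` exactly.
#'
#' @param F force, pN. Vectorised.
#' @param F_tr transition force, pN.
#' @param dX transition extension, nm. Must be positive.
#' @param kbt thermal energy, pN nm. Default [boltzmann_energy()] at 23 C.
#' @return occupancy in `[0, 1]`.
#' @examples
#' two_state_ps(63.7, 63.7, 10.8)          # 0.5
#' two_state_ps(63.7 + 4.089 / 10.8, 63.7, 10.8)  # 1/(1 + exp(-1))
#' @export
two_state_ps <- function(F, F_tr, dX, kbt = boltzmann_energy()) {
  if (!is.numeric(dX) || dX <= 0) stop("`dX` must be a positive extension (nm)")
  if (kbt <= 0) stop("`kbt` must be positive")
  stats::plogis(dX * (F - F_tr) / kbt)
}

#' Bell-Evans force-dependent transition rate
#'
#' Rate of hopping over the transition-state barrier under force, pivoted at
#' the transition force where forward and reverse rates cross:
#' \deqn{k_{B\to S}(F) = k_{tr} e^{+(F - F_{tr}) X_{B\to TS}/k_BT}, \qquad
#'       k_{S\to B}(F) = k_{tr} e^{-(F - F_{tr}) X_{S\to TS}/k_BT}}
#' `x_ts` is the distance from the departing state to the transition state;
#' force tilts the landscape by `F * x_ts`, so the forward rate grows e-fold
#' every `kbt / x_ts` piconewtons while the reverse rate shrinks.
#'
#' @param F force, pN. Vectorised.
#' @param k_tr rate at the transition force, 1/s.
#' @param F_tr transition force, pN.
#' @param x_ts distance to the transition state from the departing state, nm.
#' @param direction `"BtoS"` (force-promoted) or `"StoB"` (force-suppressed).
#' @param kbt thermal energy, pN nm.
#' @return rate in 1/s.
#' @examples
#' bell_evans_rate(63.7, 5, 63.7, 6.4, "BtoS")  # 5 at the crossing point
#' @export
bell_evans_rate <- function(F, k_tr, F_tr, x_ts,
                            direction = c("BtoS", "StoB"),
                            kbt = boltzmann_energy()) {
  direction <- match.arg(direction)
  if (!is.numeric(k_tr) || k_tr < 0) stop("`k_tr` must be a nonnegative rate (1/s)")
  if (!is.numeric(x_ts) || x_ts <= 0) stop("`x_ts` must be a positive distance (nm)")
  if (kbt <= 0) stop("`kbt` must be positive")
  sgn <- if (direction == "BtoS") +1 else -1
  k_tr * exp(sgn * (F - F_tr) * x_ts / kbt)
}
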