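#' Per-bp free-energy profile of the B-to-S transition at F_tr
#'
#' Builds the per-base-pair free energy versus per-bp extension at the
#' transition force: two equal minima at the B extension (x = 0) and the S
#' extension (x = x_BS), separated by a low barrier of height `g_ts`
#' peaking at `x_ts` (~60% of the path), with steep quadratic walls whose
#' curvatures derive from the known stretch moduli of B-DNA (~1000 pN over
#' a 0.34 nm/bp rise) and S-DNA (~3000 pN over 0.58 nm/bp). The wells are
#' joined to the barrier top by cubic Hermite bridges placed at the
#' monotonicity boundary, so the curve is C1, rises monotonically from
#' each well to the single maximum `g_ts` at `x_ts`, and is anchored only
#' by the quantities the analysis measures (barrier height and position,
#' endpoint minima); the interpolant in between is illustrative geometry.
#'
#' @param g_ts barrier height at the transition force, kBT/bp.
#' @param x_ts barrier position, nm/bp (0 < x_ts < x_BS).
#' @param x_BS S-state extension, nm/bp. Default 0.23.
#' @param stiff_B,stiff_S elastic moduli of the B and S wells, pN.
#'   Defaults 1000 and 3000.
#' @param kbt thermal energy, pN nm.
#' @param grid_res extension grid resolution, nm/bp. Default 0.001. The
#'   grid spans `[0, 1.2 x_BS]`.
#' @return object of class `fe_profile`: data.frame with `x` and
#'   `g_at_Ftr`, plus attributes `x_ts`, `g_ts`, `x_BS`.
#' @export
build_profile_at_ftr <- function(g_ts, x_ts, x_BS = 0.23,
                                 stiff_B = 1000, stiff_S = 3000,
                                 kbt = boltzmann_energy(),
                                 grid_res = 0.001) {
  if (g_ts < 0) stop("`g_ts` must be nonnegative")
  if (x_ts <= 0 || x_ts >= x_BS) stop("`x_ts` must lie strictly inside (0, x_BS)")
  if (stiff_B <= 0 || stiff_S <= 0) stop("well moduli must be positive")
  kB <- stiff_B / (0.34 * kbt)   # kBT per nm^2 per bp
  kS <- stiff_S / (0.58 * kbt)
  x <- seq(0, 1.2 * x_BS, by = grid_res)
  wellB <- function(z) 0.5 * kB * z^2
  wellS <- function(z) 0.5 * kS * (z - x_BS)^2

  if (g_ts == 0) {
    # degenerate: flat bridge at zero between the two wells
    g <- numeric(length(x))
    g[x > x_BS] <- wellS(x[x > x_BS])
  } else {
    # join point where the cubic Hermite to the barrier top sits exactly at
    # the Fritsch-Carlson monotonicity boundary (well slope = 3 * secant)
    join_offset <- function(kappa, dist) {
      off <- -dist + sqrt(dist^2 + 6 * g_ts / kappa)
      if (!is.finite(off) || off >= dist)
        stop("inconsistent geometry: barrier below well curvature intersection")
      off
    }
    xj1 <- join_offset(kB, x_ts)
    xj2 <- x_BS - join_offset(kS, x_BS - x_ts)
    hermite <- function(z, x0, x1, y0, y1, m0, m1) {
      h <- x1 - x0
      tt <- (z - x0) / h
      (2 * tt^3 - 3 * tt^2 + 1) * y0 + (tt^3 - 2 * tt^2 + tt) * h * m0 +
        (-2 * tt^3 + 3 * tt^2) * y1 + (tt^3 - tt^2) * h * m1
    }
    g <- numeric(length(x))
    reg <- x <= xj1
    g[reg] <- wellB(x[reg])
    reg <- x > xj1 & x <= x_ts
    g[reg] <- hermite(x[reg], xj1, x_ts, wellB(xj1), g_ts, kB * xj1, 0)
    reg <- x > x_ts & x < xj2
    g[reg] <- hermite(x[reg], x_ts, xj2, g_ts, wellS(xj2), 0, -kS * (x_BS - xj2))
    reg <- x >= xj2
    g[reg] <- wellS(x[reg])
  }
  out <- data.frame(x = x, g_at_Ftr = g)
  attr(out, "x_ts") <- x_ts
  attr(out, "g_ts") <- g_ts
  attr(out, "x_BS") <- x_BS
  class(out) <- c("fe_profile", "data.frame")
  out
}

#' Tilt the free-energy profile to zero force
#'
#' A pulling force F tilts the landscape by `-F x`; removing the tilt of
#' the transition force adds it back: `g(F = 0, x) = g(F_tr, x) +
#' F_tr x / kbt`, pointwise. At the S extension the added term is the
#' equilibrium per-bp free energy `F_tr x_BS / kbt ~ g`.
#'
#' @param profile an `fe_profile` from [build_profile_at_ftr()].
#' @param F_tr transition force, pN.
#' @param kbt thermal energy, pN nm.
#' @return the profile with an added `g_at_zero` column and `F_tr`
#'   attribute.
#' @export
tilt_to_zero_force <- function(profile, F_tr, kbt = boltzmann_energy()) {
  stopifnot(inherits(profile, "fe_profile"))
  profile$g_at_zero <- profile$g_at_Ftr + F_tr * profile$x / kbt
  attr(profile, "F_tr") <- F_tr
  profile
}

#' Is the S state metastable at zero force?
#'
#' Searches the zero-force profile for a local minimum within 10% of the S
#' extension and measures its escape barrier (the maximum the profile
#' rises, towards the B side, above the minimum). The S state counts as
#' metastable only if such a minimum exists with depth above
#' `min_depth` kBT/bp; otherwise the overstretched state is entirely
#' force-induced.
#'
#' @param profile an `fe_profile` that has been tilted with
#'   [tilt_to_zero_force()].
#' @param min_depth minimum escape-barrier depth, kBT/bp. Default 0.05.
#' @return list with `metastable` (logical), `depth` (kBT/bp, 0 when no
#'   local minimum exists near x_BS) and `margin` (= depth - min_depth).
#' @export
classify_metastability <- function(profile, min_depth = 0.05) {
  stopifnot(inherits(profile, "fe_profile"))
  if (is.null(profile$g_at_zero))
    stop("tilt the profile to zero force first")
  x <- profile$x
  g <- profile$g_at_zero
  x_BS <- attr(profile, "x_BS")
  n <- length(g)
  i_min <- which(diff(sign(diff(g))) > 0) + 1L   # interior local minima
  near <- i_min[abs(x[i_min] - x_BS) <= 0.1 * x_BS]
  depth <- 0
  if (length(near) > 0) {
    depths <- vapply(near, function(i) max(g[seq_len(i)]) - g[i], numeric(1))
    depth <- max(depths)
  }
  list(metastable = depth > min_depth, depth = depth,
       margin = depth - min_depth)
}

#' Reconstruct and classify the full free-energy profile
#'
#' Convenience wrapper: builds the profile at the transition force, tilts
#' it to zero force and classifies S-state metastability.
#'
#' @inheritParams build_profile_at_ftr
#' @param F_tr transition force, pN.
#' @return an `fe_profile` with both columns and a `summary` attribute
#'   (barrier position and heights at F_tr and zero force, endpoint value
#'   `g_at_zero(x_BS)`, metastability flag and margin).
#' @export
free_energy_profile <- function(g_ts, x_ts, F_tr, x_BS = 0.23,
                                stiff_B = 1000, stiff_S = 3000,
                                kbt = boltzmann_energy(),
                                grid_res = 0.001) {
  prof <- build_profile_at_ftr(g_ts, x_ts, x_BS, stiff_B, stiff_S, kbt,
                               grid_res)
  prof <- tilt_to_zero_force(prof, F_tr, kbt)
  meta <- classify_metastability(prof)
  i_ts <- which.min(abs(prof$x - x_ts))
  i_bs <- which.min(abs(prof$x - x_BS))
  attr(prof, "summary") <- list(
    x_ts = x_ts, g_ts_at_Ftr = g_ts,
    g_ts_at_zero = prof$g_at_zero[i_ts],
    g_at_zero_xBS = prof$g_at_zero[i_bs],
    s_metastable_at_zero = meta$metastable,
    metastable_margin = meta$margin)
  prof
}

#' @export
print.fe_profile <- function(x, ...) {
  s <- attr(x, "summary")
  cat("<fe_profile>\n")
  cat(sprintf("  grid %d points on [0, %.3f] nm/bp | barrier %.3f kBT/bp at %.3f nm/bp\n",
              nrow(x), max(x$x), attr(x, "g_ts"), attr(x, "x_ts")))
  if (!is.null(s))
    cat(sprintf("  at F=0: barrier %.2f, g(x_BS) %.2f kBT/bp | S metastable: %s\n",
                s$g_ts_at_zero, s$g_at_zero_xBS, s$s_metastable_at_zero))
  invisible(x)
}
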