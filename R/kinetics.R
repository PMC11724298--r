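#' Transition-force probability densities
#'
#' Histogram densities of the forces at which B-to-S and S-to-B jumps
#' occur, each normalised to integrate to 1 over the observed window
#' (trapezoid rule).
#'
#' @param events an `event_log`.
#' @param bin_width force bin width, pN. Default 0.25.
#' @param min_events minimum events per direction. Default 30.
#' @return data.frame with `force` (bin centres), `dens_BtoS`,
#'   `dens_StoB`, and raw counts `n_BtoS`, `n_StoB`.
#' @export
force_densities <- function(events, bin_width = 0.25, min_events = 30) {
  for (d in c("BtoS", "StoB")) {
    if (sum(events$direction == d) < min_events)
      stop("need at least ", min_events, " events per direction (", d, ")")
  }
  rng <- range(events$force)
  breaks <- seq(floor(rng[1] / bin_width) * bin_width,
                ceiling(rng[2] / bin_width) * bin_width, by = bin_width)
  centres <- head(breaks, -1) + bin_width / 2
  trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  dens <- function(d) {
    h <- hist(events$force[events$direction == d], breaks = breaks,
              plot = FALSE)
    dd <- h$counts / sum(h$counts) / bin_width
    area <- trapz(centres, dd)
    if (area > 0) dd <- dd / area
    list(density = dd, counts = h$counts)
  }
  f <- dens("BtoS"); r <- dens("StoB")
  out <- data.frame(force = centres,
                    dens_BtoS = f$density, dens_StoB = r$density,
                    n_BtoS = f$counts, n_StoB = r$counts)
  attr(out, "bin_width") <- bin_width
  out
}

#' Survival curves of the B and S states versus force
#'
#' Product-limit (Kaplan-Meier) estimator in the force coordinate, with
#' left truncation at each dwell's entry force (most dwells start mid-ramp
#' after a previous jump) and right censoring at the ramp ends. Release
#' half-cycles run the force backwards; their dwells are pooled with the
#' stretch dwells on the reversed axis `2 F_tr - F`, using the symmetry of
#' the ramp about the transition force. Alongside the curves, the
#' risk-set bookkeeping per force bin (events, time at risk) is returned;
#' the rate reconstruction uses it.
#'
#' @param dwells a `dwell_table` from [extract_dwells()]/[detect_dataset()].
#' @param F_tr transition force used for the release-axis reversal;
#'   default: midpoint between mean B-exit and mean S-exit forces.
#' @param bin_width force bin width for the risk tables, pN. Default 0.25.
#' @param min_dwells minimum dwells per state. Default 20.
#' @param dead_time detector time resolution, s: the first
#'   `dead_time * loading_rate` of every dwell's force interval is
#'   excluded from the risk set and shorter dwells are dropped, which
#'   keeps the hazard unbiased under the only-resolvable-dwells-observed
#'   conditioning (dwells are memoryless at fixed force). Default 0.
#' @param loading_rate pN/s; required when `dead_time > 0` and used to
#'   set at-risk interval widths from dwell durations.
#' @return list with per state (`B`, `S`): `km` (data.frame force, surv,
#'   n_risk, n_event on the pooled axis) and `risk` (data.frame force,
#'   d = exits, at_risk_force = summed force-interval overlap, on the
#'   actual force axis); plus `F_tr` used.
#' @export
survival_curves <- function(dwells, F_tr = NULL, bin_width = 0.25,
                            min_dwells = 20, dead_time = 0,
                            loading_rate = NULL) {
  stopifnot(inherits(dwells, "dwell_table") || is.data.frame(dwells))
  # dwells whose force interval is inverted (possible for very short
  # dwells once measurement noise enters the entry/exit forces) carry no
  # usable risk interval; drop them unless they dominate, which would
  # signal corrupted input rather than noise
  inverted <- (dwells$ramp == "stretch" & dwells$state == "B" &
                 dwells$exit_force < dwells$entry_force &
                 dwells$exit_kind == "transition")
  if (mean(inverted) > 0.2) stop("dwell exits before entry on a stretch ramp")
  dwells <- dwells[!inverted, , drop = FALSE]
  if (is.null(F_tr)) {
    fb <- dwells$exit_force[dwells$state == "B" & dwells$exit_kind == "transition"]
    fs <- dwells$exit_force[dwells$state == "S" & dwells$exit_kind == "transition"]
    F_tr <- if (length(fb) && length(fs)) (mean(fb) + mean(fs)) / 2
            else mean(dwells$exit_force)
  }
  out <- list(F_tr = F_tr)
  for (st in c("B", "S")) {
    dw <- dwells[dwells$state == st, , drop = FALSE]
    if (nrow(dw) == 0) next    # single-state input: report the other only
    if (nrow(dw) < min_dwells)
      stop("need at least ", min_dwells, " dwells in state ", st)
    # pooled axis: the direction along which this dwell was driven
    # (stretch keeps F, release reverses about F_tr)
    rev_ax <- dw$ramp == "release"
    u_entry <- ifelse(rev_ax, 2 * F_tr - dw$entry_force, dw$entry_force)
    u_exit <- ifelse(rev_ax, 2 * F_tr - dw$exit_force, dw$exit_force)
    ok <- u_exit > u_entry
    ev <- as.integer(dw$exit_kind == "transition")[ok]
    sf <- survival::survfit(
      survival::Surv(u_entry[ok], u_exit[ok], ev) ~ 1)
    km <- data.frame(force = sf$time, surv = sf$surv,
                     n_risk = sf$n.risk, n_event = sf$n.event)
    # risk table on the actual force axis. When the dwells come from a
    # detector with dead time tau0, only dwells longer than tau0 are
    # observable; dwell durations are memoryless at fixed force, so
    # excluding the first tau0 of every observed dwell from the risk set
    # (and dropping dwells shorter than that) keeps the hazard estimate
    # unbiased under the detection conditioning
    rng <- range(c(dw$entry_force, dw$exit_force))
    breaks <- seq(floor(rng[1] / bin_width) * bin_width,
                  ceiling(rng[2] / bin_width) * bin_width, by = bin_width)
    centres <- head(breaks, -1) + bin_width / 2
    if (!is.null(dw$entry_time) && !is.null(loading_rate)) {
      # anchor the at-risk interval at the (well-measured) exit force and
      # set its width from the dwell duration; for short dwells the
      # difference of two noisy force reads would otherwise inflate the
      # risk interval by the noise amplitude
      w <- loading_rate * (dw$exit_time - dw$entry_time)
      up <- dw$ramp == "stretch"   # force rises towards the exit
      lo <- ifelse(up, dw$exit_force - w, dw$exit_force)
      hi <- ifelse(up, dw$exit_force, dw$exit_force + w)
    } else {
      lo <- pmin(dw$entry_force, dw$exit_force)
      hi <- pmax(dw$entry_force, dw$exit_force)
    }
    if (dead_time > 0) {
      if (is.null(loading_rate))
        stop("`loading_rate` is required when `dead_time` > 0")
      adj <- loading_rate * dead_time   # entry side: lo on stretch, hi on release
      lo <- lo + ifelse(dw$ramp == "stretch", adj, 0)
      hi <- hi - ifelse(dw$ramp == "release", adj, 0)
      resolvable <- hi > lo
      dw <- dw[resolvable, , drop = FALSE]
      lo <- lo[resolvable]; hi <- hi[resolvable]
    }
    at_risk <- vapply(seq_along(centres), function(i) {
      sum(pmax(0, pmin(hi, breaks[i + 1]) - pmax(lo, breaks[i])))
    }, numeric(1))
    d <- hist(dw$exit_force[dw$exit_kind == "transition"], breaks = breaks,
              plot = FALSE)$counts
    out[[st]] <- list(km = km,
                      risk = data.frame(force = centres, d = d,
                                        at_risk_force = at_risk))
  }
  attr(out, "bin_width") <- bin_width
  out
}

#' Force-resolved transition rates from the survival analysis
#'
#' Hazard-rate transform of the dwell statistics: with the force ramped at
#' loading rate r, the transition rate at force F is `k(F) = r rho(F)/S(F)`,
#' which with the risk-set bookkeeping of [survival_curves()] is evaluated
#' per force bin as `k = r * d / L`, `d` the exits in the bin and `L` the
#' summed force-interval overlap of all dwells at risk there (so left
#' truncation is handled exactly). B-to-S rates come from B dwells,
#' S-to-B rates from S dwells.
#'
#' @param surv result of [survival_curves()].
#' @param loading_rate pN/s (see [loading_rate()]).
#' @param min_events bins with fewer exits are dropped. Default 5.
#' @param s_floor bins where the risk set has shrunk below this fraction
#'   of its peak are dropped (tail cut). Default 0.05.
#' @param dead_time effective time resolution of the event detector, s.
#'   Bins whose apparent hazard implies dwells comparable to the dead time
#'   (`k * dead_time > 0.1`) are censorship-limited, not kinetics-limited,
#'   and are dropped. Default 0 (no cut; appropriate for ground-truth
#'   dwell logs).
#' @return data.frame with `force`, `direction` (`"BtoS"`/`"StoB"`), `k`
#'   (1/s), `se_log_k` (~ 1/sqrt(d)), `d`.
#' @export
rates_from_survival <- function(surv, loading_rate, min_events = 5,
                                s_floor = 0.05, dead_time = 0) {
  if (loading_rate <= 0) stop("`loading_rate` must be positive")
  pieces <- list()
  for (st in c("B", "S")) {
    if (is.null(surv[[st]])) next
    risk <- surv[[st]]$risk
    # tail cut: with recurrent hopping most dwells enter mid-ramp, so the
    # meaningful analogue of a low-survival tail is a risk set that has
    # shrunk to a sliver of its peak; rates there would rest on a handful
    # of dwell fragments
    keep <- risk$d >= min_events &
      risk$at_risk_force >= s_floor * max(risk$at_risk_force)
    if (!any(keep)) next
    k <- loading_rate * risk$d[keep] / risk$at_risk_force[keep]
    if (dead_time > 0) {
      # merging guard: where the apparent hazard approaches the inverse
      # dead time, a sizeable fraction of exits is followed by an
      # unresolvably short partner dwell, so the exit is lost and the
      # apparent dwell spuriously continues; such bins underestimate
      # the rate in a force-dependent way
      resolvable <- k * dead_time <= 0.2
      k <- k[resolvable]
      keep[keep] <- resolvable
      if (!any(keep)) next
    }
    pieces[[st]] <- data.frame(
      force = risk$force[keep],
      direction = if (st == "B") "BtoS" else "StoB",
      k = k, se_log_k = 1 / sqrt(risk$d[keep]), d = risk$d[keep],
      stringsAsFactors = FALSE)
  }
  if (length(pieces) == 0)
    stop("survival below the floor everywhere: no rate bins usable")
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Bell-Evans fit of the force-resolved rates
#'
#' Weighted least squares of `ln k` on force in a window around the
#' transition force, separately per direction. The forward slope times kbt
#' is the B-to-TS distance, minus the reverse slope times kbt the TS-to-S
#' distance; the crossing of the two fitted lines locates the transition
#' force and the rate there; the intercepts at F = 0 give the zero-force
#' extrapolations (reported as extrapolation only: the window is 60 pN
#' away from zero force).
#'
#' @param rates data.frame from [rates_from_survival()].
#' @param F_tr transition force used to centre the window, pN.
#' @param window half-width of the fit window, pN. Default 2.
#' @param kbt thermal energy, pN nm.
#' @param min_bins minimum rate bins per direction inside the window.
#'   Default 4.
#' @param dead_time detector time resolution, s; with `jump_shift` it
#'   triggers a second fitting pass that excludes bins where the state an
#'   event lands in would not outlive the dead time (such events are
#'   systematically lost and bias the slopes). Default 0 (single pass).
#' @param jump_shift mean force step of a transition, pN (used to locate
#'   the landing force). Default 0.
#' @return list with `X_b_ts_hat`, `X_b_ts_se`, `X_s_ts_hat`, `X_s_ts_se`,
#'   `X_BS_hat`, `ts_fraction` (% of the path from B), `F_cross`,
#'   `k_at_ftr`, `log10_k0_forward`, `log10_k0_reverse`, and
#'   `non_two_state` flag (TRUE when a slope has the wrong sign).
#' @export
fit_bell_evans <- function(rates, F_tr, window = 2,
                           kbt = boltzmann_energy(), min_bins = 4,
                           dead_time = 0, jump_shift = 0) {
  fit_dir <- function(dirn, f_lo = -Inf, f_hi = Inf) {
    d <- rates[rates$direction == dirn &
                 abs(rates$force - F_tr) <= window & rates$k > 0 &
                 rates$force >= f_lo & rates$force <= f_hi, ]
    if (nrow(d) < min_bins)
      stop("need at least ", min_bins, " rate bins for ", dirn,
           " inside the window")
    w_counts <- d[["d"]]
    fit <- lm(log(k) ~ force, data = d, weights = w_counts)
    list(slope = coef(fit)[["force"]],
         slope_se = summary(fit)$coefficients["force", "Std. Error"],
         intercept = coef(fit)[["(Intercept)"]])
  }
  fw <- fit_dir("BtoS")
  rv <- fit_dir("StoB")
  if (dead_time > 0 && jump_shift > 0 && fw$slope > 0 && rv$slope < 0) {
    # detection-censoring correction: an event is only recorded if the
    # dwell it lands in outlives the detector dead time, so the apparent
    # rate is the true rate times exp(-dead_time * k_partner(F_landing)).
    # Invert that attenuation iteratively, modelling the partner rate
    # with the current Bell-Evans fit of the opposite direction. The
    # correction is only trusted while it is small (< e^0.5); bins beyond
    # that lose most of their events to censoring and are dropped
    d0 <- rates[abs(rates$force - F_tr) <= window & rates$k > 0, ]
    for (it in 1:4) {
      k_partner <- ifelse(
        d0$direction == "BtoS",
        exp(rv$intercept + rv$slope * (d0$force - jump_shift)),
        exp(fw$intercept + fw$slope * (d0$force + jump_shift)))
      corr <- dead_time * k_partner
      d1 <- d0[corr <= 0.5, ]
      d1$k <- d1$k * exp(corr[corr <= 0.5])
      refit <- function(dirn, fallback) {
        x <- d1[d1$direction == dirn, ]
        if (nrow(x) < min_bins) return(fallback)
        w1 <- x[["d"]]
        ft <- lm(log(k) ~ force, data = x, weights = w1)
        list(slope = coef(ft)[["force"]],
             slope_se = summary(ft)$coefficients["force", "Std. Error"],
             intercept = coef(ft)[["(Intercept)"]])
      }
      fw <- refit("BtoS", fw)
      rv <- refit("StoB", rv)
      if (fw$slope <= 0 || rv$slope >= 0) break
    }
  }
  non_two_state <- fw$slope <= 0 || rv$slope >= 0
  if (non_two_state)
    warning("non-two-state: rate slopes have unexpected signs")
  X_b <- fw$slope * kbt
  X_s <- -rv$slope * kbt
  F_cross <- (rv$intercept - fw$intercept) / (fw$slope - rv$slope)
  k_at_ftr <- exp(fw$intercept + fw$slope * F_cross)
  list(
    X_b_ts_hat = X_b, X_b_ts_se = fw$slope_se * kbt,
    X_s_ts_hat = X_s, X_s_ts_se = rv$slope_se * kbt,
    X_BS_hat = X_b + X_s,
    ts_fraction = 100 * X_b / (X_b + X_s),
    F_cross = F_cross, k_at_ftr = k_at_ftr,
    log10_k0_forward = fw$intercept / log(10),
    log10_k0_reverse = rv$intercept / log(10),
    non_two_state = non_two_state)
}

#' Transitions per cycle
#'
#' Mean total number of transitions (both directions) per stretch/release
#' cycle, with SEM over cycles, plus per-cycle-averaged histograms of
#' event counts versus force and versus extension with their peak
#' locations.
#'
#' @param events an `event_log`.
#' @param n_cycles total number of cycles simulated/measured (cycles with
#'   zero events are invisible in the event log); default: number of
#'   distinct cycle ids present.
#' @param force_bin,ext_bin histogram bin widths (pN, nm).
#' @return list with `N`, `sem`, `per_cycle`, `vs_force`, `vs_extension`,
#'   `peak_force`, `peak_extension`.
#' @export
transition_counts <- function(events, n_cycles = NULL, force_bin = 0.5,
                              ext_bin = 0.5) {
  if (nrow(events) == 0) {
    return(list(N = 0, sem = NA_real_, per_cycle = integer(),
                vs_force = NULL, vs_extension = NULL,
                peak_force = NA_real_, peak_extension = NA_real_))
  }
  ids <- unique(events$cycle)
  if (is.null(n_cycles)) n_cycles <- length(ids)
  counts <- tapply(rep(1, nrow(events)), events$cycle, sum)
  per_cycle <- c(as.numeric(counts), rep(0, max(0, n_cycles - length(counts))))
  N <- mean(per_cycle)
  sem <- if (length(per_cycle) >= 2) sd(per_cycle) / sqrt(length(per_cycle)) else NA_real_
  hist_avg <- function(x, bw) {
    breaks <- seq(floor(min(x) / bw) * bw, ceiling(max(x) / bw) * bw, by = bw)
    if (length(breaks) < 2) breaks <- c(breaks, breaks + bw)
    h <- hist(x, breaks = breaks, plot = FALSE)
    data.frame(centre = h$mids, per_cycle = h$counts / n_cycles)
  }
  vf <- hist_avg(events$force, force_bin)
  vx <- hist_avg(events$delta_x, ext_bin)
  list(N = N, sem = sem, per_cycle = per_cycle,
       vs_force = vf, vs_extension = vx,
       peak_force = vf$centre[which.max(vf$per_cycle)],
       peak_extension = vx$centre[which.max(vx$per_cycle)])
}

#' Per-base-pair transition barrier from count scaling
#'
#' The number of transitions per cycle is proportional to the hopping rate
#' at the transition force, which scales with the number of transitioning
#' base pairs as `k ~ exp(-n g_TS)` if the barrier free energy is
#' extensive in n. Regressing `ln N` on `n` across constructs measured
#' under the same protocol therefore gives the per-bp barrier as the
#' negated slope; with two constructs this reduces to
#' `ln(N_b/N_a)/(n_a - n_b)`.
#'
#' @param n numbers of transitioning base pairs, one per construct.
#' @param N mean transitions per cycle, same order.
#' @return list with `g_ts` (kBT/bp), `se`, `fit` (the lm object; NULL for
#'   the two-point case).
#' @export
barrier_per_bp <- function(n, N) {
  if (length(n) != length(N) || length(n) < 2)
    stop("need matched `n` and `N` for at least 2 constructs")
  if (any(N <= 0)) stop("`N` must be positive")
  if (diff(range(n)) == 0) stop("all `n` equal: slope undefined")
  if (length(n) == 2) {
    return(list(g_ts = log(N[2] / N[1]) / (n[1] - n[2]), se = NA_real_,
                fit = NULL))
  }
  fit <- lm(log(N) ~ n)
  list(g_ts = -coef(fit)[["n"]],
       se = summary(fit)$coefficients["n", "Std. Error"], fit = fit)
}

#' Attempt rate of the B-to-S transition
#'
#' Universal prefactor once the extensive barrier is factored out:
#' `k0_BS = k(F_tr) * exp(n * g_ts)`. Returned in log space as well, to
#' guard against overflow for large barriers.
#'
#' @param k_at_ftr hopping rate at the transition force, 1/s.
#' @param n number of transitioning base pairs.
#' @param g_ts per-bp barrier at the transition force, kBT/bp.
#' @return list with `k0_BS` (1/s) and `log10_k0_BS`.
#' @export
attempt_rate <- function(k_at_ftr, n, g_ts) {
  if (k_at_ftr <= 0 || n <= 0 || g_ts < 0)
    stop("`k_at_ftr` and `n` must be positive, `g_ts` nonnegative")
  lg <- log(k_at_ftr) + n * g_ts
  list(k0_BS = if (lg < 700) exp(lg) else Inf, log10_k0_BS = lg / log(10))
}

#' Full kinetic analysis of one detected dataset
#'
#' Chains [force_densities()], [survival_curves()],
#' [rates_from_survival()], [fit_bell_evans()] and [transition_counts()].
#'
#' @param detection result of [detect_dataset()].
#' @param protocol the [ramp_protocol()] the data were recorded under.
#' @param F_tr transition force for window centring; default from the
#'   survival pooling midpoint.
#' @param n_hat optional number of transitioning bp, to report per-bp
#'   transition-state distances.
#' @param n_cycles total cycle count (for zero-event cycles).
#' @param window Bell-Evans fit half-window, pN. Default 2.
#' @param bin_width force bin width, pN. Default 0.25.
#' @return object of class `kinetics_result`.
#' @export
kinetics_analysis <- function(detection, protocol, F_tr = NULL, n_hat = NULL,
                              n_cycles = NULL, window = 2, bin_width = 0.25,
                              dead_time = 3 / protocol$sample_rate) {
  ev <- detection$events
  dens <- force_densities(ev, bin_width = bin_width)
  surv <- survival_curves(detection$dwells, F_tr = F_tr,
                          bin_width = bin_width, dead_time = dead_time,
                          loading_rate = loading_rate(protocol))
  rates <- rates_from_survival(surv, loading_rate(protocol),
                               dead_time = dead_time)
  jump_shift <- if (!is.null(ev$force_after))
    mean(abs(ev$force - ev$force_after)) else 0
  be <- fit_bell_evans(rates, F_tr %||% surv$F_tr, window = window,
                       dead_time = dead_time, jump_shift = jump_shift)
  cnt <- transition_counts(ev, n_cycles = n_cycles)
  res <- c(be, list(
    N = cnt$N, N_sem = cnt$sem,
    x_b_ts = if (!is.null(n_hat)) be$X_b_ts_hat / n_hat else NA_real_,
    x_s_ts = if (!is.null(n_hat)) be$X_s_ts_hat / n_hat else NA_real_,
    densities = dens, survival = surv, rates = rates, counts = cnt))
  class(res) <- "kinetics_result"
  res
}

#' @export
print.kinetics_result <- function(x, ...) {
  cat("<kinetics_result>\n")
  cat(sprintf("  X_B->TS %.2f +- %.2f nm | X_S->TS %.2f +- %.2f nm | sum %.2f nm\n",
              x$X_b_ts_hat, x$X_b_ts_se, x$X_s_ts_hat, x$X_s_ts_se, x$X_BS_hat))
  cat(sprintf("  TS at %.1f%% from B | k(F_tr) %.3g 1/s at F %.2f pN\n",
              x$ts_fraction, x$k_at_ftr, x$F_cross))
  cat(sprintf("  N %.1f +- %.1f transitions/cycle\n", x$N, x$N_sem %||% NA))
  invisible(x)
}
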