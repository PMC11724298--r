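#' Transition force from the two-state occupancy
#'
#' Bins the per-sample state labels by force (default 0.25 pN bins),
#' computes the fraction of time spent in S per bin, and fits the two-state
#' occupancy [two_state_ps()] with free midpoint and extension. The fitted
#' midpoint is the transition force. The SEM comes from a per-cycle
#' bootstrap (cycles are the independent units; samples within a cycle are
#' correlated).
#'
#' @param states data.frame with columns `force`, `state` (`"B"`/`"S"`) and
#'   `cycle`, e.g. `detect_dataset()$states`.
#' @param kbt thermal energy, pN nm.
#' @param bin_width force bin width, pN. Default 0.25.
#' @param n_boot bootstrap resamples for the SEM. Default 200.
#' @param boot_seed fixed seed for the bootstrap stream. Default 1.
#' @param min_bin_count bins with fewer samples are ignored in the fit.
#' @return list with `F_tr_hat`, `sem`, `dX_occ` (the occupancy-slope
#'   extension), and the binned occupancy table.
#' @export
estimate_ftr <- function(states, kbt = boltzmann_energy(), bin_width = 0.25,
                         n_boot = 200, boot_seed = 1, min_bin_count = 20) {
  stopifnot(is.data.frame(states), all(c("force", "state", "cycle") %in% names(states)))
  occ <- .bin_occupancy(states$force, states$state, bin_width)
  attr(occ, "bin_width") <- bin_width
  fit <- .fit_occupancy(occ, kbt, min_bin_count)
  if (is.null(fit)) stop("no midpoint: occupancy never crosses 0.5 inside the window")

  # per-cycle bin counts for the bootstrap
  cyc <- factor(states$cycle)
  bin <- factor(.force_bin(states$force, bin_width), levels = levels(occ$bin))
  tot <- table(cyc, bin)
  in_s <- table(cyc[states$state == "S"], bin[states$state == "S"])
  in_s_full <- matrix(0, nrow(tot), ncol(tot), dimnames = dimnames(tot))
  in_s_full[rownames(in_s), colnames(in_s)] <- in_s
  sem <- NA_real_
  if (nlevels(cyc) >= 2 && n_boot > 0) {
    boots <- .with_seed(boot_seed, {
      vapply(seq_len(n_boot), function(b) {
        pick <- sample(nlevels(cyc), nlevels(cyc), replace = TRUE)
        n_b <- colSums(tot[pick, , drop = FALSE])
        s_b <- colSums(in_s_full[pick, , drop = FALSE])
        occ_b <- data.frame(bin = factor(levels(occ$bin), levels(occ$bin)),
                            force = occ$force, n = as.numeric(n_b),
                            p_S = ifelse(n_b > 0, s_b / n_b, NA))
        fb <- tryCatch(.fit_occupancy(occ_b, kbt, min_bin_count),
                       error = function(e) NULL)
        if (is.null(fb)) NA_real_ else fb$F_tr
      }, numeric(1))
    })
    sem <- sd(boots, na.rm = TRUE)
  }
  list(F_tr_hat = fit$F_tr, sem = sem, dX_occ = fit$dX, occupancy = occ)
}

.force_bin <- function(force, bin_width) {
  floor(force / bin_width) * bin_width + bin_width / 2
}

.bin_occupancy <- function(force, state, bin_width) {
  centre <- .force_bin(force, bin_width)
  lev <- sort(unique(centre))
  bin <- factor(centre, levels = lev)
  n <- as.numeric(table(bin))
  s <- as.numeric(table(factor(centre[state == "S"], levels = lev)))
  data.frame(bin = factor(lev, lev), force = lev, n = n,
             p_S = ifelse(n > 0, s / n, NA))
}

.fit_occupancy <- function(occ, kbt, min_bin_count) {
  use <- occ$n >= min_bin_count & is.finite(occ$p_S)
  d <- occ[use, ]
  if (nrow(d) < 4) return(NULL)
  if (max(d$p_S) < 0.5 || min(d$p_S) > 0.5) return(NULL)
  mid0 <- d$force[which.min(abs(d$p_S - 0.5))]
  fit <- tryCatch(
    nls(p_S ~ stats::plogis(dX * (force - Ftr) / kbt),
        data = d, start = list(Ftr = mid0, dX = 10),
        weights = d$n, control = stats::nls.control(warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- coef(fit)
  if (cf[["dX"]] <= 0) return(NULL)
  list(F_tr = cf[["Ftr"]], dX = cf[["dX"]])
}

.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Mean transition extension
#'
#' Arithmetic mean of the per-event extension change over both transition
#' directions, with SEM over cycles.
#'
#' @param events an `event_log` (detected or ground truth).
#' @param min_events minimum number of events. Default 10.
#' @return list with `dX_hat`, `sem`, `n_events`.
#' @export
mean_transition_extension <- function(events, min_events = 10) {
  if (nrow(events) == 0) stop("empty event log")
  if (nrow(events) < min_events)
    stop("need at least ", min_events, " events")
  per_cycle <- tapply(events$delta_x, events$cycle, mean)
  sem <- if (length(per_cycle) >= 2) sd(per_cycle) / sqrt(length(per_cycle)) else NA_real_
  list(dX_hat = mean(events$delta_x), sem = sem, n_events = nrow(events))
}

#' Equilibrium transition free energy from jump work
#'
#' The reversible work of one B-to-S jump at force F with extension change
#' dX is `F * dX / kbt` (the trap and handles are stiff enough not to
#' contribute within uncertainty). The transition free energy is the mean
#' of this per-event work; because the hops occur close to equilibrium,
#' averaging over both directions estimates `G_BS ~ F_tr * dX / kbt`. The
#' pre-jump force is used (this convention reproduces the `F_tr * dX`
#' product); set `midpoint_force = TRUE` for the mid-jump alternative.
#'
#' @param events an `event_log`.
#' @param kbt thermal energy, pN nm.
#' @param direction `"both"` (default) or `"BtoS"`.
#' @param midpoint_force correct each event force down/up by half the jump
#'   amplitude. Default FALSE.
#' @param K_eff effective stiffness used for the midpoint correction.
#' @param min_events minimum number of events. Default 10.
#' @return list with `G_BS` (kBT), `sem` (over cycles), `works` (per-event
#'   works in kBT, signed convention: work to go B to S).
#' @export
transition_free_energy <- function(events, kbt = boltzmann_energy(),
                                   direction = c("both", "BtoS"),
                                   midpoint_force = FALSE, K_eff = 0.1,
                                   min_events = 10) {
  direction <- match.arg(direction)
  if (nrow(events) == 0) stop("empty event log")
  ev <- if (direction == "both") events else events[events$direction == "BtoS", ]
  if (nrow(ev) < min_events) stop("need at least ", min_events, " events")
  f <- ev$force
  if (midpoint_force)
    f <- f + ifelse(ev$direction == "BtoS", -1, 1) * K_eff * ev$delta_x / 2
  w <- f * ev$delta_x / kbt
  per_cycle <- tapply(w, ev$cycle, mean)
  sem <- if (length(per_cycle) >= 2) sd(per_cycle) / sqrt(length(per_cycle)) else NA_real_
  list(G_BS = mean(w), sem = sem, works = w, n_events = nrow(ev))
}

#' Bennett acceptance-ratio free energy
#'
#' Maximum-likelihood two-sided estimator combining forward (B-to-S) and
#' reverse (S-to-B) work samples, in kBT: solves
#' \deqn{\sum_F \frac{1}{1 + e^{w_F - \Delta G + C}} =
#'       \sum_R \frac{1}{1 + e^{-w_R + \Delta G - C}}, \quad
#'       C = \ln(n_F / n_R)}
#' by root bracketing to `tol`. With identical delta-function work
#' distributions it reduces to the mean work.
#'
#' @param forward_works forward works, kBT.
#' @param reverse_works reverse works, kBT (same sign convention: work of
#'   the B-to-S direction, i.e. the work *recovered* in an S-to-B jump).
#' @param tol self-consistency tolerance, kBT. Default 1e-6.
#' @return the free energy difference, kBT.
#' @export
bar_free_energy <- function(forward_works, reverse_works, tol = 1e-6) {
  wf <- as.numeric(forward_works)
  wr <- as.numeric(reverse_works)
  if (length(wf) == 0 || length(wr) == 0)
    stop("both forward and reverse work lists must be non-empty")
  C <- log(length(wf) / length(wr))
  h <- function(dG)
    sum(stats::plogis(-(wf - dG + C))) - sum(stats::plogis(-(-wr + dG - C)))
  centre <- mean(c(wf, wr))
  span <- max(1, diff(range(c(wf, wr))))
  lo <- centre - span; hi <- centre + span
  for (i in 1:60) {
    if (h(lo) * h(hi) <= 0) break
    lo <- lo - span; hi <- hi + span
    span <- span * 2
  }
  if (h(lo) * h(hi) > 0)
    stop("no sign change in bracketing interval after expansion")
  uniroot(h, c(lo, hi), tol = tol)$root
}

#' Per-base-pair transition quantities
#'
#' Number of base pairs undergoing the B-to-S transition,
#' `n = dX / x_BS` with `x_BS = 0.23` nm/bp known from polymeric DNA
#' overstretching, and the per-bp free energy `g = G_BS / n`. `n` is
#' real-valued, not rounded.
#'
#' @param dX_hat transition extension, nm.
#' @param G_BS transition free energy, kBT.
#' @param x_BS per-bp elongation, nm/bp. Default 0.23.
#' @return list with `n_hat` (bp) and `g_hat` (kBT/bp).
#' @export
per_bp_quantities <- function(dX_hat, G_BS, x_BS = 0.23) {
  if (x_BS <= 0) stop("`x_BS` must be positive")
  if (dX_hat <= 0) stop("`dX_hat` must be positive: g undefined at n = 0")
  n <- dX_hat / x_BS
  list(n_hat = n, g_hat = G_BS / n)
}

#' Net duplex stabilisation by modifications
#'
#' Compares the transition free energy of a modified duplex against an
#' unmodified duplex over the *same* transitioning length:
#' `dG = G_BS_mod - n_mod * g_ref`, with `g_ref` the per-bp free energy of
#' the reference construct at the same salt and pulling rate. Applied to
#' the reference itself this gives 0.
#'
#' @param G_BS_mod transition free energy of the modified construct, kBT.
#' @param n_mod its number of transitioning base pairs.
#' @param g_ref per-bp free energy of the reference construct, kBT/bp.
#' @return stabilisation free energy, kBT (positive = modification
#'   stabilises B relative to S).
#' @export
stabilization_dG <- function(G_BS_mod, n_mod, g_ref) {
  if (n_mod <= 0 || g_ref <= 0) stop("`n_mod` and `g_ref` must be positive")
  G_BS_mod - n_mod * g_ref
}

#' Fraying slope from the extension-force regression
#'
#' Ordinary least squares of the per-event extension change on the event
#' force. Higher transition forces fray more base pairs, so the extension
#' shrinks with force; the slope is negative in the (extension vs force)
#' convention and is reported as a positive shortening rate, nm/pN.
#'
#' @param events an `event_log`.
#' @param min_events minimum events. Default 30.
#' @param min_span minimum force span, pN. Default 2.
#' @return list with `fray_slope_hat` (positive shortening, nm/pN), `se`,
#'   `slope_raw` (signed OLS slope).
#' @export
extension_force_regression <- function(events, min_events = 30, min_span = 2) {
  if (nrow(events) < min_events)
    stop("need at least ", min_events, " events")
  if (diff(range(events$force)) < min_span)
    stop("insufficient force spread (< ", min_span, " pN)")
  fit <- lm(delta_x ~ force, data = events)
  slope <- coef(fit)[["force"]]
  se <- summary(fit)$coefficients["force", "Std. Error"]
  list(fray_slope_hat = -slope, se = se, slope_raw = slope)
}

#' Full equilibrium analysis of one detected dataset
#'
#' Combines [estimate_ftr()], [mean_transition_extension()],
#' [transition_free_energy()] (mean-work and Bennett acceptance-ratio),
#' [per_bp_quantities()], the fraying regression and, when a reference
#' per-bp free energy is supplied, [stabilization_dG()].
#'
#' @param detection result of [detect_dataset()].
#' @param kbt thermal energy, pN nm.
#' @param x_BS per-bp elongation, nm/bp.
#' @param g_ref optional reference per-bp free energy for `dG`.
#' @param n_boot bootstrap resamples for the transition-force SEM.
#' @return object of class `equilibrium_result`.
#' @export
equilibrium_analysis <- function(detection, kbt = boltzmann_energy(),
                                 x_BS = 0.23, g_ref = NULL, n_boot = 200) {
  ev <- detection$events
  ftr <- estimate_ftr(detection$states, kbt = kbt, n_boot = n_boot)
  dx <- mean_transition_extension(ev)
  G <- transition_free_energy(ev, kbt = kbt)
  wf <- ev$force[ev$direction == "BtoS"] * ev$delta_x[ev$direction == "BtoS"] / kbt
  wr <- ev$force[ev$direction == "StoB"] * ev$delta_x[ev$direction == "StoB"] / kbt
  G_bar <- if (length(wf) && length(wr)) bar_free_energy(wf, wr) else NA_real_
  pb <- per_bp_quantities(dx$dX_hat, G$G_BS, x_BS)
  fray <- tryCatch(extension_force_regression(ev), error = function(e) NULL)
  m <- length(unique(ev$cycle))
  res <- list(
    F_tr_hat = ftr$F_tr_hat, F_tr_sem = ftr$sem,
    dX_hat = dx$dX_hat, dX_sem = dx$sem,
    G_BS = G$G_BS, G_BS_sem = G$sem, G_BS_bar = G_bar,
    n_hat = pb$n_hat, g_hat = pb$g_hat,
    dG = if (!is.null(g_ref)) stabilization_dG(G$G_BS, pb$n_hat, g_ref) else NA_real_,
    fray_slope_hat = if (!is.null(fray)) fray$fray_slope_hat else NA_real_,
    fray_slope_se = if (!is.null(fray)) fray$se else NA_real_,
    m = m, n_events = nrow(ev))
  class(res) <- "equilibrium_result"
  res
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat("<equilibrium_result>\n")
  cat(sprintf("  F_tr %.2f +- %.2f pN | dX %.2f +- %.2f nm (m = %d cycles)\n",
              x$F_tr_hat, x$F_tr_sem, x$dX_hat, x$dX_sem, x$m))
  cat(sprintf("  G_BS %.1f +- %.1f kBT (BAR %.1f) | n %.1f bp | g %.3f kBT/bp\n",
              x$G_BS, x$G_BS_sem, x$G_BS_bar, x$n_hat, x$g_hat))
  cat(sprintf("  fraying %.2f +- %.2f nm/pN | dG %s kBT\n",
              x$fray_slope_hat, x$fray_slope_se,
              ifelse(is.na(x$dG), "-", sprintf("%.2f", x$dG))))
  invisible(x)
}
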