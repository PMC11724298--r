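#' Fit the B- and S-state elastic branches
#'
#' The two states trace two straight lines in the (trap position, force)
#' plane: the S line lies at larger distance by the transition extension
#' and is slightly steeper because end fraying shrinks that extension as
#' force rises. Samples are classified to the nearer line and each line
#' refit, alternating until stable (at most `max_iter` passes); ties keep
#' the previous assignment. Samples where the converging lines come
#' within ~4x the noise (towards the ramp top) are classified but kept
#' out of the fits.
#'
#' @param half_cycle one half-cycle from [segment_cycles()], or a whole
#'   multi-cycle `fdc_trace` (branch elasticity is a property of the
#'   construct, so pooling is legitimate for drift-free data).
#' @param min_samples minimum samples per branch for a two-branch fit;
#'   below this a B-only fit is returned with `single_state = TRUE`.
#' @param max_iter classification/refit iterations. Default 5.
#' @return object of class `branch_fit`: per state slope (pN/nm),
#'   intercept (pN), residual RMS, sample count; plus the force window used
#'   and a `single_state` flag.
#' @export
fit_branches <- function(half_cycle, min_samples = 50, max_iter = 5) {
  stopifnot(inherits(half_cycle, "fdc_trace"))
  lam <- half_cycle$trap_position
  f <- half_cycle$force
  if (length(unique(lam)) < 3) stop("no ramp: trap position is constant")

  fit0 <- lm(f ~ lam)
  res <- f - fitted(fit0)
  # initial split: detrend by the known ramp slope (the trap stiffness, or
  # a robust long-lag slope when no protocol is attached) so the two
  # branches collapse to two level clusters, then cut at the
  # sum-of-squares-optimal point. Residuals of a single least-squares line
  # would not do: the line runs diagonally across the two branches and its
  # residuals mix branch offset with ramp position
  proto <- attr(half_cycle, "protocol")
  s0 <- if (!is.null(proto)) proto$K_trap else .robust_slope(lam, f)
  # classification runs on the median-filtered force: at realistic noise
  # the raw margin between the branches is only ~2-3 sigma and a hard
  # classify/refit loop would contract the fitted separation, while the
  # filtered channel keeps a >4 sigma margin. The fits themselves use the
  # raw samples
  fmed <- stats::runmed(f, 5, endrule = "median")
  rdet <- fmed - s0 * lam
  assign <- ifelse(rdet >= .best_cut(rdet), "B", "S")  # higher force = B
  one_line <- function() {
    structure(list(
      B = list(slope = coef(fit0)[[2]], intercept = coef(fit0)[[1]],
               rms = sqrt(mean(res^2)), n = length(f)),
      S = NULL, single_state = TRUE,
      force_window = range(f)), class = "branch_fit")
  }
  if (min(table(factor(assign, c("B", "S")))) < min_samples) return(one_line())

  # per-state straight-line fits; the S line is slightly steeper than the
  # B line because the frayed transition extension shrinks as force rises,
  # and that slope difference is exactly the observable fray signal
  fit_two <- function(assign, use) {
    one <- function(keep) {
      # one trimmed refit: misassigned samples from the other branch sit
      # a full separation off and would tilt the line
      ft <- lm(f[keep] ~ lam[keep])
      r <- residuals(ft)
      good <- abs(r) <= 2.5 * mad(r)
      if (!all(good) && sum(good) > 10) {
        x1 <- lam[keep][good]; y1 <- f[keep][good]
        ft <- lm(y1 ~ x1)
        r <- residuals(ft)
      }
      list(slope = coef(ft)[[2]], intercept = coef(ft)[[1]],
           rms = sqrt(mean(r^2)), n = sum(keep))
    }
    list(B = one(assign == "B" & use), S = one(assign == "S" & use))
  }
  sigma_hat <- mad(diff(f)) / sqrt(2)
  use <- rep(TRUE, length(f))
  for (it in seq_len(max_iter)) {
    br <- fit_two(assign, use)
    predB <- br$B$intercept + br$B$slope * lam
    predS <- br$S$intercept + br$S$slope * lam
    dB <- abs(fmed - predB)
    dS <- abs(fmed - predS)
    new_assign <- ifelse(dB < dS, "B", ifelse(dS < dB, "S", assign))
    # with end fraying the branches converge towards the ramp top and
    # eventually merge; samples where the lines are closer than ~3x the
    # noise cannot be assigned reliably and are kept out of the fits
    new_use <- (predB - predS) >= 3 * sigma_hat
    # an intermediate fit can place the lines too close over most of the
    # ramp; restricting to a sliver would starve the next fit, so keep
    # the previous region until the lines separate
    if (sum(new_use) < 0.2 * length(f)) new_use <- use
    if (min(table(factor(new_assign[new_use], c("B", "S")))) < min_samples)
      return(one_line())
    if (all(new_assign == assign) && all(new_use == use)) {
      assign <- new_assign; use <- new_use; break
    }
    assign <- new_assign; use <- new_use
  }
  br <- fit_two(assign, use)
  # two lines separated (at the data centre) by less than ~2.5x the
  # measurement noise are one branch split along its noise, not two
  # states (noise estimated robustly from first differences, which cancel
  # the ramp and the branch structure)
  lam_c <- mean(lam)
  sep_c <- abs((br$B$intercept + br$B$slope * lam_c) -
                 (br$S$intercept + br$S$slope * lam_c))
  if (sep_c < 2.5 * sigma_hat) return(one_line())
  structure(list(B = br$B, S = br$S, single_state = FALSE,
                 force_window = range(f)),
            class = "branch_fit")
}

# robust ramp slope: median of long-lag secants (jump contamination is a
# small minority at lag >> dwell spacing)
.robust_slope <- function(lam, f, lag = 200L) {
  n <- length(f)
  lag <- min(lag, n - 1L)
  i <- seq_len(n - lag)
  median((f[i + lag] - f[i]) / (lam[i + lag] - lam[i]))
}

# deterministic two-cluster split of a numeric vector: the cut point that
# minimises the total within-cluster sum of squares
.best_cut <- function(x, max_n = 20000L) {
  if (length(x) > max_n) {
    idx <- floor(seq(1L, length(x), length.out = max_n))
    x <- x[idx]
  }
  xs <- sort(x)
  n <- length(xs)
  cs <- cumsum(xs)
  tot <- cs[n]
  k <- seq_len(n - 1L)
  ssb <- cs[k]^2 / k + (tot - cs[k])^2 / (n - k)  # maximise between-SS
  kbest <- which.max(ssb)
  (xs[kbest] + xs[kbest + 1L]) / 2
}

#' @export
print.branch_fit <- function(x, ...) {
  cat("<branch_fit>\n")
  cat(sprintf("  B: slope %.4f pN/nm, intercept %.2f, rms %.3f (n=%d)\n",
              x$B$slope, x$B$intercept, x$B$rms, x$B$n))
  if (!x$single_state)
    cat(sprintf("  S: slope %.4f pN/nm, intercept %.2f, rms %.3f (n=%d)\n",
                x$S$slope, x$S$intercept, x$S$rms, x$S$n))
  else cat("  (single-state half-cycle: B-only fit)\n")
  invisible(x)
}

#' Horizontal distance between fitted branches at a force
#'
#' @param branches a [fit_branches()] result.
#' @param F force, pN (vectorised).
#' @return trap-distance separation of the S and B lines, nm.
#' @export
branch_separation <- function(branches, F) {
  if (branches$single_state) stop("single-state fit has no S branch")
  (F - branches$S$intercept) / branches$S$slope -
    (F - branches$B$intercept) / branches$B$slope
}

#' Detect B-S transition events on a half-cycle
#'
#' A transition shows as an abrupt force drop (B-to-S) or rise (S-to-B).
#' The detector takes the discrete difference of the median-filtered force
#' (window `median_window`), thresholds it at `min_jump` and merges
#' threshold crossings closer than `debounce` samples into one candidate.
#' Each candidate is then re-measured from branch-classified raw samples
#' of the adjoining dwells (robust against unresolved flicker and ramp
#' drift) and kept only if the settled step is comparable to the local
#' branch separation. The event force is the last pre-jump sample's
#' force; the extension change is the horizontal distance between the
#' fitted branches at that force (the force step over the effective
#' stiffness when only one branch could be fitted), and the landing force
#' is reported alongside.
#'
#' @param half_cycle one half-cycle trace.
#' @param branches a [fit_branches()] result for it (default: fitted here).
#' @param min_jump force-step threshold, pN. Default 0.5, about half the
#'   expected jump `K_eff * dX`. Must exceed twice the noise sigma.
#' @param debounce minimum separation of events, samples. Default 3.
#' @param median_window median-filter width, samples (odd). Default 5.
#' @param level_window samples on each side of a candidate used for the
#'   settled level reads. Default 20.
#' @param confirm_frac fraction of the local branch separation the
#'   re-measured step must reach. Default 2/3.
#' @return an `event_log` with columns cycle, time, direction, force,
#'   force_after, delta_x; attributes `usable` (FALSE when the branches
#'   are indistinguishable, separation < 2 nm), `initial_state` and `qc`
#'   (candidates dropped at the confirmation stage, plus the number of
#'   same-direction successions, which flag unresolved transitions in
#'   between).
#' @export
detect_events <- function(half_cycle, branches = NULL, min_jump = 0.5,
                          debounce = 3, median_window = 5,
                          level_window = 20, confirm_frac = 2/3) {
  stopifnot(inherits(half_cycle, "fdc_trace"))
  if (is.null(branches)) branches <- fit_branches(half_cycle)
  f <- half_cycle$force
  med <- stats::runmed(f, median_window, endrule = "median")
  # difference spanned over a few samples: the median filter can smear a
  # step across two increments, and a single-lag difference would then
  # miss jumps whose increments both fall below threshold
  span <- 3L
  n_med <- length(med)
  d <- med[(1L + span):n_med] - med[1:(n_med - span)]
  hit <- which(abs(d) >= min_jump)
  empty <- function(usable = TRUE, initial_state = "B", dropped = 0L) {
    ev <- data.frame(cycle = integer(), time = numeric(),
                     direction = character(), force = numeric(),
                     delta_x = numeric(), stringsAsFactors = FALSE)
    class(ev) <- c("event_log", "data.frame")
    attr(ev, "usable") <- usable
    attr(ev, "initial_state") <- initial_state
    attr(ev, "qc") <- list(dropped = dropped, n_repeat = 0L)
    ev
  }
  # effective stiffness: the trap dominates the serial compliance, so the
  # protocol's trap stiffness is the cleanest conversion from force step to
  # extension; fall back to the fitted branch slope for foreign traces
  proto <- attr(half_cycle, "protocol")
  K_eff <- if (!is.null(proto)) proto$K_trap
           else if (branches$single_state) branches$B$slope
           else mean(c(branches$B$slope, branches$S$slope))
  usable <- TRUE
  if (!branches$single_state) {
    sep <- branch_separation(branches, mean(branches$force_window))
    if (!is.finite(sep) || sep < 2) usable <- FALSE
  }
  if (length(hit) == 0) return(empty(usable))

  # merge runs of crossings closer than `debounce` samples; measure the
  # step as the level difference just outside the run (the median filter
  # has settled there), and re-threshold so that unresolved flicker pairs
  # with no net step are discarded rather than mis-directed
  grp <- cumsum(c(1L, diff(hit) > debounce))
  starts <- unname(tapply(hit, grp, min))
  ends <- unname(tapply(hit, grp, max)) + span - 1L  # cover the full step
  n_run <- length(starts)
  prev_end <- c(-2L, ends[-n_run])
  next_start <- c(starts[-1L], length(med) + 2L)
  pre_idx <- pmax(pmax(starts - 1L, prev_end + 2L), 1L)
  post_idx <- pmin(pmin(ends + 2L, next_start - 1L), length(med))
  post_idx <- pmax(post_idx, pmin(ends + 1L, length(med)))
  amp <- med[post_idx] - med[pre_idx]
  # edge guard: a step within the filter settling span of a half-cycle
  # boundary has no measurable levels on both sides
  interior <- starts > median_window & ends < length(med) - median_window
  big <- abs(amp) >= min_jump & interior
  starts <- starts[big]; ends <- ends[big]; amp <- amp[big]
  if (length(starts) == 0) return(empty(usable))

  # initial state: the ramp extremes lie outside the bistable band by
  # protocol design (no transitions ever occur beyond them), so a stretch
  # half starts in B at F_min and a release half starts in S at F_max;
  # fall back to the nearer branch over the first samples if the ramp
  # phase is unknown
  ramp_dir <- attr(half_cycle, "direction")
  if (!is.null(ramp_dir)) {
    initial_state <- if (ramp_dir == "stretch") "B" else "S"
  } else {
    init_idx <- seq_len(min(max(debounce, 5L), starts[1]))
    initial_state <- "B"
    if (!branches$single_state) {
      lam0 <- half_cycle$trap_position[init_idx]
      f0 <- f[init_idx]
      dB <- abs(f0 - (branches$B$intercept + branches$B$slope * lam0))
      dS <- abs(f0 - (branches$S$intercept + branches$S$slope * lam0))
      initial_state <- if (mean(dB) <= mean(dS)) "B" else "S"
    }
  }

  dropped <- 0L

  # second pass: re-measure each step from branch-classified raw samples.
  # Unresolved flicker (sub-bandwidth excursions to the other state) sits a
  # full jump away from the local level and would bias a plain median; the
  # nearest-branch classification excludes those samples.
  force_at <- f[starts]
  if (!branches$single_state) {
    lamv <- half_cycle$trap_position
    resB <- abs(med - (branches$B$intercept + branches$B$slope * lamv))
    resS <- abs(med - (branches$S$intercept + branches$S$slope * lamv))
    samp_state <- ifelse(resB <= resS, "B", "S")
    # ramp detrend at the known effective stiffness; the fitted shared
    # slope is slightly tilted by the force-dependent fray offsets, and a
    # tilted detrend would bias long level windows
    slope <- if (!is.null(proto)) proto$K_trap else branches$B$slope
    n <- length(f)
    # local vertical separation of the branches (the lines are not quite
    # parallel: fraying makes the S line steeper)
    sep_at <- function(lam1)
      abs((branches$B$intercept - branches$S$intercept) +
            (branches$B$slope - branches$S$slope) * lam1)
    sep_vv <- sep_at(lamv[starts])
    # minimum classified-run length: a phantom event needs a run of
    # noise-misclassified samples, each misclassified with probability
    # p_mis; require runs long enough that the expected number of such
    # runs in this half-cycle is below one
    sigma_loc <- mad(diff(f)) / sqrt(2) * 0.54  # runmed(5) noise gain
    p_mis <- 2 * stats::pnorm(-mean(sep_vv) / (2 * max(sigma_loc, 1e-9)))
    n_min_run <- 2L
    if (is.finite(p_mis) && p_mis > 0 && p_mis < 1)
      n_min_run <- max(2L, min(8L, ceiling(log(1 / length(f)) / log(p_mis))))
    adjacent_run <- function(idx, ok, from_end) {
      # contiguous run of accepted samples nearest the event edge (so the
      # level belongs to the dwell the jump connects, not to a later
      # flicker excursion with a different fray offset)
      if (!any(ok)) return(integer())
      r <- rle(ok)
      stops <- cumsum(r$lengths)
      begins <- stops - r$lengths + 1L
      runs <- which(r$values)
      pick <- if (from_end) runs[length(runs)] else runs[1L]
      idx[begins[pick]:stops[pick]]
    }
    for (i in seq_along(starts)) {
      pre_state <- if (amp[i] < 0) "B" else "S"
      post_state <- if (amp[i] < 0) "S" else "B"
      lam0 <- lamv[starts[i]]
      pre_idx <- max(1L, starts[i] - level_window):starts[i]
      post_idx <- min(n, ends[i] + 1L):min(n, ends[i] + level_window + 1L)
      pre_w <- adjacent_run(pre_idx, samp_state[pre_idx] == pre_state, TRUE)
      post_w <- adjacent_run(post_idx, samp_state[post_idx] == post_state, FALSE)
      if (length(pre_w) < n_min_run || length(post_w) < n_min_run) {
        # no settled dwell on both sides: a residue of sub-bandwidth
        # flicker that the filtered diff mistook for a step
        amp[i] <- 0
        next
      }
      detr <- function(w) f[w] - slope * (lamv[w] - lam0)
      lev_pre <- median(detr(pre_w))
      lev_post <- median(detr(post_w))
      # refinement: reselect dwell samples symmetrically around each level
      # and iterate to convergence. The first-pass selection cuts at the
      # midline between the branches, which one-sidedly truncates the noise
      # of a dwell whose branch runs close to the midline (the S branch
      # does, increasingly with force, through fraying) and would bias the
      # level read; re-centring the acceptance band removes the truncation
      for (pass in 1:3) {
        pre_w2 <- adjacent_run(pre_idx, abs(detr(pre_idx) - lev_pre) < sep_vv[i] / 2, TRUE)
        post_w2 <- adjacent_run(post_idx, abs(detr(post_idx) - lev_post) < sep_vv[i] / 2, FALSE)
        if (length(pre_w2) < 2 || length(post_w2) < 2) break
        lev_pre <- median(detr(pre_w2))
        lev_post <- median(detr(post_w2))
        pre_w <- pre_w2; post_w <- post_w2
      }
      if (length(pre_w) >= 2) {
        # the last pre-jump sample (timing from the dwell selection, not
        # the filtered diff, which jitters under noise) is reported as the
        # event force; it is kept out of the level median so the force and
        # extension estimates carry independent noise (a shared term would
        # bias the fraying regression)
        force_at[i] <- f[pre_w[length(pre_w)]]
        if (length(pre_w) >= 3) pre_w <- pre_w[-length(pre_w)]
      }
      if (length(pre_w) >= 2 && length(post_w) >= 2) {
        amp[i] <- median(detr(post_w)) - median(detr(pre_w))
      } else {
        amp[i] <- 0
      }
    }
    # a genuine transition connects the two branches, so its settled step
    # must be comparable to the fitted branch separation; runs of
    # noise-misclassified samples produce sub-separation steps. Where the
    # converging branches are within the classification margin (towards
    # the ramp top) no step is measurable at all
    confirmed <- abs(amp) >= pmax(min_jump, confirm_frac * sep_vv) &
      sep_vv >= 5 * sigma_loc
    dropped <- dropped + sum(!confirmed)
    starts <- starts[confirmed]; ends <- ends[confirmed]
    amp <- amp[confirmed]; force_at <- force_at[confirmed]
    sep_vv <- sep_vv[confirmed]
    if (length(starts) == 0) return(empty(usable, initial_state, dropped))
  }

  # directions follow the sign of the confirmed, level-measured step; a
  # same-direction succession means the partner transition of an
  # unresolved flicker excursion was missed in between, so it is counted
  # in QC (and the dwell spanning it is invalidated downstream) rather
  # than used to drop measured events, which would cascade
  dirs <- ifelse(amp < 0, "BtoS", "StoB")
  n_repeat <- sum(head(dirs, -1) == tail(dirs, -1))
  # per-event extension change: horizontal distance between the fitted
  # branches at the event force. Because fraying makes the S line steeper
  # than the B line, this distance shrinks with force and carries the
  # fraying signal; the raw force step over K_eff is kept as the fallback
  # when only one branch could be fitted
  delta_x <- if (!branches$single_state)
    abs(branch_separation(branches, force_at)) else abs(amp) / K_eff
  ev <- data.frame(
    cycle = half_cycle$cycle_id[starts],
    time = half_cycle$time[starts],
    direction = dirs,
    force = force_at,
    force_after = force_at + amp,
    delta_x = delta_x,
    stringsAsFactors = FALSE)
  class(ev) <- c("event_log", "data.frame")
  attr(ev, "usable") <- usable
  attr(ev, "initial_state") <- initial_state
  attr(ev, "qc") <- list(dropped = dropped, n_repeat = n_repeat)
  ev
}

#' Dwell intervals between transitions
#'
#' Cuts a half-cycle into residence intervals in one state: the first dwell
#' enters at the ramp start force, each transition closes one dwell and
#' opens the next in the other state, and the final dwell is censored at
#' the ramp end. Dwell count is event count + 1 when the event directions
#' are fully consistent; intervals bracketed by same-direction events (or
#' inconsistent with the known ramp-end states) contain unresolved
#' transitions and are omitted.
#'
#' @param half_cycle one half-cycle trace.
#' @param events the [detect_events()] result for it (or ground-truth
#'   events restricted to this half-cycle).
#' @param initial_state state at the ramp start; default taken from the
#'   events' attribute, else from the first event direction, else `"B"`.
#' @return a `dwell_table` data.frame: state, entry_force, exit_force,
#'   exit_kind (`"transition"`/`"censored"`), ramp, cycle.
#' @export
extract_dwells <- function(half_cycle, events, initial_state = NULL) {
  stopifnot(inherits(half_cycle, "fdc_trace"))
  ramp <- attr(half_cycle, "direction") %||%
    (if (median(diff(half_cycle$trap_position)) > 0) "stretch" else "release")
  if (nrow(events) > 0 && is.unsorted(events$time))
    stop("out-of-order events")
  if (is.null(initial_state))
    initial_state <- attr(events, "initial_state") %||%
      (if (ramp == "stretch") "B" else "S")
  K_eff <- attr(half_cycle, "protocol")$K_trap %||% 0.1
  med <- stats::runmed(half_cycle$force, 5, endrule = "median")
  f_start <- med[1]
  f_end <- med[length(med)]
  cyc <- half_cycle$cycle_id[1]

  t_start <- half_cycle$time[1]
  t_end <- half_cycle$time[nrow(half_cycle)]
  n_ev <- nrow(events)
  if (n_ev == 0) {
    dw <- data.frame(state = initial_state, entry_force = f_start,
                     exit_force = f_end, entry_time = t_start,
                     exit_time = t_end, exit_kind = "censored",
                     ramp = ramp, cycle = cyc, stringsAsFactors = FALSE)
    class(dw) <- c("dwell_table", "data.frame")
    return(dw)
  }
  pre_state <- ifelse(events$direction == "BtoS", "B", "S")
  land_state <- ifelse(events$direction == "BtoS", "S", "B")
  # post-jump force: logged with the event when available (simulator truth
  # or measured landing level); else pre-jump force -/+ the nominal step
  force_after <- if (!is.null(events$force_after)) {
    events$force_after
  } else {
    events$force + ifelse(events$direction == "BtoS", -1, 1) *
      K_eff * events$delta_x
  }
  states <- c(pre_state[1], land_state)
  entry <- c(f_start, force_after)
  exitf <- c(events$force, f_end)
  entry_t <- c(t_start, events$time)
  exit_t <- c(events$time, t_end)
  kind <- c(rep("transition", n_ev), "censored")
  # a dwell between two events is only meaningful if the second event
  # departs from the state the first one landed in; a same-direction
  # succession means at least one unresolved transition happened in
  # between, so that interval carries no usable residence information.
  # The first and last dwells are likewise only usable if they connect to
  # the known states at the ramp ends (pure B at the bottom, pure S at
  # the top of the window, outside which no transitions occur)
  end_state <- if (ramp == "stretch") "S" else "B"
  valid <- c(pre_state[1] == initial_state,
             land_state == c(pre_state[-1], end_state))
  dw <- data.frame(state = states, entry_force = entry, exit_force = exitf,
                   entry_time = entry_t, exit_time = exit_t,
                   exit_kind = kind, ramp = ramp, cycle = cyc,
                   stringsAsFactors = FALSE)[valid, , drop = FALSE]
  rownames(dw) <- NULL
  class(dw) <- c("dwell_table", "data.frame")
  dw
}

#' Per-sample state assignment
#'
#' Labels every sample of a half-cycle B or S from the detected events:
#' state is constant between transitions, starting from the detector's
#' initial state.
#'
#' @param half_cycle one half-cycle trace.
#' @param events [detect_events()] result for it.
#' @return character vector of `"B"`/`"S"`, one per sample.
#' @export
classify_states <- function(half_cycle, events) {
  init <- attr(events, "initial_state") %||% "B"
  n <- nrow(half_cycle)
  st <- rep(init, n)
  if (nrow(events) > 0) {
    idx <- findInterval(half_cycle$time, events$time + 1e-12)
    seq_states <- character(nrow(events) + 1)
    seq_states[1] <- init
    for (i in seq_len(nrow(events)))
      seq_states[i + 1] <- if (events$direction[i] == "BtoS") "S" else "B"
    st <- seq_states[idx + 1L]
  }
  st
}

#' Run detection over a whole multi-cycle trace
#'
#' Segments the trace, fits branches and detects events per half-cycle,
#' extracts dwell intervals and per-sample state labels, and aggregates
#' per-cycle QC.
#'
#' @param trace an `fdc_trace` (typically noisy, from
#'   [simulate_dataset()] or [read_trace()]).
#' @param pool_branches fit the branch lines once on the whole trace
#'   (default) rather than per half-cycle; pooling sharpens the S-line
#'   slope that carries the fray signal and is appropriate whenever the
#'   instrument does not drift between cycles.
#' @inheritParams detect_events
#' @return list with `events` (event_log over all half-cycles), `dwells`
#'   (dwell_table), `states` (data.frame: time, force, cycle, ramp, state),
#'   `qc` (per half-cycle: branch rms, event count, usable flag).
#' @export
detect_dataset <- function(trace, min_jump = 0.5, debounce = 3,
                           median_window = 5, pool_branches = TRUE) {
  halves <- segment_cycles(trace)
  # branch elasticity is a property of the construct, not of one ramp, so
  # by default the two lines are fitted once on the pooled trace; the
  # slope contrast between the S and B lines (the fray signal) is then
  # determined by the full dataset rather than one half-cycle
  br_global <- if (pool_branches) fit_branches(trace) else NULL
  ev_list <- list(); dw_list <- list(); st_list <- list(); qc <- list()
  for (h in halves) {
    br <- if (pool_branches) br_global else fit_branches(h)
    ev <- detect_events(h, br, min_jump = min_jump, debounce = debounce,
                        median_window = median_window)
    dw <- extract_dwells(h, ev)
    st <- classify_states(h, ev)
    ev_list[[length(ev_list) + 1L]] <- ev
    dw_list[[length(dw_list) + 1L]] <- dw
    st_list[[length(st_list) + 1L]] <- data.frame(
      time = h$time, force = h$force, cycle = h$cycle_id,
      ramp = attr(h, "direction"), state = st, stringsAsFactors = FALSE)
    qc[[length(qc) + 1L]] <- data.frame(
      half_id = attr(h, "half_id"), cycle = h$cycle_id[1],
      direction = attr(h, "direction"),
      rms_B = br$B$rms, rms_S = if (br$single_state) NA_real_ else br$S$rms,
      n_events = nrow(ev), usable = attr(ev, "usable"),
      dropped = attr(ev, "qc")$dropped,
      n_repeat = attr(ev, "qc")$n_repeat)
  }
  events <- do.call(rbind, ev_list)
  class(events) <- c("event_log", "data.frame")
  dwells <- do.call(rbind, dw_list)
  class(dwells) <- c("dwell_table", "data.frame")
  list(events = events, dwells = dwells,
       states = do.call(rbind, st_list), qc = do.call(rbind, qc))
}
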