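#' Write and read force-distance traces
#'
#' Traces travel as tab-separated text (columns `time_s`,
#' `trap_position_nm`, `force_pN`, optionally `cycle_id` and `truth_state`)
#' with a JSON sidecar (`<path>.json`) carrying the protocol metadata:
#' construct, temperature_C, salt_mM, K_trap_pN_per_nm, velocity_nm_per_s,
#' F_min_pN, F_max_pN, sample_rate_Hz, seed, cycle_count. Numeric columns
#' round-trip losslessly at 9 significant digits.
#'
#' @param trace an `fdc_trace` (see [simulate_cycle()]).
#' @param path file to write the TSV to; the sidecar goes to `<path>.json`.
#' @param metadata named list merged over the defaults taken from the
#'   trace's protocol attribute.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns an
#'   `fdc_trace` with the sidecar stored in the `"sidecar"` attribute.
#' @export
write_trace <- function(trace, path, metadata = list()) {
  stopifnot(inherits(trace, "fdc_trace"))
  proto <- attr(trace, "protocol")
  side <- list(
    construct = attr(trace, "construct") %||% "unknown",
    temperature_C = 23, salt_mM = 1000,
    K_trap_pN_per_nm = proto$K_trap, velocity_nm_per_s = proto$velocity,
    F_min_pN = proto$F_min, F_max_pN = proto$F_max,
    sample_rate_Hz = proto$sample_rate, seed = NA,
    cycle_count = length(unique(trace$cycle_id)))
  side <- modifyList(side, metadata)
  out <- data.frame(
    time_s = sprintf("%.9g", trace$time),
    trap_position_nm = sprintf("%.9g", trace$trap_position),
    force_pN = sprintf("%.9g", trace$force),
    cycle_id = trace$cycle_id,
    stringsAsFactors = FALSE)
  if (!is.null(trace$truth_state)) out$truth_state <- trace$truth_state
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(jsonlite::toJSON(side, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, na = "null"),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(path)) stop("trace file not found: ", path)
  if (!file.exists(sidecar_path))
    stop("missing sidecar: ", sidecar_path)
  side <- jsonlite::fromJSON(sidecar_path)
  required <- c("construct", "K_trap_pN_per_nm", "velocity_nm_per_s",
                "F_min_pN", "F_max_pN", "sample_rate_Hz", "cycle_count")
  missing_f <- setdiff(required, names(side))
  if (length(missing_f) > 0)
    stop("sidecar missing required field(s): ", paste(missing_f, collapse = ", "))
  raw <- read.delim(path, stringsAsFactors = FALSE)
  for (col in c("time_s", "trap_position_nm", "force_pN"))
    if (!col %in% names(raw)) stop("trace missing column: ", col)
  if (any(diff(raw$time_s) <= 0)) stop("non-monotone time")
  trace <- data.frame(
    time = raw$time_s, trap_position = raw$trap_position_nm,
    force = raw$force_pN,
    cycle_id = if (!is.null(raw$cycle_id)) raw$cycle_id else 1L,
    stringsAsFactors = FALSE)
  if (!is.null(raw$truth_state)) trace$truth_state <- raw$truth_state
  attr(trace, "protocol") <- ramp_protocol(
    F_min = side$F_min_pN, F_max = side$F_max_pN,
    velocity = side$velocity_nm_per_s, K_trap = side$K_trap_pN_per_nm,
    sample_rate = side$sample_rate_Hz, n_cycles = max(1L, side$cycle_count),
    noise_sigma_F = side$noise_sigma_F %||% 0)
  attr(trace, "construct") <- side$construct
  attr(trace, "sidecar") <- side
  class(trace) <- c("fdc_trace", "data.frame")
  trace
}

#' Write and read transition event tables
#'
#' Events as CSV with columns cycle, time_s, direction, force_pN,
#' delta_x_nm.
#'
#' @param events an `event_log`.
#' @param path CSV path.
#' @return `write_events` returns `path` invisibly; `read_events` an
#'   `event_log`.
#' @export
write_events <- function(events, path) {
  out <- data.frame(cycle = events$cycle,
                    time_s = sprintf("%.9g", events$time),
                    direction = events$direction,
                    force_pN = sprintf("%.9g", events$force),
                    delta_x_nm = sprintf("%.9g", events$delta_x))
  write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  ev <- data.frame(cycle = raw$cycle, time = raw$time_s,
                   direction = raw$direction, force = raw$force_pN,
                   delta_x = raw$delta_x_nm, stringsAsFactors = FALSE)
  class(ev) <- c("event_log", "data.frame")
  ev
}

#' Segment a trace into stretch/release half-cycles
#'
#' Splits the series at the turning points of the trap position (the
#' noise-free command signal; force would be confounded by transition
#' jumps). A turning-point sample closes the preceding half-cycle
#' (half-open intervals). Half-cycles alternate stretch/release; each takes
#' about `(F_max - F_min) / (K_trap * velocity)` seconds.
#'
#' @param trace an `fdc_trace` spanning at least one ramp.
#' @param F_min,F_max optional force window (defaults from the trace's
#'   protocol); retained as metadata on each half-cycle.
#' @return list of `fdc_trace` half-cycles, each with attributes
#'   `direction` (`"stretch"`/`"release"`) and `half_id`.
#' @export
segment_cycles <- function(trace, F_min = NULL, F_max = NULL) {
  stopifnot(inherits(trace, "fdc_trace"))
  if (nrow(trace) == 0) stop("empty trace")
  proto <- attr(trace, "protocol")
  if (is.null(F_min)) F_min <- proto$F_min
  if (is.null(F_max)) F_max <- proto$F_max
  lam <- trace$trap_position
  if (length(unique(lam)) < 2) stop("no ramp: trap position is constant")
  d <- diff(lam)
  s <- sign(d)
  s[s == 0] <- NA
  s <- zoo_na_locf(s)
  turns <- which(diff(s) != 0) + 1L   # index of turning-point sample
  bounds <- c(0L, turns, nrow(trace))
  halves <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    idx <- (bounds[i] + 1L):bounds[i + 1L]
    if (length(idx) < 2) next
    h <- trace[idx, , drop = FALSE]
    dir <- if (median(diff(h$trap_position)) > 0) "stretch" else "release"
    attr(h, "protocol") <- proto
    attr(h, "construct") <- attr(trace, "construct")
    attr(h, "direction") <- dir
    attr(h, "half_id") <- length(halves) + 1L
    attr(h, "F_window") <- c(F_min, F_max)
    class(h) <- c("fdc_trace", "data.frame")
    halves[[length(halves) + 1L]] <- h
  }
  if (length(halves) == 0) stop("no turning point found and trace too short")
  if (length(halves) == 1)
    warning("monotone trace: single ", attr(halves[[1]], "direction"),
            " half-cycle")
  halves
}

# last-observation-carried-forward for the leading/trailing NA run
zoo_na_locf <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) stop("no ramp: trap position is constant")
  idx <- cummax(ifelse(ok, seq_along(x), 0L))
  first <- which(ok)[1]
  idx[idx == 0L] <- first
  x[idx]
}
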