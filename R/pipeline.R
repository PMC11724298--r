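#' Assemble and validate a pipeline configuration
#'
#' One configuration object drives the whole chain: simulate
#' stretch/release cycles for a set of constructs, detect transitions,
#' run the equilibrium and kinetic analyses, reconstruct the free-energy
#' profile, and write tabular reports. Unknown fields are rejected; a seed
#' is mandatory because the pipeline starts from simulation.
#'
#' @param constructs character vector of preset names (see
#'   [construct_preset()]) or a list of [construct_model()] objects.
#' @param protocol named list of [ramp_protocol()] arguments.
#' @param n_cycles cycles per construct (scalar or one per construct);
#'   default: the `m` column of [preset_table()] for named presets, else
#'   50.
#' @param detector named list of [detect_dataset()] arguments
#'   (`min_jump`, `debounce`, `median_window`).
#' @param n_boot bootstrap resamples for SEMs. Default 200.
#' @param reference name of the construct used as the unmodified
#'   reference for the stabilisation free energy. Default
#'   `"Unmodified"` when present.
#' @param out_dir directory for report files; `NULL` for no files.
#' @param seed integer root seed (required).
#' @param path alternatively, read the configuration from a JSON (or
#'   YAML, if the yaml package is installed) file with these fields.
#' @return a validated `pipeline_config` object.
#' @export
pipeline_config <- function(constructs = "Unmodified", protocol = list(),
                            n_cycles = NULL, detector = list(),
                            n_boot = 200, reference = NULL, out_dir = NULL,
                            seed, path = NULL) {
  if (!is.null(path)) {
    raw <- if (grepl("\\.ya?ml$", path)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs requires the yaml package")
      yaml::read_yaml(path)
    } else jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    allowed <- c("constructs", "protocol", "n_cycles", "detector",
                 "n_boot", "reference", "out_dir", "seed")
    unknown <- setdiff(names(raw), allowed)
    if (length(unknown) > 0)
      stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    return(do.call(pipeline_config, raw))
  }
  if (missing(seed) || is.null(seed))
    stop("`seed` is mandatory for simulation runs")
  if (is.character(constructs)) {
    constructs <- lapply(constructs, construct_preset)
  } else if (inherits(constructs, "construct_model")) {
    constructs <- list(constructs)
  } else if (is.list(constructs) && !inherits(constructs[[1]], "construct_model")) {
    constructs <- lapply(constructs, function(p) do.call(construct_model, p))
  }
  names(constructs) <- vapply(constructs, `[[`, "", "name")
  bad_proto <- setdiff(names(protocol),
                       names(formals(ramp_protocol)))
  if (length(bad_proto) > 0)
    stop("unknown protocol field(s): ", paste(bad_proto, collapse = ", "))
  bad_det <- setdiff(names(detector),
                     c("min_jump", "debounce", "median_window"))
  if (length(bad_det) > 0)
    stop("unknown detector field(s): ", paste(bad_det, collapse = ", "))
  if (is.null(n_cycles)) {
    tab <- preset_table()
    n_cycles <- vapply(names(constructs), function(nm) {
      if (nm %in% tab$construct) tab$m[tab$construct == nm] else 50L
    }, numeric(1))
  }
  n_cycles <- rep_len(as.integer(n_cycles), length(constructs))
  if (is.null(reference) && "Unmodified" %in% names(constructs))
    reference <- "Unmodified"
  structure(list(constructs = constructs, protocol = protocol,
                 n_cycles = n_cycles, detector = detector, n_boot = n_boot,
                 reference = reference, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Simulate, detect, and analyse every configured construct, then pool the
#' constructs for the barrier scaling and free-energy profile. With an
#' output directory set, writes `table1.json`/`.csv` (equilibrium
#' results), `table2.json`/`.csv` (kinetics), `profile.csv`,
#' and `manifest.json`. Deterministic under the configured seed.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with `equilibrium` and `kinetics` (one
#'   entry per construct), `barrier` (`g_ts` fit across constructs),
#'   `attempt` (attempt-rate estimate), `profile` (an `fe_profile`),
#'   `table1`, `table2` (data.frame reports) and `detections`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  protocol <- do.call(ramp_protocol, config$protocol)
  kbt <- boltzmann_energy()
  x_BS <- bs_constants()$x_BS

  sims <- simulate_dataset(config$constructs, protocol,
                           n_cycles = config$n_cycles, seed = config$seed)
  eq <- list(); kin <- list(); detections <- list()
  for (nm in names(sims)) {
    det <- do.call(detect_dataset, c(list(sims[[nm]]$trace), config$detector))
    detections[[nm]] <- det
    m <- config$n_cycles[match(nm, names(sims))]
    e <- tryCatch(
      equilibrium_analysis(det, kbt = kbt, x_BS = x_BS,
                           n_boot = config$n_boot),
      error = function(err) stop("equilibrium stage failed for construct ",
                                 nm, ": ", conditionMessage(err)))
    k <- tryCatch(
      kinetics_analysis(det, protocol, F_tr = e$F_tr_hat, n_hat = e$n_hat,
                        n_cycles = m),
      error = function(err) stop("kinetics stage failed for construct ",
                                 nm, ": ", conditionMessage(err)))
    eq[[nm]] <- e
    kin[[nm]] <- k
  }
  # stabilisation free energies against the reference construct
  if (!is.null(config$reference) && config$reference %in% names(eq)) {
    g_ref <- eq[[config$reference]]$g_hat
    for (nm in names(eq))
      eq[[nm]]$dG <- stabilization_dG(eq[[nm]]$G_BS, eq[[nm]]$n_hat, g_ref)
  }

  barrier <- NULL; attempt <- NULL; profile <- NULL
  if (length(eq) >= 2) {
    n_vec <- vapply(eq, `[[`, 0, "n_hat")
    N_vec <- vapply(kin, `[[`, 0, "N")
    barrier <- barrier_per_bp(n_vec, N_vec)
  }
  ref <- config$reference %||% names(eq)[1]
  if (!is.null(barrier)) {
    attempt <- attempt_rate(kin[[ref]]$k_at_ftr, eq[[ref]]$n_hat,
                            max(barrier$g_ts, 0))
    profile <- free_energy_profile(
      g_ts = max(barrier$g_ts, 1e-6),
      x_ts = kin[[ref]]$X_b_ts_hat / eq[[ref]]$n_hat,
      F_tr = eq[[ref]]$F_tr_hat, x_BS = x_BS, kbt = kbt)
  }

  table1 <- do.call(rbind, lapply(names(eq), function(nm) {
    e <- eq[[nm]]
    data.frame(construct = nm, m = e$m, F_tr = e$F_tr_hat,
               F_tr_sem = e$F_tr_sem, dX = e$dX_hat, dX_sem = e$dX_sem,
               G_BS = e$G_BS, G_BS_sem = e$G_BS_sem, G_BS_bar = e$G_BS_bar,
               n = e$n_hat, g = e$g_hat, dG = e$dG,
               fray_slope = e$fray_slope_hat)
  }))
  table2 <- do.call(rbind, lapply(names(kin), function(nm) {
    k <- kin[[nm]]
    data.frame(construct = nm, X_b_ts = k$X_b_ts_hat,
               X_b_ts_se = k$X_b_ts_se, X_s_ts = k$X_s_ts_hat,
               X_s_ts_se = k$X_s_ts_se, X_BS = k$X_BS_hat,
               x_b_ts = k$x_b_ts, x_s_ts = k$x_s_ts,
               ts_pct = k$ts_fraction, k_at_ftr = k$k_at_ftr,
               N = k$N, N_sem = k$N_sem)
  }))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wjson <- function(x, f)
      jsonlite::write_json(x, file.path(config$out_dir, f),
                           auto_unbox = TRUE, digits = NA, na = "null",
                           dataframe = "rows")
    wjson(table1, "table1.json")
    wjson(table2, "table2.json")
    write.csv(table1, file.path(config$out_dir, "table1.csv"), row.names = FALSE)
    write.csv(table2, file.path(config$out_dir, "table2.csv"), row.names = FALSE)
    if (!is.null(profile))
      write.csv(data.frame(x_nm_per_bp = profile$x,
                           g_at_Ftr_kBT = profile$g_at_Ftr,
                           g_at_zero_kBT = profile$g_at_zero),
                file.path(config$out_dir, "profile.csv"), row.names = FALSE)
    manifest <- list(
      seed = config$seed,
      constructs = names(config$constructs),
      n_cycles = config$n_cycles,
      protocol = unclass(protocol),
      g_ts = if (!is.null(barrier)) barrier$g_ts else NULL,
      k0_BS = if (!is.null(attempt)) attempt$k0_BS else NULL)
    wjson(manifest, "manifest.json")
  }
  invisible(list(equilibrium = eq, kinetics = kin, barrier = barrier,
                 attempt = attempt, profile = profile,
                 table1 = table1, table2 = table2,
                 detections = detections))
}
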