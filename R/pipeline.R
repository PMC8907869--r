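#' Full calibration pipeline on a patient bundle
#'
#' Runs the complete workflow on a (virtual or file-loaded) patient:
#' pressure-target derivation, outlet flow targets, distensibility
#' estimation from the area waveforms, whole-system Windkessel tuning of
#' the total compliance, 0D network assembly, proximal-resistance tuning
#' against the pressure targets, and (when a mesh is present) the wall
#' stiffness field with its smoothing passes.
#'
#' @param vp a `virtual_patient` (or equivalently structured bundle).
#' @param mode `"compliant"` or `"rigid"`. The rigid mode removes the
#'   segment volume-compliance states but keeps the compliant outlet
#'   capacitances, so both variants target identical pressures and flows.
#' @param tol relative pressure tolerance for both tuning stages.
#' @param round_psa see [derive_central_pressures()].
#' @param smoothing_passes stiffness smoothing passes (default 5).
#' @param boundary_factor boundary-ring stiffening factor.
#' @param ctot optional pre-computed total arterial compliance (skips the
#'   system-Windkessel stage, e.g. when the rigid run reuses the compliant
#'   calibration).
#' @param fixed_c optional named per-outlet capacitances (ml/mmHg). When
#'   given, the outlet C column is taken as-is and only the proximal
#'   resistances are tuned — the default pipeline uses this so the rigid
#'   variant reports the same C column as the compliant one.
#' @param verbose print per-stage progress.
#' @return object of class `calibration`: list with `targets`,
#'   `flow_targets`, `D_regions` (1/mmHg), `system` (`system_wk3`),
#'   `network` (tuned `network_0d`), `result` (`sim_result_0d`),
#'   `wk3` (data.frame), `field`, `mesh`, `mode`.
#' @export
calibrate_patient <- function(vp, mode = c("compliant", "rigid"),
                              tol = 0.005, round_psa = TRUE,
                              smoothing_passes = 5, boundary_factor = 1e3,
                              ctot = NULL, fixed_c = NULL, verbose = FALSE) {
  mode <- match.arg(mode)
  say <- function(...) if (verbose) message(sprintf(...))

  say("[targets] deriving central pressures and flow targets")
  targets <- derive_central_pressures(vp$psb, vp$pdb, round_psa = round_psa)
  sa_ids <- setdiff(vp$branches$id, terminal_id(vp))
  sa_areas <- stats::setNames(
    vp$branches$area_m2[match(sa_ids, vp$branches$id)], sa_ids)
  ft <- flow_targets(vp$waveform$qmean, vp$qda, sa_areas,
                     terminal_id = terminal_id(vp))

  say("[mechanics] distensibility from area waveforms")
  D_regions <- vapply(vp$area_waves, distensibility_from_area,
                      numeric(1), ppulse = targets$ppulse)

  seg <- vp$segments
  segments <- lapply(seq_len(nrow(seg)), function(i)
    segment_props(seg$id[i], seg$length_m[i], seg$area_m2[i],
                  seg$volume_ml[i], D_mmhg = D_regions[[seg$region[i]]],
                  rho = vp$profile$rho))
  cv_sum <- sum(vapply(segments, function(s) s$CV, numeric(1)))

  if (is.null(ctot)) {
    say("[system-wk3] tuning total arterial compliance")
    sys <- tune_system_wk3(vp$waveform, targets, tol = tol)
  } else {
    sys <- ctot
  }
  cper <- sys$Ctot - cv_sum
  if (cper < 0) {
    warning("segment compliance exceeds the tuned total; peripheral ",
            "compliance clamped to zero")
    cper <- 0
  }
  say("[system-wk3] Ctot %.3f ml/mmHg, Cper %.3f ml/mmHg", sys$Ctot, cper)

  cw <- if (is.null(fixed_c))
    wk3_capacitances(cper, ft$targets, vp$waveform$qmean,
                     terminal_id = terminal_id(vp))
  else fixed_c[vp$branches$id]
  rho <- vp$profile$rho
  wk3s <- lapply(vp$branches$id, function(id) {
    i <- match(id, vp$branches$id)
    rtot <- total_outlet_resistance(targets$pmean, ft$targets[[id]])
    bp <- branch_distensibility(vp$branches$diameter_mm[i], rho)
    rp <- initial_rp(rho, bp$pwv, vp$branches$area_m2[i], rtot = rtot)
    wk3_params(rp, rtot - rp, cw[[id]], id = id)
  })
  names(wk3s) <- vp$branches$id

  topo <- list(
    attach = stats::setNames(
      vp$branches$attach_to[match(sa_ids, vp$branches$id)], sa_ids),
    terminal = terminal_id(vp))
  net <- build_network(segments, wk3s, topo,
                       compliant = mode == "compliant")

  say("[network] tuning proximal resistances (%s)", mode)
  tuned <- tune_network(net, vp$waveform, targets, tol = tol,
                        tune_c = is.null(fixed_c))
  res <- attr(tuned, "result")
  say("[network] inlet %.1f/%.1f mmHg in %d cycle(s)",
      res$psys, res$pdias, res$cycles)

  field <- NULL
  if (!is.null(vp$mesh)) {
    say("[stiffness] building and smoothing the wall stiffness field")
    amin_m2 <- vapply(vp$area_waves, function(w) w$amin, numeric(1)) * 1e-6
    ca <- area_compliance(distensibility_mmhg_to_pa(D_regions), amin_m2)
    field <- stiffness_field(vp$mesh, ca, amin_m2,
                             boundary_factor = boundary_factor,
                             pext = mmhg_to_pa(targets$pda))
    field <- smooth_field(field, vp$mesh, passes = smoothing_passes)
  }

  structure(list(
    targets = targets, flow_targets = ft, D_regions = D_regions,
    system = sys, cper = cper, network = tuned, result = res,
    wk3 = wk3_table(tuned), field = field, mesh = vp$mesh, mode = mode
  ), class = "calibration")
}

terminal_id <- function(vp) {
  if (!is.null(vp$profile$terminal)) vp$profile$terminal else
    utils::tail(vp$branches$id, 1)
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("Calibration (%s): inlet %.1f/%.1f mmHg (targets %d/%g)\n",
              x$mode, x$result$psys, x$result$pdias,
              as.integer(x$targets$psa_presentation), x$targets$pda))
  cat("Windkessel table:\n")
  print(x$wk3, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write one or two calibrated Windkessel tables as CSV
#'
#' Layout mirrors the standard reporting table: one row per parameter
#' (`R1` proximal, `R2` distal, `C`) and mode, one column per outlet.
#' @param calibs named list of `calibration` objects (names are modes).
#' @param path output path.
#' @export
write_wk3_csv <- function(calibs, path) {
  rows <- do.call(rbind, lapply(names(calibs), function(md) {
    w <- calibs[[md]]$wk3
    out <- as.data.frame(rbind(R1 = w$Rp, R2 = w$Rd, C = w$C))
    names(out) <- w$outlet
    cbind(mode = md, param = rownames(out), out, row.names = NULL)
  }))
  # full binary precision so a re-read table drives an identical simulation
  for (cl in names(rows))
    if (is.numeric(rows[[cl]])) rows[[cl]] <- sprintf("%.17g", rows[[cl]])
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a Windkessel table CSV written by [write_wk3_csv()]
#' @param path CSV path.
#' @param mode which mode block to read (default first present).
#' @return named list of [wk3_params()].
#' @export
read_wk3_csv <- function(path, mode = NULL) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (is.null(mode)) mode <- d$mode[1]
  d <- d[d$mode == mode, ]
  outlets <- setdiff(names(d), c("mode", "param"))
  out <- lapply(outlets, function(o)
    wk3_params(d[d$param == "R1", o], d[d$param == "R2", o],
               d[d$param == "C", o], id = o))
  stats::setNames(out, outlets)
}

#' Write the calibration target report as JSON
#'
#' Mirrors the target column of the clinical comparison table: systolic
#' and diastolic pressure plus per-outlet mean flows, alongside the values
#' the tuned 0D model achieved.
#' @param calib a `calibration`.
#' @param path output path.
#' @export
write_targets_json <- function(calib, path) {
  t <- calib$targets
  jsonlite::write_json(list(
    psys_target_mmhg = t$psa_presentation,
    pdia_target_mmhg = t$pda,
    pmean_mmhg = t$pmean,
    psys_simulated_mmhg = calib$result$psys,
    pdia_simulated_mmhg = calib$result$pdias,
    flow_targets_ml_s = as.list(calib$flow_targets$targets),
    flow_simulated_ml_s = as.list(calib$result$qout_mean),
    mode = calib$mode
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write last-cycle pressure/flow traces as CSV
#' @param res `sim_result_0d`.
#' @param path output path.
#' @export
write_traces_csv <- function(res, path) {
  d <- data.frame(time_s = res$t, p_inlet_mmHg = res$p_inlet)
  for (o in colnames(res$q_out)) d[[paste0("q_", o, "_ml_s")]] <- res$q_out[, o]
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a run configuration
#'
#' Accepts a YAML file path or a list. Recognised fields: `mode`
#' (`compliant`/`rigid`/`both`), `seed`, `tolerance`, `out_dir`,
#' `smoothing_passes`, `boundary_factor`, `round_psa`, `noise`, and either
#' `synthetic: true` (with optional `profile` overrides) or an `inputs`
#' block with `waveform_csv`, `areas_csv`, `geometry_yaml`, `mesh_vtk`.
#' All defaults correspond to the package's standard calibration constants.
#' @param config path or list.
#' @return normalised configuration list.
#' @export
load_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(mode = "both", seed = 1, tolerance = 0.005,
                   out_dir = "aortacal-out", smoothing_passes = 5,
                   boundary_factor = 1e3, round_psa = TRUE, noise = 0,
                   synthetic = TRUE)
  cfg <- utils::modifyList(defaults, config)
  if (!cfg$mode %in% c("compliant", "rigid", "both"))
    stop("mode must be compliant, rigid or both")
  if (cfg$tolerance <= 0) stop("tolerance must be positive")
  if (!isTRUE(cfg$synthetic)) {
    req <- c("waveform_csv", "areas_csv", "geometry_yaml")
    miss <- setdiff(req, names(cfg$inputs))
    if (length(miss)) stop("missing input path(s): ",
                           paste(miss, collapse = ", "))
    for (f in unlist(cfg$inputs)) if (!file.exists(f))
      stop("input file does not exist: ", f)
  }
  cfg
}

#' Assemble a patient bundle from configuration inputs
#' @param cfg normalised configuration from [load_run_config()].
#' @return a `virtual_patient`-structured bundle.
#' @export
load_patient <- function(cfg) {
  if (isTRUE(cfg$synthetic)) {
    profile <- default_patient_profile()
    if (!is.null(cfg$profile)) profile <- utils::modifyList(profile, cfg$profile)
    return(make_virtual_patient(profile, seed = cfg$seed,
                                noise = cfg$noise))
  }
  geom <- yaml::read_yaml(cfg$inputs$geometry_yaml)
  hr <- geom$heart_rate_bpm
  raw <- read_waveform_csv(cfg$inputs$waveform_csv)
  waveform <- resample_inlet_waveform(raw, hr)
  area_waves <- read_area_csv(cfg$inputs$areas_csv)
  segments <- do.call(rbind, lapply(geom$segments, as.data.frame))
  branches <- do.call(rbind, lapply(geom$branches, as.data.frame))
  mesh <- if (!is.null(cfg$inputs$mesh_vtk))
    read_mesh_vtk(cfg$inputs$mesh_vtk) else NULL
  structure(list(
    profile = list(rho = if (is.null(geom$rho)) 1056 else geom$rho,
                   terminal = utils::tail(branches$id, 1)),
    hr = hr, psb = geom$brachial_pressures_mmhg[1],
    pdb = geom$brachial_pressures_mmhg[2],
    waveform = waveform, area_waves = area_waves,
    segments = segments, branches = branches,
    qda = geom$qda_ml_s, mesh = mesh,
    truth = NULL
  ), class = "virtual_patient")
}

#' Run the full calibration workflow and write its artefact bundle
#'
#' Executes targets -> mechanics -> system Windkessel -> network build ->
#' tuning -> stiffness field for the requested mode(s), and writes the
#' Windkessel table, target report, last-cycle traces, stiffness CSV/VTK
#' and a run manifest into `out_dir`. Every tuning iteration is logged with
#' its residuals.
#'
#' @param config configuration path or list, see [load_run_config()].
#' @return invisibly, a named list of `calibration` objects; attribute
#'   `manifest` lists the files written and whether all tolerances were
#'   met.
#' @export
run_calibration <- function(config) {
  cfg <- load_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(cfg$out_dir, "run.log")
  logline <- function(...) {
    msg <- sprintf(...)
    message(msg)
    cat(msg, "\n", file = logfile, append = TRUE, sep = "")
  }
  vp <- load_patient(cfg)
  logline("patient: HR %g bpm, BP %g/%g mmHg, Qmean %.2f ml/s",
          vp$hr, vp$psb, vp$pdb, vp$waveform$qmean)

  modes <- if (cfg$mode == "both") c("compliant", "rigid") else cfg$mode
  calibs <- list()
  ok <- TRUE
  ctot <- NULL
  fixed_c <- NULL
  files <- character(0)
  for (md in modes) {
    cal <- calibrate_patient(vp, mode = md, tol = cfg$tolerance,
                             round_psa = cfg$round_psa,
                             smoothing_passes = cfg$smoothing_passes,
                             boundary_factor = cfg$boundary_factor,
                             ctot = ctot, fixed_c = fixed_c, verbose = TRUE)
    # a subsequent (rigid) run reuses the compliant Ctot and C column
    ctot <- cal$system
    fixed_c <- stats::setNames(cal$wk3$C, cal$wk3$outlet)
    it <- attr(cal$network, "iterations")
    for (i in seq_len(nrow(it)))
      logline("[tune %s] mult %.4f -> %.2f/%.2f mmHg", md, it$mult[i],
              it$psys[i], it$pdias[i])
    logline("[%s] final inlet %.2f/%.2f mmHg, converged: %s", md,
            cal$result$psys, cal$result$pdias,
            attr(cal$network, "converged"))
    ok <- ok && isTRUE(attr(cal$network, "converged"))
    calibs[[md]] <- cal

    f <- file.path(cfg$out_dir, sprintf("traces_%s.csv", md))
    write_traces_csv(cal$result, f); files <- c(files, f)
    f <- file.path(cfg$out_dir, sprintf("targets_%s.json", md))
    write_targets_json(cal, f); files <- c(files, f)
  }

  f <- file.path(cfg$out_dir, "wk3_table.csv")
  write_wk3_csv(calibs, f); files <- c(files, f)

  cal1 <- calibs[[1]]
  if (!is.null(cal1$field)) {
    disp <- displace_nodes(vp$mesh, cal1$field,
                           mmhg_to_pa(cal1$targets$psa_presentation))
    f <- file.path(cfg$out_dir, "stiffness.csv")
    write_field_csv(vp$mesh, cal1$field, f, disp$vectors); files <- c(files, f)
    f <- file.path(cfg$out_dir, "stiffness.vtk")
    write_mesh_vtk(vp$mesh, f, stiffness = cal1$field$K,
                   displacement = disp$vectors); files <- c(files, f)
  }

  manifest <- list(files = files, modes = modes, tolerances_met = ok,
                   seed = cfg$seed)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  attr(calibs, "manifest") <- manifest
  invisible(calibs)
}

#' Re-simulate a calibrated 0D configuration without tuning
#'
#' Reads a Windkessel table, rebuilds the network for the configured
#' patient, solves to periodic convergence and writes traces plus a
#' convergence report. Non-convergence is reported, not an error.
#'
#' @param config configuration path or list.
#' @param wk3_table path to a CSV written by [write_wk3_csv()].
#' @param mode mode block to read from the table.
#' @return the `sim_result_0d`, invisibly.
#' @export
run_simulate0d <- function(config, wk3_table, mode = "compliant") {
  cfg <- load_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  vp <- load_patient(cfg)
  targets <- derive_central_pressures(vp$psb, vp$pdb,
                                      round_psa = cfg$round_psa)
  D_regions <- vapply(vp$area_waves, distensibility_from_area,
                      numeric(1), ppulse = targets$ppulse)
  seg <- vp$segments
  segments <- lapply(seq_len(nrow(seg)), function(i)
    segment_props(seg$id[i], seg$length_m[i], seg$area_m2[i],
                  seg$volume_ml[i], D_mmhg = D_regions[[seg$region[i]]],
                  rho = vp$profile$rho))
  wk3s <- read_wk3_csv(wk3_table, mode = mode)
  sa_ids <- setdiff(vp$branches$id, terminal_id(vp))
  topo <- list(
    attach = stats::setNames(
      vp$branches$attach_to[match(sa_ids, vp$branches$id)], sa_ids),
    terminal = terminal_id(vp))
  net <- build_network(segments, wk3s[vp$branches$id], topo,
                       compliant = mode == "compliant")
  res <- solve_network(net, vp$waveform)
  write_traces_csv(res, file.path(cfg$out_dir,
                                  sprintf("traces_resim_%s.csv", mode)))
  jsonlite::write_json(
    list(converged = res$converged, cycles = res$cycles,
         psys_mmhg = res$psys, pdia_mmhg = res$pdias,
         mass_balance_error = res$mass_balance_error),
    file.path(cfg$out_dir, sprintf("convergence_%s.json", mode)),
    auto_unbox = TRUE, digits = NA)
  invisible(res)
}
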