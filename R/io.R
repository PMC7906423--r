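# Frozen table of the printed model parameters. Every default used across
# the package is asserted against this table in the test suite.
#' Canonical parameter table
#'
#' The frozen set of physical and numerical constants the package defaults
#' to: blood rheology, cardiac-cycle timing, catheter dimensions and
#' operating points, solver steps and thresholds.
#'
#' @return Named list of constants.
#' @export
default_constants <- function() {
  list(
    rho = 1060, mu0 = 0.056, mu_inf = 0.00345, lambda_t = 3.313,
    n_index = 0.3568, mu_newt = 0.004,
    period = 0.8, diastole = 0.5, systole = 0.3,
    venous_flow_mlmin = 400, venous_pressure_mmHg = 248,
    arterial_pressure_mmHg = c(A = -250, B = -250, C = -250, D = -188),
    arterial_flow_mlmin = c(A = 350, B = 380, C = 360, D = 370),
    tip_length_mm = c(A = 290, B = 290, C = 152, D = 240),
    outer_diameter_Fr = c(A = 15.5, B = 15.5, C = 15, D = 16),
    lumen_area_mm2 = c(A = 7.8, B = 7.8, C = 3.5, D = 7.8),
    tip_volume_mm = list(A = c(4.5, 25, 6), B = c(8, 10, 6),
                         C = c(7, 7, 7), D = c(13, 9, 5.5)),
    svc_diameter_mm = 17.06, ivc_diameter_mm = 16.89,
    tv_area_cm2 = 9.95, chamber_volume_ml = 175.27,
    dt_single = 0.005, dt_multiphase = 0.001, residual_tol = 1e-4,
    n_cycles = 4, analysis_cycle = 4,
    tau_threshold_Pa = 10, laminar_threshold = 2300,
    mesh_wss_threshold_pct = 0.5, mesh_probe_threshold_pct = 3,
    fr_to_mm = 0.33, mmHg_to_Pa = 133.322,
    mean_ra_pressure_mmHg = 3)
}

#' Default pipeline configuration
#'
#' Full nested configuration with every key at its default; the physical
#' defaults equal [default_constants()].
#'
#' @return Named list of configuration sections.
#' @export
default_config <- function() {
  k <- default_constants()
  list(
    fluid = list(model = "bird_carreau", rho = k$rho, mu0 = k$mu0,
                 mu_inf = k$mu_inf, lambda_t = k$lambda_t,
                 n_index = k$n_index, mu_newt = k$mu_newt),
    cycle = list(diastole = k$diastole, systole = k$systole),
    waveform = list(mean_mmHg = k$mean_ra_pressure_mmHg, amplitude_mmHg = 2,
                    n_samples = 161, interpolation = "linear",
                    csv = NULL),
    geometry = list(Lx = 0.08, Ly = 0.06, h = 0.002,
                    svc_diameter = 17.06e-3, ivc_diameter = 16.89e-3,
                    tv_area = 9.95e-4, target_volume = 175.27e-6),
    catheter = list(enabled = FALSE, design = "A",
                    tip_position = "position1",
                    venous_flow = k$venous_flow_mlmin,
                    venous_pressure = k$venous_pressure_mmHg),
    solver = list(dt = "auto", n_cycles = k$n_cycles,
                  residual_tol = k$residual_tol, cfl_cap = 0.45,
                  scheme = "van_leer", snapshot_stride = 10,
                  adaptive = TRUE, admittance = 5e-4),
    metrics = list(tau_threshold = k$tau_threshold_Pa,
                   analysis_cycle = k$analysis_cycle),
    output = list(dir = "output"),
    seed = 1,
    log_level = "info")
}

merge_config <- function(defaults, user, path = character(0)) {
  for (nm in names(user)) {
    here <- paste(c(path, nm), collapse = ".")
    if (!nm %in% names(defaults)) {
      stop(sprintf("unknown configuration key '%s'", here), call. = FALSE)
    }
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(user[[nm]])) {
        stop(sprintf("configuration key '%s' must be a section", here),
             call. = FALSE)
      }
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     c(path, nm))
    } else {
      defaults[nm] <- list(user[[nm]])  # keeps explicit NULLs
    }
  }
  defaults
}

validate_config <- function(cfg) {
  with(cfg, {
    if (!fluid$model %in% c("bird_carreau", "newtonian")) {
      stop("fluid.model must be bird_carreau or newtonian", call. = FALSE)
    }
    if (catheter$venous_flow <= 0) {
      stop("catheter.venous_flow must be positive", call. = FALSE)
    }
    if (!(solver$n_cycles >= 1)) stop("solver.n_cycles must be >= 1",
                                      call. = FALSE)
    if (!solver$scheme %in% c("van_leer", "upwind")) {
      stop("solver.scheme must be van_leer or upwind", call. = FALSE)
    }
  })
  invisible(cfg)
}

#' Read a pipeline configuration
#'
#' Parses a YAML configuration file, fills in defaults for anything not
#' given, rejects unknown keys by name and validates the result. The
#' provenance of each top-level section (default vs user-set) is recorded
#' in attribute `"provenance"`.
#'
#' @param path YAML file path; an empty file yields the full default
#'   configuration.
#' @return Named configuration list (class `pipeline_config`).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such config file: %s", path),
                               call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_config(), user)
  validate_config(cfg)
  attr(cfg, "provenance") <- vapply(
    names(cfg), function(nm) if (nm %in% names(user)) "user" else "default",
    character(1))
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname read_config
#' @param cfg a configuration list.
#' @export
write_config <- function(cfg, path) {
  attr(cfg, "provenance") <- NULL
  cfg <- unclass(cfg)
  writeLines(yaml::as.yaml(cfg, precision = 17), path)
  invisible(path)
}

# ---- time-series CSV --------------------------------------------------------

#' Read / write uniformly sampled series as CSV
#'
#' The on-disk layout is one `time` column plus one column per quantity;
#' values survive the round trip to better than 1e-12 relative. Non-uniform
#' time grids are rejected with an explicit message.
#'
#' @param path CSV file.
#' @param T cardiac-cycle length attached to each series [s].
#' @return Named list of [time_series()].
#' @export
read_series_csv <- function(path, T = 0.8) {
  d <- utils::read.csv(path)
  if (!"time" %in% names(d)) {
    stop(sprintf("%s: series CSV needs a 'time' column", path), call. = FALSE)
  }
  qcols <- setdiff(names(d), "time")
  if (!length(qcols)) stop("series CSV has no value columns", call. = FALSE)
  out <- lapply(qcols, function(q) time_series(q, d$time, d[[q]], T))
  names(out) <- qcols
  out
}

#' @rdname read_series_csv
#' @param series a [time_series()] or named list of them on a common grid.
#' @export
write_series_csv <- function(series, path) {
  if (inherits(series, "time_series")) series <- list(series)
  t <- series[[1]]$t
  d <- data.frame(time = t)
  for (s in series) {
    stopifnot(identical(length(s$t), length(t)))
    d[[s$name]] <- s$values
  }
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

# ---- VTK / STL --------------------------------------------------------------

#' Write field snapshots as legacy-ASCII VTK files
#'
#' One structured-points file per snapshot (cell-centre sample points) with
#' pressure, phase fraction and shear rate as scalars and the velocity as a
#' vector field, plus a `manifest.csv` mapping files to times. Files open
#' in standard VTK viewers.
#'
#' @param x a `chamber_run`, a single [field_snapshot()] or a list of them.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the manifest data frame.
#' @export
write_fields_vtk <- function(x, dir, prefix = "field") {
  snaps <- if (inherits(x, "chamber_run")) x$snapshots
  else if (inherits(x, "field_snapshot")) list(x) else x
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(snaps), function(i) {
    s <- snaps[[i]]
    nx <- length(s$x); ny <- length(s$y)
    fn <- file.path(dir, sprintf("%s_%04d.vtk", prefix, i))
    con <- file(fn, "w")
    on.exit(close(con))
    wl <- function(...) writeLines(sprintf(...), con)
    wl("# vtk DataFile Version 3.0")
    wl("atriaflow field snapshot t=%.9g", s$time)
    wl("ASCII")
    wl("DATASET STRUCTURED_POINTS")
    wl("DIMENSIONS %d %d 1", nx, ny)
    wl("ORIGIN %.9g %.9g 0", s$x[1], s$y[1])
    wl("SPACING %.9g %.9g %.9g", s$h, s$h, s$h)
    wl("POINT_DATA %d", nx * ny)
    scalar <- function(name, m) {
      if (is.null(m)) return(invisible())
      wl("SCALARS %s double 1", name)
      wl("LOOKUP_TABLE default")
      writeLines(format(as.vector(m), digits = 12, trim = TRUE,
                        scientific = TRUE), con)
    }
    scalar("pressure", s$p)
    scalar("phase_fraction", s$phi)
    scalar("shear_rate", s$gamma_dot)
    wl("VECTORS velocity double")
    vel <- cbind(as.vector(s$u), as.vector(s$v), 0)
    writeLines(apply(format(vel, digits = 12, trim = TRUE,
                            scientific = TRUE), 1, paste, collapse = " "),
               con)
    data.frame(file = basename(fn), time = s$time)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Summarize an ASCII STL surface mesh
#'
#' Inspection-only reader: triangle count and axis-aligned bounding box.
#'
#' @param path ASCII STL file.
#' @return List with `n_triangles` and `bbox` (2 x 3 matrix, rows min/max).
#' @export
read_stl <- function(path) {
  head <- readBin(path, "raw", n = 6)
  if (!identical(rawToChar(head[1:5]), "solid")) {
    stop(sprintf("%s: not an ASCII STL file (expected leading 'solid')", path),
         call. = FALSE)
  }
  lines <- trimws(readLines(path, warn = FALSE))
  n_tri <- sum(startsWith(lines, "facet normal"))
  vl <- lines[startsWith(lines, "vertex")]
  if (length(vl) != 3L * n_tri) {
    stop(sprintf("%s: malformed STL (%d vertices for %d facets near line %d)",
                 path, length(vl), n_tri,
                 which(startsWith(lines, "vertex"))[length(vl)] %||% 0L),
         call. = FALSE)
  }
  coords <- do.call(rbind, lapply(strsplit(sub("^vertex\\s+", "", vl),
                                           "\\s+"), as.numeric))
  bbox <- rbind(min = apply(coords, 2, min), max = apply(coords, 2, max))
  colnames(bbox) <- c("x", "y", "z")
  list(n_triangles = n_tri, bbox = bbox)
}

# ---- command-line interface -------------------------------------------------

cli_usage <- function() {
  paste(
    "usage: atriaflow <subcommand> [--flag value ...]",
    "subcommands:",
    "  simulate    --config FILE --out DIR",
    "  metrics     --run-dir DIR --out DIR",
    "  validate    --supplementary DIR --out DIR [--cycle-length T]",
    "  convergence --levels FILE --out DIR",
    "  synth       --kind NAME --seed N --out DIR",
    "  report      --metrics FILE --out DIR",
    sep = "\n")
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--") || i == length(args)) {
      stop(sprintf("bad argument '%s'", a), call. = FALSE)
    }
    flags[[sub("^--", "", a)]] <- args[i + 1L]
    i <- i + 2L
  }
  flags
}

cli_simulate <- function(flags) {
  cfg <- read_config(flags$config %||% stop("--config required", call. = FALSE))
  out <- flags$out %||% cfg$output$dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  run <- run_from_config(cfg)
  utils::write.csv(run$monitors, file.path(out, "monitors.csv"),
                   row.names = FALSE)
  write_fields_vtk(run, file.path(out, "fields"))
  if (!is.null(run$arterial_monitor)) {
    am <- run$arterial_monitor
    d <- data.frame(time = am$time)
    for (k in seq_along(am$area)) {
      d[[paste0("phi_", k)]] <- am$phi[, k]
      d[[paste0("un_", k)]] <- am$un[, k]
    }
    utils::write.csv(d, file.path(out, "arterial_monitor.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(facet = seq_along(am$area), area = am$area,
                                T = am$T),
                     file.path(out, "arterial_facets.csv"), row.names = FALSE)
  }
  s <- summary(run)
  utils::write.csv(data.frame(quantity = c("mean_speed", "mean_pressure",
                                           "max_balance", "max_residual"),
                              value = c(s$mean_speed_final_cycle,
                                        s$mean_pressure_final_cycle,
                                        s$max_balance_error,
                                        s$max_residual)),
                   file.path(out, "summary.csv"), row.names = FALSE)
  0L
}

#' Build and run a simulation from a configuration
#'
#' @param cfg a configuration from [read_config()] or [default_config()].
#' @return A `chamber_run`.
#' @export
run_from_config <- function(cfg) {
  props <- fluid_properties(rho = cfg$fluid$rho, mu0 = cfg$fluid$mu0,
                            mu_inf = cfg$fluid$mu_inf,
                            lambda_t = cfg$fluid$lambda_t,
                            n_index = cfg$fluid$n_index,
                            model = cfg$fluid$model,
                            mu_newt = cfg$fluid$mu_newt)
  cyc <- cardiac_cycle(cfg$cycle$diastole, cfg$cycle$systole)
  wf <- if (!is.null(cfg$waveform$csv)) {
    read_waveform_csv(cfg$waveform$csv, cyc,
                      interpolation = cfg$waveform$interpolation)
  } else {
    build_default_waveform(cyc, mean_p = cfg$waveform$mean_mmHg,
                           pulse_amplitude = cfg$waveform$amplitude_mmHg,
                           n_samples = cfg$waveform$n_samples,
                           interpolation = cfg$waveform$interpolation)
  }
  geom <- chamber_geometry(Lx = cfg$geometry$Lx, Ly = cfg$geometry$Ly,
                           h = cfg$geometry$h,
                           svc_diameter = cfg$geometry$svc_diameter,
                           ivc_diameter = cfg$geometry$ivc_diameter,
                           tv_area = cfg$geometry$tv_area,
                           target_volume = cfg$geometry$target_volume)
  cath <- NULL
  if (isTRUE(cfg$catheter$enabled)) {
    cath <- catheter_config(cfg$catheter$design,
                            tip_position = cfg$catheter$tip_position)
  }
  dt <- if (identical(cfg$solver$dt, "auto")) NULL else cfg$solver$dt
  st <- solver_settings(dt = dt, n_cycles = cfg$solver$n_cycles,
                        residual_tol = cfg$solver$residual_tol,
                        cfl_cap = cfg$solver$cfl_cap,
                        scheme = cfg$solver$scheme,
                        snapshot_stride = cfg$solver$snapshot_stride,
                        adaptive = cfg$solver$adaptive,
                        admittance = cfg$solver$admittance,
                        seed = cfg$seed)
  solve_transient(geom, props, wf, cath, st)
}

cli_metrics <- function(flags) {
  rd <- flags$`run-dir` %||% stop("--run-dir required", call. = FALSE)
  out <- flags$out %||% rd
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  mons <- utils::read.csv(file.path(rd, "monitors.csv"))
  res <- list(mean_speed = mean(mons$mean_speed),
              mean_pressure_Pa = mean(mons$mean_p),
              max_balance = max(mons$balance))
  fam <- file.path(rd, "arterial_facets.csv")
  if (file.exists(fam)) {
    fac <- utils::read.csv(fam)
    am <- utils::read.csv(file.path(rd, "arterial_monitor.csv"))
    K <- nrow(fac)
    ps <- patch_series("cath_arterial", am$time,
                       as.matrix(am[paste0("phi_", seq_len(K))]),
                       as.matrix(am[paste0("un_", seq_len(K))]),
                       fac$area, fac$T[1])
    res$Rf <- recirculation_fraction(ps)$Rf
  }
  utils::write.csv(data.frame(quantity = names(res),
                              value = unlist(res)),
                   file.path(out, "metrics.csv"), row.names = FALSE)
  0L
}

cli_validate <- function(flags) {
  sup <- flags$supplementary %||% stop("--supplementary required",
                                       call. = FALSE)
  out <- flags$out %||% "."
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  T <- as.numeric(flags$`cycle-length` %||% 0.8)
  res <- recompute_supplementary(sup, T = T)
  scalars <- res[vapply(res, function(v) is.numeric(v) && length(v) == 1L,
                        logical(1))]
  utils::write.csv(data.frame(quantity = names(scalars),
                              value = unlist(scalars)),
                   file.path(out, "validation.csv"), row.names = FALSE)
  0L
}

cli_convergence <- function(flags) {
  lv <- utils::read.csv(flags$levels %||% stop("--levels required",
                                               call. = FALSE))
  out <- flags$out %||% "."
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  tab <- mesh_convergence(lv)
  utils::write.csv(tab, file.path(out, "mesh_convergence.csv"),
                   row.names = FALSE)
  0L
}

cli_synth <- function(flags) {
  kind <- flags$kind %||% stop("--kind required", call. = FALSE)
  seed <- as.integer(flags$seed %||% 1)
  out <- flags$out %||% "."
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (kind == "waveform") {
    write_waveform_csv(build_default_waveform(),
                       file.path(out, "waveform.csv"))
  } else if (kind == "viscosity_table") {
    utils::write.csv(viscosity_table(), file.path(out, "viscosity_table.csv"),
                     row.names = FALSE)
  } else if (kind == "supplementary") {
    make_supplementary_mock(out, seed = seed)
  } else if (kind == "phase_pattern") {
    ps <- make_phase_pattern(seed = seed)
    d <- data.frame(time = ps$time)
    for (k in seq_along(ps$area)) {
      d[[paste0("phi_", k)]] <- ps$phi[, k]
      d[[paste0("un_", k)]] <- ps$un[, k]
    }
    utils::write.csv(d, file.path(out, "phase_pattern.csv"),
                     row.names = FALSE)
  } else {
    f <- make_field(kind, seed = seed)
    write_fields_vtk(f, out, prefix = kind)
  }
  0L
}

cli_report <- function(flags) {
  mf <- flags$metrics %||% stop("--metrics required", call. = FALSE)
  out <- flags$out %||% "."
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  d <- utils::read.csv(mf)
  if (!"model" %in% names(d)) stop("metrics CSV needs a 'model' column",
                                   call. = FALSE)
  res <- lapply(seq_len(nrow(d)), function(i) as.list(d[i, -1, drop = FALSE]))
  names(res) <- d$model
  rep <- build_report(res)
  utils::write.csv(rep, file.path(out, "report.csv"), row.names = FALSE)
  writeLines(report_markdown(rep), file.path(out, "report.md"))
  0L
}

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands (`simulate`, `metrics`, `validate`,
#' `convergence`, `synth`, `report`). Returns 0 on success, 1 on a runtime
#' failure and 2 on a usage error; a thin Rscript wrapper is installed at
#' `inst/cli/atriaflow`.
#'
#' @param args character vector of command-line arguments.
#' @return Integer exit code, invisibly.
#' @export
af_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    message(cli_usage())
    return(invisible(2L))
  }
  sub <- args[1]
  handlers <- list(simulate = cli_simulate, metrics = cli_metrics,
                   validate = cli_validate, convergence = cli_convergence,
                   synth = cli_synth, report = cli_report)
  if (!sub %in% names(handlers)) {
    message(sprintf("unknown subcommand '%s'\n%s", sub, cli_usage()))
    return(invisible(2L))
  }
  flags <- tryCatch(parse_flags(args[-1]), error = function(e) e)
  if (inherits(flags, "error")) {
    message(conditionMessage(flags), "\n", cli_usage())
    return(invisible(2L))
  }
  code <- tryCatch(handlers[[sub]](flags), error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}
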