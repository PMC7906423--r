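#' Mesh-convergence assessment
#'
#' Relative errors of per-mesh probe velocity and surface-averaged WSS
#' against the finest mesh, \eqn{E = |(v_B - v_L)/v_L| \cdot 100}, with the
#' acceptance thresholds used for chamber meshes: below 0.5 percent for the
#' average WSS and below 3 percent for the probe velocity. The coarsest
#' level meeting both criteria is flagged.
#'
#' @param levels data frame with columns `n_elements` (or `level`),
#'   `probe_velocity` and `avg_wss`, ordered or orderable by refinement;
#'   the finest (largest) level is the reference.
#' @param wss_threshold acceptance threshold for average WSS [%].
#' @param probe_threshold acceptance threshold for probe velocity [%].
#' @return Data frame with per-level errors `E_probe`, `E_wss` and logical
#'   `pass`; attributes `pass_level` (first passing level, NA if none) and
#'   `reference_level`.
#' @export
mesh_convergence <- function(levels, wss_threshold = 0.5,
                             probe_threshold = 3) {
  lv <- if ("n_elements" %in% names(levels)) levels$n_elements else levels$level
  if (is.null(lv)) stop("levels needs an 'n_elements' or 'level' column",
                        call. = FALSE)
  if (!all(c("probe_velocity", "avg_wss") %in% names(levels))) {
    stop("levels needs 'probe_velocity' and 'avg_wss' columns", call. = FALSE)
  }
  if (nrow(levels) < 2L) stop("need at least two mesh levels", call. = FALSE)
  o <- order(lv)
  levels <- levels[o, , drop = FALSE]; lv <- lv[o]
  ref <- nrow(levels)
  if (levels$probe_velocity[ref] == 0 || levels$avg_wss[ref] == 0) {
    stop("reference-level value is zero: relative error undefined",
         call. = FALSE)
  }
  E_probe <- abs((levels$probe_velocity - levels$probe_velocity[ref]) /
                   levels$probe_velocity[ref]) * 100
  E_wss <- abs((levels$avg_wss - levels$avg_wss[ref]) /
                 levels$avg_wss[ref]) * 100
  pass <- E_probe < probe_threshold & E_wss < wss_threshold
  out <- data.frame(level = lv, probe_velocity = levels$probe_velocity,
                    avg_wss = levels$avg_wss, E_probe = E_probe,
                    E_wss = E_wss, pass = pass)
  # exclude the trivially exact reference when picking the pass level
  cand <- which(pass & seq_len(nrow(out)) < ref)
  attr(out, "pass_level") <- if (length(cand)) lv[min(cand)] else
    if (pass[ref]) lv[ref] else NA
  attr(out, "reference_level") <- lv[ref]
  out
}

#' Literature validation bands
#'
#' Default in-vivo/clinical ranges used to validate the chamber model:
#' volume-averaged velocity 0.174 +/- 0.027 m/s, volume-averaged vorticity
#' 37-54 1/s, mean right-atrial pressure 0-5 mmHg.
#'
#' @return Data frame with columns `name`, `low`, `high`, `source`.
#' @export
default_validation_bands <- function() {
  data.frame(
    name = c("velocity", "vorticity", "pressure_mmHg"),
    low = c(0.174 - 0.027, 37, 0),
    high = c(0.174 + 0.027, 54, 5),
    source = c("clinical volume-averaged RA velocity",
               "in vivo RA vorticity",
               "clinical mean RA pressure"),
    stringsAsFactors = FALSE)
}

#' Check metrics against literature bands
#'
#' Reports, for each named metric, whether it lies inside its closed
#' validation interval. Out-of-band values are reported, never raised;
#' metrics without a band (or non-finite values) are listed as unchecked.
#'
#' @param metrics named numeric vector of computed quantities.
#' @param bands data frame as [default_validation_bands()].
#' @return Data frame with columns `name`, `value`, `low`, `high`, `status`
#'   (`"inside"`, `"outside"`, `"unchecked"`).
#' @export
validate_bands <- function(metrics, bands = default_validation_bands()) {
  stopifnot(!is.null(names(metrics)))
  rows <- lapply(names(metrics), function(nm) {
    v <- metrics[[nm]]
    b <- bands[bands$name == nm, , drop = FALSE]
    if (nrow(b) != 1L || !is.finite(v)) {
      if (!is.finite(v)) {
        warning(sprintf("metric '%s' is not finite; left unchecked", nm),
                call. = FALSE)
      }
      return(data.frame(name = nm, value = v, low = NA_real_,
                        high = NA_real_, status = "unchecked"))
    }
    status <- if (v >= b$low && v <= b$high) "inside" else "outside"
    data.frame(name = nm, value = v, low = b$low, high = b$high,
               status = status)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# robust cycle index for a sample time on a uniform grid starting after 0
cycle_index <- function(t, T) ceiling(t / T - 1e-9)

#' Recompute validation statistics from supplementary-schema time series
#'
#' Reads CSV files in the schemas of the published supplementary
#' spreadsheets (or of the mocks written by [make_supplementary_mock()]) and
#' recomputes the summary statistics from them:
#' \itemize{
#'   \item `s9` (columns `time`, `velocity`, `pressure`): per-cycle means
#'     and cycle-to-cycle relative errors against the reference cycle;
#'     reported for the analysis cycle as `velocity_error_pct` and
#'     `pressure_error_pct`, full table as `temporal_errors`.
#'   \item `s10` (columns `boundary`, `time`, `velocity`, `area`): flow-rate
#'     series per boundary and their maxima, `flow_peak_<boundary>` [ml/s].
#'   \item `s11` (columns `time`, `wss`, `vorticity`): Pearson correlation
#'     `pearson_wss_vorticity` and the analysis-cycle time-averaged
#'     vorticity `vorticity_cycle_avg` [1/s].
#'   \item `s12` (columns `time`, `model`, `vorticity`): analysis-cycle
#'     averaged vorticity per model, `vorticity_avg_<model>`.
#'   \item `s13` (columns `time`, `model`, `tau`): time-averaged tip shear
#'     per catheter model, `tip_shear_<model>` [Pa].
#' }
#'
#' @param files named list with any of `s9`, `s10`, `s11`, `s12`, `s13`
#'   CSV paths, or a directory containing files whose names contain those
#'   tags.
#' @param T cardiac-cycle length [s].
#' @param analysis_cycle cycle used for averaged quantities.
#' @param ref_cycle reference cycle for temporal errors; default the
#'   next-to-last cycle present (the published convention), or the last if
#'   only that is available.
#' @param pearson_window `"all"` (full series) or `"cycle"` (analysis cycle
#'   only).
#' @return Named list of recomputed statistics.
#' @export
recompute_supplementary <- function(files, T = 0.8, analysis_cycle = 4,
                                    ref_cycle = NULL,
                                    pearson_window = c("all", "cycle")) {
  pearson_window <- match.arg(pearson_window)
  if (is.character(files) && length(files) == 1L && dir.exists(files)) {
    all <- list.files(files, pattern = "\\.csv$", full.names = TRUE)
    files <- list()
    for (tag in c("s9", "s10", "s11", "s12", "s13")) {
      hit <- grep(paste0("(^|[^0-9a-z])", tag, "([^0-9]|$)"), basename(all),
                  ignore.case = TRUE, value = FALSE)
      if (length(hit)) files[[tag]] <- all[hit[1]]
    }
  }
  need <- function(d, cols, tag) {
    miss <- setdiff(cols, names(d))
    if (length(miss)) {
      stop(sprintf("%s file: missing column(s) %s; expected layout: %s",
                   tag, paste(miss, collapse = ", "),
                   paste(cols, collapse = ", ")), call. = FALSE)
    }
  }
  out <- list()
  if (!is.null(files$s9)) {
    d <- utils::read.csv(files$s9)
    need(d, c("time", "velocity", "pressure"), "s9")
    cyc <- cycle_index(d$time, T)
    agg <- stats::aggregate(d[c("velocity", "pressure")], list(cycle = cyc),
                            mean)
    rc <- ref_cycle %||% if (max(agg$cycle) >= 2) max(agg$cycle) - 1L else
      max(agg$cycle)
    tab <- check_temporal_convergence(agg, ref_cycle = rc)
    out$temporal_errors <- tab
    sel <- function(q) tab$E[tab$cycle == analysis_cycle & tab$quantity == q]
    out$velocity_error_pct <- sel("velocity")
    out$pressure_error_pct <- sel("pressure")
  }
  if (!is.null(files$s10)) {
    d <- utils::read.csv(files$s10)
    need(d, c("boundary", "time", "velocity", "area"), "s10")
    for (b in unique(d$boundary)) {
      db <- d[d$boundary == b, , drop = FALSE]
      q <- boundary_flow_rate(db)
      out[[paste0("flow_peak_", b)]] <- max(q)
    }
  }
  if (!is.null(files$s11)) {
    d <- utils::read.csv(files$s11)
    need(d, c("time", "wss", "vorticity"), "s11")
    keep <- if (pearson_window == "cycle") {
      cycle_index(d$time, T) == analysis_cycle
    } else rep(TRUE, nrow(d))
    out$pearson_wss_vorticity <- pearson_r(d$wss[keep], d$vorticity[keep])
    win <- d$time > (analysis_cycle - 1) * T - 1e-9 &
      d$time <= analysis_cycle * T + 1e-9
    out$vorticity_cycle_avg <-
      trapz_int(d$time[win], d$vorticity[win]) /
      (d$time[win][sum(win)] - d$time[win][1])
    out$wss_cycle_avg <-
      trapz_int(d$time[win], d$wss[win]) /
      (d$time[win][sum(win)] - d$time[win][1])
  }
  if (!is.null(files$s12)) {
    d <- utils::read.csv(files$s12)
    need(d, c("time", "model", "vorticity"), "s12")
    for (m in unique(d$model)) {
      dm <- d[d$model == m, , drop = FALSE]
      win <- dm$time > (analysis_cycle - 1) * T - 1e-9 &
        dm$time <= analysis_cycle * T + 1e-9
      out[[paste0("vorticity_avg_", m)]] <-
        trapz_int(dm$time[win], dm$vorticity[win]) /
        (dm$time[win][sum(win)] - dm$time[win][1])
    }
  }
  if (!is.null(files$s13)) {
    d <- utils::read.csv(files$s13)
    need(d, c("time", "model", "tau"), "s13")
    for (m in unique(d$model)) {
      dm <- d[d$model == m, , drop = FALSE]
      out[[paste0("tip_shear_", m)]] <-
        time_average(dm$tau, t = dm$time, T = T)
    }
  }
  if (!length(out)) stop("no recognised supplementary files supplied",
                         call. = FALSE)
  out
}
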