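#' Cardiac-cycle timing
#'
#' The cycle period is the sum of the diastolic and systolic durations;
#' defaults are a 0.8 s cycle split into 0.5 s diastole and 0.3 s systole.
#'
#' @param diastole diastolic duration [s].
#' @param systole systolic duration [s].
#' @return Object of class `cardiac_cycle` with fields `period`, `diastole`,
#'   `systole`.
#' @export
cardiac_cycle <- function(diastole = 0.5, systole = 0.3) {
  if (!(diastole > 0 && systole > 0)) {
    stop("diastole and systole must be positive", call. = FALSE)
  }
  structure(list(period = diastole + systole, diastole = diastole,
                 systole = systole),
            class = "cardiac_cycle")
}

#' @export
print.cardiac_cycle <- function(x, ...) {
  cat(sprintf("Cardiac cycle: T = %g s (diastole %g s + systole %g s)\n",
              x$period, x$diastole, x$systole))
  invisible(x)
}

MMHG_PA <- 133.322

#' Unit conversions at the config/report boundary
#'
#' Exact linear conversions between the clinical units used at the interface
#' (mmHg, ml/min, French gauge) and SI. 1 mmHg = 133.322 Pa;
#' 1 ml/min = 1e-6/60 m^3/s; 1 Fr = 0.33 mm.
#'
#' @param value numeric value(s), finite.
#' @param kind one of `"mmHg_to_Pa"`, `"Pa_to_mmHg"`, `"mlmin_to_m3s"`,
#'   `"m3s_to_mlmin"`, `"Fr_to_mm"`, `"mm_to_Fr"`.
#' @return Converted value(s).
#' @export
convert_units <- function(value, kind) {
  if (!all(is.finite(value))) stop("value must be finite", call. = FALSE)
  switch(kind,
    mmHg_to_Pa   = value * MMHG_PA,
    Pa_to_mmHg   = value / MMHG_PA,
    mlmin_to_m3s = value * 1e-6 / 60,
    m3s_to_mlmin = value * 60 / 1e-6,
    Fr_to_mm     = value * 0.33,
    mm_to_Fr     = value / 0.33,
    stop(sprintf("unknown conversion kind '%s'", kind), call. = FALSE)
  )
}

#' Catheter operating point
#'
#' Lumen flow and gauge pressures of a dialysis catheter. The venous lumen
#' returns filtered blood at a prescribed flow rate (default 400 ml/min, the
#' clinical maximum) under a positive pump pressure (default 248 mmHg); the
#' arterial lumen draws blood under negative gauge pressure. In reverse mode
#' the venous and arterial lumens swap roles.
#'
#' @param venous_flow venous lumen flow rate [ml/min].
#' @param venous_gauge_pressure venous-side gauge pressure [mmHg].
#' @param arterial_gauge_pressure arterial-side gauge pressure [mmHg]
#'   (negative).
#' @param arterial_flow arterial lumen flow rate achieved at that pressure
#'   [ml/min].
#' @param mode `"standard"` or `"reverse"`.
#' @return Object of class `catheter_operating_point`.
#' @export
catheter_operating_point <- function(venous_flow = 400,
                                     venous_gauge_pressure = 248,
                                     arterial_gauge_pressure = -250,
                                     arterial_flow = 350,
                                     mode = c("standard", "reverse")) {
  mode <- match.arg(mode)
  if (!(venous_flow > 0)) stop("venous_flow must be positive", call. = FALSE)
  if (!(arterial_flow > 0)) stop("arterial_flow must be positive", call. = FALSE)
  if (!(arterial_gauge_pressure < venous_gauge_pressure)) {
    stop("arterial gauge pressure must be below venous gauge pressure",
         call. = FALSE)
  }
  structure(list(venous_flow = venous_flow,
                 venous_gauge_pressure = venous_gauge_pressure,
                 arterial_gauge_pressure = arterial_gauge_pressure,
                 arterial_flow = arterial_flow,
                 mode = mode),
            class = "catheter_operating_point")
}

#' Construct an inlet pressure waveform from samples
#'
#' An inlet waveform is a periodic pressure signal sampled on a uniform time
#' grid covering one cardiac cycle (first and last samples coincide).
#'
#' @param cycle a [cardiac_cycle()].
#' @param t uniform time grid [s] from 0 to `cycle$period` inclusive.
#' @param p pressure samples [Pa] with `p[1] == p[length(p)]` (to tolerance).
#' @param interpolation `"linear"` or `"periodic_spline"`.
#' @param mean_band allowed band for the time-average gauge pressure [mmHg];
#'   default `c(0, 5)`, the physiological right-atrial range.
#' @return Object of class `inlet_waveform`.
#' @export
inlet_waveform <- function(cycle, t, p,
                           interpolation = c("linear", "periodic_spline"),
                           mean_band = c(0, 5)) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(cycle, "cardiac_cycle"), length(t) == length(p),
            length(t) >= 3L)
  dt <- diff(t)
  if (max(abs(dt - dt[1])) > 1e-9 * max(abs(dt))) {
    stop("time grid must be uniform", call. = FALSE)
  }
  if (abs(t[1]) > 1e-12 || abs(t[length(t)] - cycle$period) > 1e-9) {
    stop("time grid must span exactly [0, period]", call. = FALSE)
  }
  scale <- max(abs(p), 1)
  if (abs(p[1] - p[length(p)]) > 1e-9 * scale) {
    stop("waveform must be periodic: first and last samples differ",
         call. = FALSE)
  }
  mean_p <- trapz_mean(t, p) / MMHG_PA
  if (mean_p < mean_band[1] - 1e-9 || mean_p > mean_band[2] + 1e-9) {
    stop(sprintf(
      "mean gauge pressure %.3g mmHg outside physiological band [%g, %g] mmHg",
      mean_p, mean_band[1], mean_band[2]), call. = FALSE)
  }
  structure(list(cycle = cycle, t = t, p = p, interpolation = interpolation),
            class = "inlet_waveform")
}

#' @export
print.inlet_waveform <- function(x, ...) {
  cat(sprintf(
    "Inlet waveform: T = %g s, %d samples, mean %.3g mmHg, range [%.3g, %.3g] mmHg (%s)\n",
    x$cycle$period, length(x$t), trapz_mean(x$t, x$p) / MMHG_PA,
    min(x$p) / MMHG_PA, max(x$p) / MMHG_PA, x$interpolation))
  invisible(x)
}

#' @export
plot.inlet_waveform <- function(x, n = 400, ...) {
  tt <- seq(0, x$cycle$period, length.out = n)
  graphics::plot(tt, sample_waveform(x, tt) / MMHG_PA, type = "l",
                 xlab = "time [s]", ylab = "pressure [mmHg]",
                 main = "Inlet pressure waveform", ...)
  graphics::abline(v = x$cycle$diastole, lty = 2, col = "grey40")
  invisible(x)
}

# trapezoidal mean over a (uniform or not) grid
trapz_mean <- function(t, y) {
  trapz_int(t, y) / (t[length(t)] - t[1])
}

trapz_int <- function(t, y) {
  n <- length(t)
  sum((y[-1] + y[-n]) * diff(t)) / 2
}

#' Sample an inlet waveform at arbitrary times
#'
#' Periodic evaluation: `t` is reduced modulo the cycle period and the
#' configured interpolation (piecewise linear or periodic cubic spline) is
#' applied; values at grid points are exact.
#'
#' @param w an [inlet_waveform()].
#' @param t time(s) [s], non-negative; vectorized.
#' @return Pressure(s) [Pa].
#' @export
sample_waveform <- function(w, t) {
  stopifnot(inherits(w, "inlet_waveform"))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  tm <- t %% w$cycle$period
  if (w$interpolation == "linear") {
    stats::approx(w$t, w$p, xout = tm, rule = 2)$y
  } else {
    f <- stats::splinefun(w$t, w$p, method = "periodic")
    f(tm)
  }
}

#' Build the default two-peaked venous inlet waveform
#'
#' Parametric venous pressure waveform with the classic a- and v-wave
#' morphology: one pressure peak late in diastole (atrial contraction) and
#' one during ventricular systole, superposed on a physiological mean. The
#' shape is two raised-cosine bumps recentred to zero mean, so the
#' time-average of the output equals `mean_p` up to interpolation error
#' (well within 1 percent).
#'
#' @param cycle a [cardiac_cycle()] (default 0.8 s = 0.5 s + 0.3 s).
#' @param mean_p mean gauge pressure [mmHg], default 3 (normal right-atrial
#'   mean).
#' @param pulse_amplitude peak deviation from the mean [mmHg], default 2.
#' @param n_samples grid size over one period.
#' @param a_peak,v_peak peak centres as fractions of the period; the a-wave
#'   defaults to late diastole, the v-wave to mid systole.
#' @param a_width,v_width bump half-widths as fractions of the period.
#' @param v_rel relative height of the v-wave versus the a-wave.
#' @param interpolation passed to [inlet_waveform()].
#' @param mean_band physiological band for the mean [mmHg].
#' @return An [inlet_waveform()] whose measured period equals `cycle$period`
#'   and whose time average equals `mean_p` within 1 percent.
#' @export
build_default_waveform <- function(cycle = cardiac_cycle(),
                                   mean_p = 3, pulse_amplitude = 2,
                                   n_samples = 161,
                                   a_peak = 0.55, v_peak = 0.81,
                                   a_width = 0.18, v_width = 0.14,
                                   v_rel = 0.8,
                                   interpolation = "linear",
                                   mean_band = c(0, 5)) {
  if (pulse_amplitude < 0) stop("pulse_amplitude must be >= 0", call. = FALSE)
  if (mean_p < mean_band[1] || mean_p > mean_band[2]) {
    stop(sprintf("mean_p %.3g mmHg outside band [%g, %g] mmHg",
                 mean_p, mean_band[1], mean_band[2]), call. = FALSE)
  }
  t <- seq(0, cycle$period, length.out = n_samples)
  x <- t / cycle$period
  bump <- function(x, c0, w) {
    # periodic raised cosine centred at c0 with half-width w
    d <- (x - c0) %% 1
    d <- pmin(d, 1 - d)
    ifelse(d < w, 0.5 * (1 + cos(pi * d / w)), 0)
  }
  s <- bump(x, a_peak, a_width) + v_rel * bump(x, v_peak, v_width)
  s[n_samples] <- s[1]                       # enforce exact periodicity
  s <- s - trapz_mean(t, s)                  # zero time mean
  if (max(abs(s)) > 0) s <- s / max(abs(s))  # unit peak deviation
  p <- (mean_p + pulse_amplitude * s) * MMHG_PA
  # an amplitude large enough to produce a negative *absolute* pressure is
  # unphysical (atmosphere ~ 760 mmHg)
  if (min(p) < -760 * MMHG_PA) {
    stop("pulse_amplitude produces negative absolute pressure", call. = FALSE)
  }
  inlet_waveform(cycle, t, p, interpolation = interpolation,
                 mean_band = mean_band)
}

#' Read / write a sampled waveform as CSV
#'
#' Two columns, `time` and `pressure`; the pressure unit is declared in the
#' header as `pressure_mmHg` or `pressure_Pa`.
#'
#' @param path CSV file path.
#' @param cycle a [cardiac_cycle()] giving the expected period.
#' @param ... passed to [inlet_waveform()].
#' @return An [inlet_waveform()].
#' @export
read_waveform_csv <- function(path, cycle = cardiac_cycle(), ...) {
  d <- utils::read.csv(path)
  if (!("time" %in% names(d))) {
    stop("waveform CSV must have a 'time' column", call. = FALSE)
  }
  pcol <- intersect(c("pressure_Pa", "pressure_mmHg"), names(d))
  if (length(pcol) != 1L) {
    stop("waveform CSV must have exactly one of 'pressure_Pa' or 'pressure_mmHg'",
         call. = FALSE)
  }
  p <- d[[pcol]]
  if (pcol == "pressure_mmHg") p <- convert_units(p, "mmHg_to_Pa")
  inlet_waveform(cycle, d$time, p, ...)
}

#' @rdname read_waveform_csv
#' @param w an [inlet_waveform()] to write.
#' @param unit `"mmHg"` or `"Pa"`.
#' @export
write_waveform_csv <- function(w, path, unit = c("mmHg", "Pa")) {
  unit <- match.arg(unit)
  p <- if (unit == "mmHg") w$p / MMHG_PA else w$p
  d <- data.frame(time = w$t, p = p)
  names(d)[2] <- paste0("pressure_", unit)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
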