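# finite differences: central interior, second-order one-sided at the edges
fd_axis <- function(f, h, axis = 1) {
  f <- as.array(f); d <- dim(f); K <- length(d)
  if (d[axis] < 3L) stop("grid too small for the derivative stencil", call. = FALSE)
  perm <- c(axis, setdiff(seq_len(K), axis))
  g <- aperm(f, perm)
  dims_p <- dim(g)
  dim(g) <- c(d[axis], prod(d[-axis]))
  n <- nrow(g)
  out <- g
  out[2:(n - 1), ] <- (g[3:n, , drop = FALSE] - g[1:(n - 2), , drop = FALSE]) / (2 * h)
  out[1, ] <- (-3 * g[1, ] + 4 * g[2, ] - g[3, ]) / (2 * h)
  out[n, ] <- (3 * g[n, ] - 4 * g[n - 1, ] + g[n - 2, ]) / (2 * h)
  dim(out) <- dims_p
  aperm(out, order(perm))
}

d_dx_centered <- function(f, h) fd_axis(f, h, 1)
d_dy_centered <- function(f, h) fd_axis(f, h, 2)
d_dz_centered <- function(f, h) fd_axis(f, h, 3)

is_3d_field <- function(field) !is.null(field$w)

#' Vorticity of a velocity field
#'
#' Discrete curl of the velocity field by central differences (second-order
#' one-sided at the edges). For a planar 2D field only the out-of-plane
#' component \eqn{\omega_z = \partial v/\partial x - \partial u/\partial y}
#' is non-zero.
#'
#' @param field a [field_snapshot()].
#' @return Object of class `vorticity_field`: components (`wz` for 2D;
#'   `wx`, `wy`, `wz` for 3D) and `magnitude`.
#' @export
vorticity <- function(field) {
  stopifnot(inherits(field, "field_snapshot"))
  h <- field$h
  if (is_3d_field(field)) {
    wx <- d_dy_centered(field$w, h) - d_dz_centered(field$v, h)
    wy <- d_dz_centered(field$u, h) - d_dx_centered(field$w, h)
    wz <- d_dx_centered(field$v, h) - d_dy_centered(field$u, h)
    out <- list(wx = wx, wy = wy, wz = wz,
                magnitude = sqrt(wx^2 + wy^2 + wz^2))
  } else {
    wz <- d_dx_centered(field$v, h) - d_dy_centered(field$u, h)
    out <- list(wx = NULL, wy = NULL, wz = wz, magnitude = abs(wz))
  }
  class(out) <- "vorticity_field"
  out
}

#' Kinetic helicity density
#'
#' The scalar product of velocity and vorticity, \eqn{u \cdot \omega},
#' distinguishing helical from purely vortical flow. Identically zero for
#' any planar 2D field (the vorticity is perpendicular to the plane).
#'
#' @param field a [field_snapshot()].
#' @return Array of helicity density values [m/s^2].
#' @export
helicity_density <- function(field) {
  stopifnot(inherits(field, "field_snapshot"))
  if (!is_3d_field(field)) {
    return(array(0, dim(as.array(field$u))))
  }
  om <- vorticity(field)
  field$u * om$wx + field$v * om$wy + field$w * om$wz
}

#' Strain-rate tensor, its magnitude and the shear stress
#'
#' Computes the symmetric strain-rate tensor
#' \eqn{\epsilon_{ij} = (\partial u_j/\partial x_i + \partial u_i/\partial x_j)/2},
#' its magnitude \eqn{|\epsilon| = \sqrt{2\,\epsilon_{ij}\epsilon_{ij}}}
#' (summed over the full tensor), and the generalized-Newtonian shear stress
#' \eqn{\tau = \mu(\dot\gamma)\,|\epsilon|} with the shear rate identified
#' with \eqn{|\epsilon|}. For simple shear with rate \eqn{\dot\gamma_0} this
#' reduces to the 1-D law \eqn{|\epsilon| = \dot\gamma_0},
#' \eqn{\tau = \mu(\dot\gamma_0)\dot\gamma_0}.
#'
#' @param field a [field_snapshot()].
#' @param props a [fluid_properties()].
#' @return Object of class `shear_fields`: tensor components, `magnitude`
#'   [1/s] and `tau` [Pa].
#' @export
strain_and_stress <- function(field, props = fluid_properties()) {
  stopifnot(inherits(field, "field_snapshot"))
  h <- field$h
  e11 <- d_dx_centered(field$u, h)
  e22 <- d_dy_centered(field$v, h)
  e12 <- 0.5 * (d_dy_centered(field$u, h) + d_dx_centered(field$v, h))
  if (is_3d_field(field)) {
    e33 <- d_dz_centered(field$w, h)
    e13 <- 0.5 * (d_dz_centered(field$u, h) + d_dx_centered(field$w, h))
    e23 <- 0.5 * (d_dz_centered(field$v, h) + d_dy_centered(field$w, h))
    mag <- sqrt(2 * (e11^2 + e22^2 + e33^2 + 2 * (e12^2 + e13^2 + e23^2)))
    out <- list(e11 = e11, e22 = e22, e33 = e33,
                e12 = e12, e13 = e13, e23 = e23)
  } else {
    mag <- sqrt(2 * (e11^2 + e22^2 + 2 * e12^2))
    out <- list(e11 = e11, e22 = e22, e12 = e12)
  }
  out$magnitude <- mag
  out$tau <- apparent_viscosity(mag, props) * mag
  class(out) <- "shear_fields"
  out
}

#' Wall shear stress along one wall
#'
#' One-sided second-order estimate of the wall-normal gradient of the
#' tangential velocity at a no-slip wall, using the first two cell layers
#' and the zero wall value: \eqn{u'(0) = (9u_1 - u_2)/(3h)} with \eqn{u_1}
#' at distance \eqn{h/2} and \eqn{u_2} at \eqn{3h/2}. The WSS is
#' \eqn{\tau_w = \mu(\dot\gamma_w)\,\dot\gamma_w} with
#' \eqn{\dot\gamma_w = |u'(0)|}, so it is exact for a parabolic (Poiseuille)
#' profile and doubles when a fixed Newtonian field's viscosity doubles.
#'
#' @param field a 2D [field_snapshot()].
#' @param wall `"ymin"`, `"ymax"`, `"xmin"` or `"xmax"`.
#' @param props a [fluid_properties()].
#' @param exclude optional indices of wall faces to drop from the spatial
#'   average (e.g. port faces that are not true wall).
#' @return List with `tau` (WSS along the wall [Pa]), `shear_rate` [1/s] and
#'   `average` (spatial mean [Pa]).
#' @export
wall_shear_stress <- function(field, wall = c("ymin", "ymax", "xmin", "xmax"),
                              props = fluid_properties(), exclude = NULL) {
  stopifnot(inherits(field, "field_snapshot"))
  wall <- match.arg(wall)
  if (is_3d_field(field)) {
    stop("wall_shear_stress expects a 2D snapshot", call. = FALSE)
  }
  h <- field$h
  u <- field$u; v <- field$v
  nx <- nrow(u); ny <- ncol(u)
  if ((wall %in% c("ymin", "ymax") && ny < 2) ||
      (wall %in% c("xmin", "xmax") && nx < 2)) {
    stop("need at least two interior cells normal to the wall", call. = FALSE)
  }
  g <- switch(wall,
    ymin = (9 * u[, 1] - u[, 2]) / (3 * h),
    ymax = (9 * u[, ny] - u[, ny - 1]) / (3 * h),
    xmin = (9 * v[1, ] - v[2, ]) / (3 * h),
    xmax = (9 * v[nx, ] - v[nx - 1, ]) / (3 * h))
  gw <- abs(g)
  tau <- apparent_viscosity(gw, props) * gw
  keep <- setdiff(seq_along(tau), exclude)
  list(tau = tau, shear_rate = gw, average = mean(tau[keep]))
}

#' Flow rate through a boundary
#'
#' Sum of facet fluxes \eqn{Q = \sum_k u_k \cdot A_k}, signed by the outward
#' normal convention (positive = outflow), reported in ml/s. Accepts either
#' a velocity-area series table (columns `velocity` [m/s] and `area` [m^2]),
#' or a [field_snapshot()] together with the geometry and a patch name (the
#' facet velocity is taken from the wall-adjacent cells).
#'
#' @param x a data frame or a [field_snapshot()].
#' @param geom a [chamber_geometry()] (snapshot method).
#' @param patch patch name (snapshot method).
#' @param ... unused.
#' @return Flow rate(s) [ml/s].
#' @export
boundary_flow_rate <- function(x, ...) UseMethod("boundary_flow_rate")

#' @rdname boundary_flow_rate
#' @export
boundary_flow_rate.data.frame <- function(x, ...) {
  if (!all(c("velocity", "area") %in% names(x))) {
    stop("series table needs 'velocity' and 'area' columns", call. = FALSE)
  }
  if (nrow(x) == 0L) stop("empty boundary series", call. = FALSE)
  x$velocity * x$area * 1e6
}

#' @rdname boundary_flow_rate
#' @export
boundary_flow_rate.field_snapshot <- function(x, geom, patch, ...) {
  p <- geom$patches[[patch]]
  if (is.null(p)) stop(sprintf("no patch named '%s'", patch), call. = FALSE)
  if (length(p$faces) == 0L) stop("patch has no facets", call. = FALSE)
  nx <- geom$nx; ny <- geom$ny
  un <- switch(p$side,              # outward-positive normal velocity
    xmin = -x$u[1, p$faces],
    xmax = x$u[nx, p$faces],
    ymin = -x$v[p$faces, 1],
    ymax = x$v[p$faces, ny])
  sum(un * geom$h * p$depth) * 1e6
}

#' Uniformly sampled named time series
#'
#' @param name quantity label.
#' @param t strictly increasing uniform time grid [s].
#' @param values samples.
#' @param T cardiac-cycle length [s].
#' @return Object of class `time_series`.
#' @export
time_series <- function(name, t, values, T) {
  stopifnot(length(t) == length(values), length(t) >= 2L)
  dt <- diff(t)
  if (any(dt <= 0)) stop("time grid must be strictly increasing", call. = FALSE)
  if (max(abs(dt - dt[1])) > 1e-9 * abs(dt[1])) {
    stop("time grid must be uniform (1e-9 relative)", call. = FALSE)
  }
  structure(list(name = name, t = t, values = values, T = T),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("Time series '%s': %d samples, t in [%g, %g] s, cycle T = %g s\n",
              x$name, length(x$t), x$t[1], x$t[length(x$t)], x$T))
  invisible(x)
}

#' Trapezoidal time average over one cardiac cycle
#'
#' Integrates the series with the trapezoid rule over exactly one cycle
#' length `T` and divides by `T`. If the series spans more than one cycle
#' the last full cycle is used (the analysis cycle); a constant series
#' averages to that constant exactly.
#'
#' @param x a [time_series()], or a numeric vector of values (then `t` must
#'   be given).
#' @param t time grid when `x` is a plain vector.
#' @param T cycle length; defaults to the series' own `T`.
#' @return Scalar time average.
#' @export
time_average <- function(x, t = NULL, T = NULL) {
  if (inherits(x, "time_series")) {
    t <- x$t; T <- T %||% x$T; x <- x$values
  }
  stopifnot(length(t) == length(x))
  T <- T %||% (t[length(t)] - t[1])
  span <- t[length(t)] - t[1]
  if (span < T - 1e-9) {
    stop("series shorter than one cycle", call. = FALSE)
  }
  keep <- t >= t[length(t)] - T - 1e-9
  tt <- t[keep]; yy <- x[keep]
  trapz_int(tt, yy) / (tt[length(tt)] - tt[1])
}

#' Volume average of a cell field
#'
#' Cell-volume-weighted mean; on the uniform grids used here this is the
#' plain mean over cells.
#'
#' @param x numeric array (or [field_snapshot()] plus `what`).
#' @param what field name when `x` is a snapshot (e.g. `"p"`).
#' @return Scalar.
#' @export
volume_average <- function(x, what = NULL) {
  if (inherits(x, "field_snapshot")) x <- x[[what]]
  mean(x)
}

#' Pearson correlation of two aligned series
#'
#' Sample Pearson correlation coefficient; errors on zero-variance input
#' (where the coefficient is undefined) rather than returning NA.
#'
#' @param a,b numeric vectors on a common grid (or [time_series()]).
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(a, b) {
  if (inherits(a, "time_series")) a <- a$values
  if (inherits(b, "time_series")) b <- b$values
  if (length(a) != length(b)) stop("series not aligned", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("Pearson correlation undefined for a zero-variance series",
         call. = FALSE)
  }
  stats::cor(a, b)
}

#' Signed percent change against a reference
#'
#' \eqn{(value - reference)/|reference| \cdot 100}.
#'
#' @param value new value.
#' @param reference baseline value, non-zero.
#' @return Percent change (signed).
#' @export
percent_change <- function(value, reference) {
  if (any(reference == 0)) {
    stop("percent change undefined for a zero reference", call. = FALSE)
  }
  (value - reference) / abs(reference) * 100
}

#' Mass-weighted recirculation fraction at the catheter intake
#'
#' Implements the recirculation measure: per facet the time-averaged
#' filtered-blood fraction \eqn{\bar\phi_k = \frac{1}{T}\int_0^T \phi_r\,dt}
#' (trapezoid rule over the last full cycle), per facet the time-averaged
#' mass flow \eqn{\dot m_k = \rho\,(u_k \cdot A_k)}, and the mass-weighted
#' average \eqn{R_f = \frac{1}{\dot m_T}\sum_k \bar\phi_k \dot m_k}
#' expressed in percent.
#'
#' @param ps a `patch_series` facet monitor (from [solve_transient()], field
#'   `arterial_monitor`) or a list with elements `time`, `phi` (time x facet
#'   matrix), `un` (outward normal velocity, same shape), `area` (facet
#'   areas) and `T` (cycle length).
#' @param rho blood density [kg/m^3].
#' @return Object of class `recirc_result`: `Rf` [%], `phi_bar_k`,
#'   `mdot_k` [kg/s], `mdot_T` [kg/s].
#' @export
recirculation_fraction <- function(ps, rho = 1060) {
  t <- ps$time
  T <- ps$T
  span <- t[length(t)] - t[1]
  if (span < T - 1e-9) stop("monitor spans less than one cycle", call. = FALSE)
  keep <- which(t >= t[length(t)] - T - 1e-9)
  tt <- t[keep]
  dur <- tt[length(tt)] - tt[1]
  phi_bar <- apply(ps$phi[keep, , drop = FALSE], 2,
                   function(y) trapz_int(tt, y) / dur)
  un_bar <- apply(ps$un[keep, , drop = FALSE], 2,
                  function(y) trapz_int(tt, y) / dur)
  mdot_k <- rho * un_bar * ps$area
  mdot_T <- sum(mdot_k)
  if (mdot_T == 0) {
    stop("total patch mass flow is zero: recirculation fraction undefined",
         call. = FALSE)
  }
  Rf <- sum(phi_bar * mdot_k) / mdot_T * 100
  structure(list(Rf = Rf, phi_bar_k = phi_bar, mdot_k = mdot_k,
                 mdot_T = mdot_T),
            class = "recirc_result")
}

#' @export
print.recirc_result <- function(x, ...) {
  cat(sprintf("Recirculation fraction Rf = %.4g %% (%d facets, mdot_T = %.4g kg/s)\n",
              x$Rf, length(x$mdot_k), x$mdot_T))
  invisible(x)
}

#' Shear-stress statistics in the tip sampling volume
#'
#' Cell-volume-weighted average shear stress
#' \eqn{\bar\tau = \frac{1}{V}\int_{tip} \tau\, dV} inside the rectangular
#' tip prism, and the percentage of the prism volume where \eqn{\tau} meets
#' the platelet-activation threshold (default 10 Pa, compared with >=), per
#' snapshot and time-averaged over the analysis cycle.
#'
#' @param x a `chamber_run` or a list of [field_snapshot()]s covering one
#'   cycle.
#' @param tip a [tip_volume()]; defaults to the run's catheter tip prism.
#' @param props a [fluid_properties()]; defaults to the run's.
#' @param anchor tip-prism anchor `c(x_centre, y_top)` [m]; defaults to the
#'   catheter venous port centre on the top wall.
#' @param threshold shear-stress threshold [Pa].
#' @param T cycle length for the time average; defaults to the run period.
#' @return List: `series` (data frame time, `tau_bar`, `frac_above`),
#'   `tau_bar_avg` [Pa], `frac_above_avg` [%], `n_cells`, `threshold`.
#' @export
tip_statistics <- function(x, tip = NULL, props = NULL, anchor = NULL,
                           threshold = 10, T = NULL) {
  if (inherits(x, "chamber_run")) {
    geom <- x$geometry
    tip <- tip %||% geom$catheter$tip
    props <- props %||% x$props
    T <- T %||% x$period
    if (is.null(anchor)) {
      p <- geom$patches[["cath_venous"]]
      if (is.null(p)) stop("run has no catheter venous patch", call. = FALSE)
      anchor <- c(mean((p$faces - 0.5) * geom$h), geom$Ly)
    }
    snaps <- x$snapshots
  } else {
    snaps <- x
    if (is.null(tip) || is.null(anchor)) {
      stop("supply tip and anchor for plain snapshot lists", call. = FALSE)
    }
    props <- props %||% fluid_properties()
  }
  if (length(snaps) < 2L) stop("need at least two snapshots", call. = FALSE)
  wx <- tip$width * 1e-3; lx <- tip$length * 1e-3
  s1 <- snaps[[1]]
  in_x <- s1$x >= anchor[1] - wx / 2 & s1$x <= anchor[1] + wx / 2
  in_y <- s1$y >= anchor[2] - lx & s1$y <= anchor[2]
  if (!any(in_x) || !any(in_y)) {
    stop("tip volume lies outside the grid", call. = FALSE)
  }
  rows <- lapply(snaps, function(s) {
    tau <- if (!is.null(s$gamma_dot)) {
      apparent_viscosity(s$gamma_dot, props) * s$gamma_dot
    } else {
      strain_and_stress(s, props)$tau
    }
    tcell <- tau[in_x, in_y, drop = FALSE]
    c(time = s$time, tau_bar = mean(tcell),
      frac_above = mean(tcell >= threshold) * 100)
  })
  ser <- as.data.frame(do.call(rbind, rows))
  T <- T %||% (ser$time[nrow(ser)] - ser$time[1])
  list(series = ser,
       tau_bar_avg = time_average(ser$tau_bar, t = ser$time, T = T),
       frac_above_avg = time_average(ser$frac_above, t = ser$time, T = T),
       n_cells = sum(in_x) * sum(in_y), threshold = threshold)
}

#' Assemble the per-model haemodynamic report
#'
#' One row per model with the comparison quantities: recirculation fraction
#' [%], time-and-volume-averaged vorticity [1/s], time-averaged WSS [Pa],
#' time-averaged tip shear stress [Pa] and the tip-volume percentage at or
#' above the shear threshold. Metrics a model does not define (e.g. Rf for
#' the catheter-free chamber) are carried as NA and rendered as "-".
#'
#' @param results named list (one element per model) of named lists/vectors
#'   with any of `Rf`, `vorticity`, `wss`, `tip_shear`, `tip_volume_pct`.
#' @return Data frame of class `metrics_report`, rows in input order.
#' @export
build_report <- function(results) {
  cols <- c("Rf", "vorticity", "wss", "tip_shear", "tip_volume_pct")
  if (length(results) == 0L) {
    out <- as.data.frame(stats::setNames(
      c(list(character(0)), replicate(length(cols), numeric(0), simplify = FALSE)),
      c("model", cols)))
    class(out) <- c("metrics_report", "data.frame")
    return(out)
  }
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    vals <- vapply(cols, function(cn) {
      v <- r[[cn]]
      if (is.null(v) || length(v) == 0L) NA_real_ else as.numeric(v)
    }, numeric(1))
    data.frame(model = nm, t(vals), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("metrics_report", "data.frame")
  out
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  labs <- c(model = "Model", Rf = "Rf [%]", vorticity = "omega [1/s]",
            wss = "WSS [Pa]", tip_shear = "tau_tip [Pa]",
            tip_volume_pct = "V(tau>=thr) [%]")
  cat("Haemodynamic report (time-averaged over the analysis cycle)\n")
  fmt <- function(v) {
    if (is.numeric(v)) ifelse(is.na(v), "-", format(signif(v, digits))) else v
  }
  d <- as.data.frame(lapply(x, fmt), stringsAsFactors = FALSE)
  names(d) <- labs[names(x)]
  print(d, row.names = FALSE)
  invisible(x)
}

#' Render the report as a markdown table
#'
#' @param x a `metrics_report`.
#' @param digits significant digits.
#' @return Character vector of markdown lines.
#' @export
report_markdown <- function(x, digits = 4) {
  hdr <- c("Model", "Rf [%]", "omega [1/s]", "WSS [Pa]", "tau_tip [Pa]",
           "V(tau>=thr) [%]")
  fmt <- function(v) if (is.na(v)) "-" else format(signif(v, digits))
  lines <- c(paste0("| ", paste(hdr, collapse = " | "), " |"),
             paste0("|", paste(rep("---", length(hdr)), collapse = "|"), "|"))
  for (i in seq_len(nrow(x))) {
    cells <- c(x$model[i], vapply(
      c("Rf", "vorticity", "wss", "tip_shear", "tip_volume_pct"),
      function(cn) fmt(x[[cn]][i]), character(1)))
    lines <- c(lines, paste0("| ", paste(cells, collapse = " | "), " |"))
  }
  lines
}
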