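# cell-centre coordinate helpers for generated fields
cell_centres <- function(n, L) (seq_len(n) - 0.5) * (L / n)

#' Generate an analytic velocity field with known ground truth
#'
#' Seeded generators for every field class the metric operators consume,
#' each sampled at cell centres of a uniform grid and carrying its analytic
#' ground truth as attribute `"ground_truth"`:
#' \describe{
#'   \item{`poiseuille`}{plane channel profile
#'     \eqn{u = 4 U_{max} y (H - y)/H^2}; truth: wall WSS
#'     \eqn{4\mu U_{max}/H}, centreline velocity, 2D flow rate
#'     \eqn{2 U_{max} H/3}.}
#'   \item{`rigid_rotation`}{solid-body rotation at rate \eqn{\Omega};
#'     truth: vorticity magnitude \eqn{2\Omega} everywhere, zero strain.}
#'   \item{`taylor_green`}{\eqn{u = A\cos kx \sin ky},
#'     \eqn{v = -A\sin kx \cos ky} on \eqn{[0, 2\pi]^2}; divergence-free;
#'     truth: \eqn{\omega_z = -2Ak\cos kx \cos ky} as a closure.}
#'   \item{`uniform_jet`}{constant velocity; truth: zero vorticity/strain.}
#'   \item{`simple_shear`}{\eqn{u = \dot\gamma_0 y}; truth:
#'     \eqn{|\epsilon| = \dot\gamma_0}.}
#'   \item{`beltrami`}{3D ABC flow (unit wavenumber), an eigenfield of the
#'     curl: truth \eqn{\omega = u}, helicity density \eqn{|u|^2}.}
#'   \item{`random_linear`}{seeded random linear field \eqn{u = M x + c};
#'     truth: constant strain tensor \eqn{(M + M^T)/2}.}
#' }
#'
#' @param kind generator name.
#' @param n cells per dimension (length 2, or 3 for `beltrami`).
#' @param params named list of generator parameters (see details above;
#'   sensible defaults are used for anything omitted).
#' @param seed integer seed (only `random_linear` draws random numbers, but
#'   the seed is always applied so generation is reproducible by contract).
#' @return A [field_snapshot()] with attribute `ground_truth`.
#' @export
make_field <- function(kind = c("poiseuille", "rigid_rotation",
                                "taylor_green", "uniform_jet",
                                "simple_shear", "beltrami", "random_linear"),
                       n = c(48, 48), params = list(), seed = 1L) {
  kind <- match.arg(kind)
  set.seed(seed)
  P <- function(name, default) params[[name]] %||% default
  if (kind == "beltrami") {
    if (length(n) != 3L) n <- rep(n[1], 3)
    L <- 2 * pi; h <- L / n[1]
    if (length(unique(n)) != 1L) stop("beltrami needs a cubic grid", call. = FALSE)
    x <- cell_centres(n[1], L); y <- cell_centres(n[2], L); z <- cell_centres(n[3], L)
    A <- P("A", 1); B <- P("B", 1); C <- P("C", 1)
    X <- array(rep(x, times = n[2] * n[3]), dim = n)
    Y <- array(rep(rep(y, each = n[1]), times = n[3]), dim = n)
    Z <- array(rep(z, each = n[1] * n[2]), dim = n)
    u <- A * sin(Z) + C * cos(Y)
    v <- B * sin(X) + A * cos(Z)
    w <- C * sin(Y) + B * cos(X)
    f <- field_snapshot(0, x, y, u, v, w = w, z = z, h = h)
    attr(f, "ground_truth") <- list(
      vorticity = list(wx = u, wy = v, wz = w),
      helicity = u^2 + v^2 + w^2)
    return(f)
  }
  if (length(n) != 2L) stop("2D generators need length-2 n", call. = FALSE)
  gt <- list()
  switch(kind,
    poiseuille = {
      H <- P("H", 0.02); Lx <- P("L", 0.04)
      U <- P("U_max", 0.5); mu <- P("mu", 0.004)
      h <- H / n[2]
      if (abs(Lx / n[1] - h) > 1e-12) Lx <- n[1] * h  # square cells
      x <- cell_centres(n[1], Lx); y <- cell_centres(n[2], H)
      u <- matrix(rep(4 * U * y * (H - y) / H^2, each = n[1]), n[1], n[2])
      v <- matrix(0, n[1], n[2])
      gt <- list(wss = 4 * mu * U / H, u_max = U,
                 flow_rate_2d = 2 * U * H / 3, mu = mu, H = H)
    },
    rigid_rotation = {
      L <- P("L", 1); om <- P("omega", 5)
      h <- L / n[1]
      x <- cell_centres(n[1], L); y <- cell_centres(n[2], n[2] * h)
      xc <- P("xc", max(x) / 2); yc <- P("yc", max(y) / 2)
      u <- -om * outer(rep(1, n[1]), y - yc)
      v <- om * outer(x - xc, rep(1, n[2]))
      gt <- list(vorticity_mag = 2 * om, strain_mag = 0, omega = om)
    },
    taylor_green = {
      L <- 2 * pi; h <- L / n[1]
      A <- P("A", 1); k <- P("k", 1)
      x <- cell_centres(n[1], L); y <- cell_centres(n[2], n[2] * h)
      u <- A * outer(cos(k * x), sin(k * y))
      v <- -A * outer(sin(k * x), cos(k * y))
      gt <- list(wz = function(x, y) -2 * A * k * outer(cos(k * x), cos(k * y)),
                 divergence = 0)
    },
    uniform_jet = {
      L <- P("L", 1); h <- L / n[1]
      x <- cell_centres(n[1], L); y <- cell_centres(n[2], n[2] * h)
      u <- matrix(P("speed_x", 0.1), n[1], n[2])
      v <- matrix(P("speed_y", 0), n[1], n[2])
      gt <- list(vorticity_mag = 0, strain_mag = 0)
    },
    simple_shear = {
      H <- P("H", 1); g0 <- P("gamma0", 100)
      h <- H / n[2]
      x <- cell_centres(n[1], n[1] * h); y <- cell_centres(n[2], H)
      u <- matrix(rep(g0 * y, each = n[1]), n[1], n[2])
      v <- matrix(0, n[1], n[2])
      gt <- list(strain_mag = g0, gamma0 = g0)
    },
    random_linear = {
      L <- P("L", 1); h <- L / n[1]
      x <- cell_centres(n[1], L); y <- cell_centres(n[2], n[2] * h)
      M <- matrix(stats::rnorm(4), 2, 2)
      cc <- stats::rnorm(2)
      u <- M[1, 1] * outer(x, rep(1, n[2])) +
        M[1, 2] * outer(rep(1, n[1]), y) + cc[1]
      v <- M[2, 1] * outer(x, rep(1, n[2])) +
        M[2, 2] * outer(rep(1, n[1]), y) + cc[2]
      S <- (M + t(M)) / 2
      gt <- list(M = M, strain_tensor = S,
                 strain_mag = sqrt(2 * sum(S^2)),
                 vorticity_z = M[2, 1] - M[1, 2])
    })
  f <- field_snapshot(0, x, y, u, v, h = h)
  attr(f, "ground_truth") <- gt
  f
}

#' Outlet phase-fraction pattern with a planted recirculation fraction
#'
#' Constructs a facet-resolved monitor of the catheter arterial patch whose
#' mass-weighted recirculation fraction equals `Rf` exactly: heterogeneous
#' facet mass flows are drawn, facet mean fractions are perturbed around
#' `Rf/100` with a mass-weighted zero-sum perturbation, and each facet's
#' time trace adds a zero-time-mean oscillation so the trapezoidal time
#' average recovers the planted facet means.
#'
#' @param Rf planted recirculation fraction [%], in `[0, 100]`.
#' @param K number of facets.
#' @param n_t number of time samples over one cycle (inclusive grid).
#' @param T cycle length [s].
#' @param rho blood density [kg/m^3].
#' @param heterogeneous perturb facet fractions and mass flows (if `FALSE`
#'   all facets share `Rf/100` and equal flows).
#' @param seed integer seed.
#' @return A `patch_series` with attribute `planted` (list with `Rf`,
#'   `phi_bar_k`, `mdot_k`).
#' @export
make_phase_pattern <- function(Rf = 25, K = 6, n_t = 41, T = 0.8,
                               rho = 1060, heterogeneous = TRUE, seed = 1L) {
  if (Rf < 0 || Rf > 100) stop("planted Rf must lie in [0, 100]", call. = FALSE)
  set.seed(seed)
  t <- seq(0, T, length.out = n_t)
  area <- stats::runif(K, 0.5, 1.5) * 1e-6
  un <- if (heterogeneous) stats::runif(K, 0.05, 0.5) else rep(0.2, K)
  mdot <- rho * un * area
  wgt <- mdot / sum(mdot)
  phi0 <- Rf / 100
  if (heterogeneous && phi0 > 0 && phi0 < 1) {
    r <- stats::runif(K, -1, 1)
    r <- r - sum(wgt * r)                    # mass-weighted zero sum
    smax <- 0.9 * min(phi0, 1 - phi0) / max(abs(r), 1e-12)
    phi_bar <- phi0 + smax * r
  } else {
    phi_bar <- rep(phi0, K)
  }
  # zero-time-mean wiggle keeps the trapezoidal facet average exact
  phi <- matrix(NA_real_, n_t, K)
  for (k in seq_len(K)) {
    amp <- 0.9 * min(phi_bar[k], 1 - phi_bar[k])
    phi[, k] <- phi_bar[k] + amp * sin(2 * pi * (k %% 3 + 1) * t / T)
  }
  un_mat <- matrix(un, n_t, K, byrow = TRUE)
  ps <- patch_series("synthetic_outlet", t, phi, un_mat, area, T)
  attr(ps, "planted") <- list(Rf = Rf, phi_bar_k = phi_bar, mdot_k = mdot)
  ps
}

# pair of standard-normal vectors with *exact* sample correlation r,
# via orthogonalization of a second draw against the first
exact_corr_pair <- function(n, r) {
  x <- stats::rnorm(n); e <- stats::rnorm(n)
  x0 <- (x - mean(x)) / stats::sd(x)
  e1 <- e - mean(e)
  e1 <- e1 - sum(e1 * x0) / sum(x0 * x0) * x0
  e0 <- e1 / stats::sd(e1)
  y <- r * x0 + sqrt(1 - r^2) * e0
  list(x = x0, y = y)
}

#' Multi-cycle series with planted convergence errors and correlation
#'
#' Builds per-quantity pulsatile series over `n_cycles` cardiac cycles whose
#' cycle means reproduce a planted sequence of relative errors against a
#' reference cycle exactly (each cycle's mean is
#' \eqn{v_{ref}(1 + E_c/100)}; within-cycle oscillations have exactly zero
#' arithmetic mean so per-cycle means recover the plant), plus, optionally,
#' a pair of series with an exactly planted Pearson correlation obtained by
#' seeded Gaussian mixing with orthogonalization.
#'
#' @param errors named list of per-cycle error sequences [%] (e.g.
#'   `list(velocity = c(5, 2, 0), pressure = ...)`); the reference cycle's
#'   entry must be 0.
#' @param ref_values named reference values, same names as `errors`.
#' @param ref_cycle index of the reference cycle; default the last.
#' @param n_per_cycle samples per cycle.
#' @param T cycle length [s].
#' @param target_r optional planted Pearson correlation in `(-1, 1)` for
#'   the extra pair (`pair_a`, `pair_b`).
#' @param n_pair length of the correlated pair.
#' @param seed integer seed.
#' @return Named list of [time_series()] (one per quantity, plus `pair_a`,
#'   `pair_b` when `target_r` is given) with attribute `planted`.
#' @export
make_pulsatile_series <- function(errors = list(velocity = c(5, 2, 0)),
                                  ref_values = c(velocity = 0.192),
                                  ref_cycle = NULL,
                                  n_per_cycle = 100, T = 0.8,
                                  target_r = NULL, n_pair = 1000,
                                  seed = 1L) {
  set.seed(seed)
  n_cycles <- unique(vapply(errors, length, integer(1)))
  if (length(n_cycles) != 1L || n_cycles < 2L) {
    stop("all error sequences must share one length >= 2", call. = FALSE)
  }
  ref_cycle <- ref_cycle %||% n_cycles
  out <- list()
  t <- seq_len(n_cycles * n_per_cycle) * (T / n_per_cycle)
  for (nm in names(errors)) {
    E <- errors[[nm]]
    if (any(E < 0)) stop("planted errors must be non-negative", call. = FALSE)
    if (E[ref_cycle] != 0) {
      stop("the reference cycle's planted error must be 0", call. = FALSE)
    }
    vref <- ref_values[[nm]]
    if (is.null(vref) || vref == 0) {
      stop(sprintf("non-zero reference value needed for '%s'", nm),
           call. = FALSE)
    }
    means <- vref * (1 + E / 100)
    vals <- numeric(length(t))
    for (cc in seq_len(n_cycles)) {
      idx <- ((cc - 1) * n_per_cycle + 1):(cc * n_per_cycle)
      wig <- sin(2 * pi * seq_len(n_per_cycle) / n_per_cycle)
      wig <- wig - mean(wig)                 # exactly zero-mean
      vals[idx] <- means[cc] + 0.05 * abs(vref) * wig
    }
    out[[nm]] <- time_series(nm, t, vals, T)
  }
  planted <- list(errors = errors, ref_cycle = ref_cycle)
  if (!is.null(target_r)) {
    if (abs(target_r) >= 1) stop("target correlation must lie in (-1, 1)",
                                 call. = FALSE)
    pr <- exact_corr_pair(n_pair, target_r)
    tp <- seq_len(n_pair) * (T / n_per_cycle)
    out$pair_a <- time_series("pair_a", tp, pr$x, T)
    out$pair_b <- time_series("pair_b", tp, pr$y, T)
    planted$target_r <- target_r
  }
  attr(out, "planted") <- planted
  out
}

#' Write a synthetic set of supplementary-schema CSV files
#'
#' Emulates the published supplementary summaries at desk scale: files in
#' the exact schemas read by [recompute_supplementary()], with the headline
#' statistics planted so the reader/statistics path is round-trip testable.
#' Defaults plant the published values: temporal-convergence errors at the
#' analysis cycle of 1.28 percent (velocity) and 4.12 percent (pressure)
#' against cycle 7 of 8, WSS-vorticity Pearson correlation 0.87,
#' analysis-cycle averaged chamber vorticity 44.1 1/s and WSS 1.89 Pa, peak
#' boundary flows 106/120/225 ml/s (IVC/SVC/TV), per-model averaged
#' vorticity and time-averaged tip shear per catheter. All files carry
#' "synthetic" in their names.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param T cycle length [s].
#' @param n_cycles number of cycles in the s9/s11 series.
#' @param n_per_cycle samples per cycle.
#' @param analysis_cycle cycle whose statistics are planted.
#' @param ref_cycle reference cycle for the temporal errors.
#' @param pearson planted WSS-vorticity correlation.
#' @param vel_errors,press_errors planted per-cycle error sequences [%].
#' @param vorticity_avg planted analysis-cycle vorticity [1/s].
#' @param wss_avg planted analysis-cycle WSS [Pa].
#' @param flow_peaks named planted peak flows [ml/s].
#' @param model_vorticity named per-model averaged vorticity [1/s].
#' @param model_tip_shear named per-model time-averaged tip shear [Pa].
#' @return Invisibly, the named list of file paths.
#' @export
make_supplementary_mock <- function(dir, seed = 1L, T = 0.8, n_cycles = 8,
                                    n_per_cycle = 100, analysis_cycle = 4,
                                    ref_cycle = 7,
                                    pearson = 0.87,
                                    vel_errors = c(12, 6, 2.8, 1.28, 0.9,
                                                   0.5, 0, 0.2),
                                    press_errors = c(20, 11, 6.5, 4.12, 2.4,
                                                     1.1, 0, 0.5),
                                    vorticity_avg = 44.1, wss_avg = 1.89,
                                    flow_peaks = c(IVC = 106, SVC = 120,
                                                   TV = 225),
                                    model_vorticity = c(RA = 44.10, A1 = 54,
                                                        A2 = 55.20, A3 = 55,
                                                        B = 57.20, C = 56.10,
                                                        D1 = 55.80, D2 = 54.90),
                                    model_tip_shear = c(A1 = 12.90, A2 = 15.50,
                                                        A3 = 13.70, B = 13.80,
                                                        C = 11.20, D1 = 11.60,
                                                        D2 = 10.20)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  paths <- list()

  # s9: volume-averaged velocity and pressure per time step
  ser <- make_pulsatile_series(
    errors = list(velocity = vel_errors, pressure = press_errors),
    ref_values = c(velocity = 0.192, pressure = 1.18 * 133.322),
    ref_cycle = ref_cycle, n_per_cycle = n_per_cycle, T = T, seed = seed)
  paths$s9 <- file.path(dir, "s9_temporal_convergence_synthetic.csv")
  utils::write.csv(data.frame(time = ser$velocity$t,
                              velocity = ser$velocity$values,
                              pressure = ser$pressure$values),
                   paths$s9, row.names = FALSE)

  # s10: boundary velocity-area series over one cycle with planted peaks
  areas <- c(IVC = pi * 16.89e-3^2 / 4, SVC = pi * 17.06e-3^2 / 4,
             TV = 9.95e-4)
  t1 <- seq(0, T, length.out = n_per_cycle + 1)
  shape <- 0.35 + 0.65 * 0.5 * (1 - cos(2 * pi * t1 / T))  # peak mid-cycle
  shape <- shape / max(shape)                              # unit peak
  rows <- lapply(names(flow_peaks), function(b) {
    A <- areas[[b]]
    vel <- (flow_peaks[[b]] / 1e6 / A) * shape
    data.frame(boundary = b, time = t1, velocity = vel, area = A)
  })
  paths$s10 <- file.path(dir, "s10_boundary_flows_synthetic.csv")
  utils::write.csv(do.call(rbind, rows), paths$s10, row.names = FALSE)

  # s11: WSS and vorticity with exact correlation; affine maps preserve it,
  # and the analysis-cycle trapezoidal mean of the vorticity is re-centred
  # onto its planted value (same for WSS)
  n11 <- n_cycles * n_per_cycle
  pr <- exact_corr_pair(n11, pearson)
  t11 <- seq_len(n11) * (T / n_per_cycle)
  win <- t11 > (analysis_cycle - 1) * T - 1e-9 &
    t11 <= analysis_cycle * T + 1e-9
  cyc_mean <- function(yy) trapz_int(t11[win], yy[win]) /
    (t11[win][sum(win)] - t11[win][1])
  vort <- 4 * pr$x; vort <- vort + (vorticity_avg - cyc_mean(vort))
  wss <- 0.3 * pr$y; wss <- wss + (wss_avg - cyc_mean(wss))
  paths$s11 <- file.path(dir, "s11_wss_vorticity_synthetic.csv")
  utils::write.csv(data.frame(time = t11, wss = wss, vorticity = vort),
                   paths$s11, row.names = FALSE)

  # s12: per-model vorticity series with planted analysis-cycle averages
  rows <- lapply(names(model_vorticity), function(m) {
    base <- 3 * sin(2 * pi * t11 / T) + stats::rnorm(n11, sd = 0.5)
    y <- base + (model_vorticity[[m]] - cyc_mean(base))
    data.frame(time = t11, model = m, vorticity = y)
  })
  paths$s12 <- file.path(dir, "s12_model_vorticity_synthetic.csv")
  utils::write.csv(do.call(rbind, rows), paths$s12, row.names = FALSE)

  # s13: per-model tip shear with planted last-cycle time averages
  avg_last <- function(yy) time_average(yy, t = t11, T = T)
  rows <- lapply(names(model_tip_shear), function(m) {
    base <- 1.5 * sin(2 * pi * t11 / T + 0.6) + stats::rnorm(n11, sd = 0.3)
    y <- base + (model_tip_shear[[m]] - avg_last(base))
    data.frame(time = t11, model = m, tau = y)
  })
  paths$s13 <- file.path(dir, "s13_tip_shear_synthetic.csv")
  utils::write.csv(do.call(rbind, rows), paths$s13, row.names = FALSE)

  invisible(paths)
}
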