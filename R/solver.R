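#' Solver settings
#'
#' Numerical controls for [solve_transient()]. The default time step is
#' 0.005 s for single-phase runs and 0.001 s when the filtered-blood phase
#' fraction is tracked (a catheter is present); the run covers `n_cycles`
#' cardiac cycles (default 4) and the final cycle is flagged as the analysis
#' cycle. Continuity is enforced by a direct pressure projection and checked
#' against `residual_tol` (default 1e-4, normalized). Advection of the phase
#' fraction uses either first-order `"upwind"` or the bound-preserving
#' flux-limited `"van_leer"` scheme (default). When the advective or
#' diffusive stability number of a step exceeds `cfl_cap`, the step is
#' subdivided if `adaptive` is `TRUE`, otherwise the solver aborts.
#'
#' @param dt time step [s], or `NULL` to pick the phase-dependent default.
#' @param n_cycles number of cardiac cycles to run.
#' @param residual_tol normalized continuity residual tolerance.
#' @param cfl_cap stability-number cap per (sub)step.
#' @param scheme phase-fraction advection scheme.
#' @param snapshot_stride emit a field snapshot every this many steps.
#' @param adaptive allow sub-stepping when `cfl_cap` is exceeded.
#' @param admittance linear admittance mapping inlet gauge pressure to
#'   inflow velocity [m/s per Pa] (velocity-driven inlet mode).
#' @param t_end explicit end time [s] (used by waveform-free runs such as
#'   the channel verification; otherwise derived from the waveform period).
#' @param seed integer seed for any perturbed initialization (the default
#'   rest start is deterministic; the seed is recorded for reproducibility).
#' @return Object of class `solver_settings`.
#' @export
solver_settings <- function(dt = NULL, n_cycles = 4, residual_tol = 1e-4,
                            cfl_cap = 0.45,
                            scheme = c("van_leer", "upwind"),
                            snapshot_stride = 10L, adaptive = TRUE,
                            admittance = 5e-4, t_end = NULL, seed = 1L) {
  scheme <- match.arg(scheme)
  if (!is.null(dt) && dt <= 0) stop("dt must be positive", call. = FALSE)
  if (residual_tol <= 0) stop("residual_tol must be positive", call. = FALSE)
  structure(list(dt = dt, n_cycles = n_cycles, residual_tol = residual_tol,
                 cfl_cap = cfl_cap, scheme = scheme,
                 snapshot_stride = as.integer(snapshot_stride),
                 adaptive = adaptive, admittance = admittance,
                 t_end = t_end, seed = as.integer(seed)),
            class = "solver_settings")
}

# ---- discrete operators -----------------------------------------------------

# graph Laplacian over cells (interior-face connections; optional periodic x),
# pinned at cell 1 to fix the pressure gauge; returns a Cholesky factor
build_poisson <- function(geom) {
  nx <- geom$nx; ny <- geom$ny
  id <- matrix(seq_len(nx * ny), nx, ny)
  from <- integer(0); to <- integer(0)
  if (nx > 1) {
    from <- c(from, id[1:(nx - 1), ]); to <- c(to, id[2:nx, ])
  }
  if (geom$periodic_x) {
    from <- c(from, id[nx, ]); to <- c(to, id[1, ])
  }
  if (ny > 1) {
    from <- c(from, id[, 1:(ny - 1)]); to <- c(to, id[, 2:ny])
  }
  n <- nx * ny
  A <- Matrix::sparseMatrix(i = c(from, to), j = c(to, from),
                            x = -1, dims = c(n, n))
  deg <- -Matrix::rowSums(A)
  A <- A + Matrix::Diagonal(n, deg)
  A[1, 1] <- A[1, 1] + 1  # pin the gauge
  Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE, perm = TRUE)
}

# face-depth arrays: interior faces carry the slab depth b0, boundary faces
# the depth of the patch they belong to (walls: b0, velocity there is zero)
face_depths <- function(geom) {
  nx <- geom$nx; ny <- geom$ny; b0 <- geom$b0
  bu <- matrix(b0, nx + 1, ny)
  bv <- matrix(b0, nx, ny + 1)
  for (p in geom$patches) {
    switch(p$side,
      xmin = { bu[1, p$faces] <- p$depth },
      xmax = { bu[nx + 1, p$faces] <- p$depth },
      ymin = { bv[p$faces, 1] <- p$depth },
      ymax = { bv[p$faces, ny + 1] <- p$depth })
  }
  list(bu = bu, bv = bv)
}

# port masks for tangential ghost construction: TRUE where a boundary face of
# the *tangential* velocity sits next to a port cell (zero-gradient instead of
# no-slip there)
port_masks <- function(geom) {
  nx <- geom$nx; ny <- geom$ny
  cells <- function(side) {
    out <- integer(0)
    for (p in geom$patches) if (p$side == side) out <- c(out, p$faces)
    out
  }
  adj <- function(cells, n) {
    m <- logical(n + 1)
    if (length(cells)) {
      m[cells] <- TRUE       # face left/below of cell
      m[cells + 1L] <- TRUE  # face right/above of cell
    }
    m
  }
  list(u_bottom = adj(cells("ymin"), nx),  # u-faces along y = 0
       u_top = adj(cells("ymax"), nx),     # u-faces along y = Ly
       v_left = adj(cells("xmin"), ny),    # v-faces along x = 0
       v_right = adj(cells("xmax"), ny))
}

# quadratic no-slip ghost: wall value 0 to second order; ports: zero gradient
ghost_row <- function(near, next_in, port_mask) {
  g <- (next_in - 6 * near) / 3
  g[port_mask] <- near[port_mask]
  g
}

# prescribe boundary normal velocities at time t; the pressure outlet (TV)
# absorbs the net volumetric imbalance so continuity is exactly compatible
set_normal_bcs <- function(u, v, geom, p_inlet, settings) {
  nx <- geom$nx; ny <- geom$ny
  if (!geom$periodic_x) { u[1, ] <- 0; u[nx + 1, ] <- 0 }
  v[, 1] <- 0; v[, ny + 1] <- 0
  q <- numeric(0)  # signed volumetric flow per patch, inflow positive
  outlet <- NULL
  for (p in geom$patches) {
    if (p$kind == "pressure_outlet") { outlet <- p; next }
    un <- switch(p$kind,
      pressure_inlet = settings$admittance * p_inlet,  # inflow speed
      velocity_inlet = p$flow / p$area,
      catheter_venous = p$flow / p$area,
      catheter_arterial = -p$flow / p$area,            # outflow
      wall = 0)
    qp <- un * p$area
    switch(p$side,
      xmin = { u[1, p$faces] <- un },
      xmax = { u[nx + 1, p$faces] <- -un },
      ymin = { v[p$faces, 1] <- un },
      ymax = { v[p$faces, ny + 1] <- -un })
    q[p$name] <- qp
  }
  if (!is.null(outlet)) {
    un_out <- sum(q) / outlet$area
    switch(outlet$side,
      xmin = { u[1, outlet$faces] <- -un_out },
      xmax = { u[nx + 1, outlet$faces] <- un_out },
      ymin = { v[outlet$faces, 1] <- -un_out },
      ymax = { v[outlet$faces, ny + 1] <- un_out })
    q[outlet$name] <- -un_out * outlet$area
  }
  list(u = u, v = v, q = q)
}

# cell-centred shear-rate magnitude |eps| from staggered velocities
staggered_shear_rate <- function(u, v, h) {
  nx <- nrow(u) - 1L; ny <- ncol(v) - 1L
  uc <- (u[1:nx, , drop = FALSE] + u[2:(nx + 1), , drop = FALSE]) / 2
  vc <- (v[, 1:ny, drop = FALSE] + v[, 2:(ny + 1), drop = FALSE]) / 2
  e11 <- (u[2:(nx + 1), , drop = FALSE] - u[1:nx, , drop = FALSE]) / h
  e22 <- (v[, 2:(ny + 1), drop = FALSE] - v[, 1:ny, drop = FALSE]) / h
  dudy <- d_dy_centered(uc, h)
  dvdx <- d_dx_centered(vc, h)
  e12 <- 0.5 * (dudy + dvdx)
  list(gamma = sqrt(2 * (e11^2 + e22^2 + 2 * e12^2)), uc = uc, vc = vc)
}

# upwind advection + explicit diffusion for the two momentum components;
# returns time derivatives on interior faces (chamber) or all faces (channel)
momentum_rhs <- function(u, v, geom, nu, masks, rho) {
  nx <- geom$nx; ny <- geom$ny; h <- geom$h
  per <- geom$periodic_x
  gx <- geom$body_force[1] / rho; gy <- geom$body_force[2] / rho

  # --- u component ---
  gb <- ghost_row(u[, 1], u[, min(2, ny)], masks$u_bottom)
  gt <- ghost_row(u[, ny], u[, max(ny - 1, 1)], masks$u_top)
  Ue <- cbind(gb, u, gt)  # (nx+1) x (ny+2)
  if (per) {
    ii <- 1:nx                      # unique faces, u[nx+1,] mirrors u[1,]
    im <- c(nx, 1:(nx - 1)); ip <- c(2:nx, 1)
    uP <- u[ii, , drop = FALSE]
    uW <- u[im, , drop = FALSE]; uE <- u[ip, , drop = FALSE]
    vat <- 0.25 * (v[im, 1:ny] + v[ii, 1:ny] + v[im, 2:(ny + 1)] + v[ii, 2:(ny + 1)])
    uS <- Ue[ii, 1:ny, drop = FALSE]; uN <- Ue[ii, 3:(ny + 2), drop = FALSE]
  } else {
    ii <- 2:nx
    uP <- u[ii, , drop = FALSE]
    uW <- u[1:(nx - 1), , drop = FALSE]; uE <- u[3:(nx + 1), , drop = FALSE]
    vat <- 0.25 * (v[1:(nx - 1), 1:ny] + v[ii, 1:ny] +
                   v[1:(nx - 1), 2:(ny + 1)] + v[ii, 2:(ny + 1)])
    uS <- Ue[ii, 1:ny, drop = FALSE]; uN <- Ue[ii, 3:(ny + 2), drop = FALSE]
  }
  adv_u <- pmax(uP, 0) * (uP - uW) / h + pmin(uP, 0) * (uE - uP) / h +
    pmax(vat, 0) * (uP - uS) / h + pmin(vat, 0) * (uN - uP) / h
  if (per) {
    nu_u <- (nu[im, , drop = FALSE] + nu[ii, , drop = FALSE]) / 2
  } else {
    nu_u <- (nu[1:(nx - 1), , drop = FALSE] + nu[ii, , drop = FALSE]) / 2
  }
  lap_u <- (uE + uW - 2 * uP) / h^2 + (uN + uS - 2 * uP) / h^2
  du <- -adv_u + nu_u * lap_u + gx

  # --- v component ---
  gl <- ghost_row(v[1, ], v[min(2, nx), ], masks$v_left)
  gr <- ghost_row(v[nx, ], v[max(nx - 1, 1), ], masks$v_right)
  Ve <- rbind(gl, v, gr)  # (nx+2) x (ny+1)
  jj <- 2:ny
  vP <- v[, jj, drop = FALSE]
  vS <- v[, 1:(ny - 1), drop = FALSE]; vN <- v[, 3:(ny + 1), drop = FALSE]
  uat <- 0.25 * (u[1:nx, jj - 1] + u[2:(nx + 1), jj - 1] +
                 u[1:nx, jj] + u[2:(nx + 1), jj])
  if (per) {
    imc <- c(nx, 1:(nx - 1)); ipc <- c(2:nx, 1)
    vW <- v[imc, jj, drop = FALSE]; vE <- v[ipc, jj, drop = FALSE]
  } else {
    vW <- Ve[1:nx, jj, drop = FALSE]; vE <- Ve[3:(nx + 2), jj, drop = FALSE]
  }
  adv_v <- pmax(uat, 0) * (vP - vW) / h + pmin(uat, 0) * (vE - vP) / h +
    pmax(vP, 0) * (vP - vS) / h + pmin(vP, 0) * (vN - vP) / h
  nu_v <- (nu[, jj - 1, drop = FALSE] + nu[, jj, drop = FALSE]) / 2
  lap_v <- (vE + vW - 2 * vP) / h^2 + (vN + vS - 2 * vP) / h^2
  dv <- -adv_v + nu_v * lap_v + gy
  list(du = du, dv = dv, ii = ii, jj = jj)
}

# one directional TVD sweep for the phase fraction (x direction; call with
# transposed arguments for y). Non-conservative convex form: bounded for
# upwind; the van Leer antidiffusion is limited cell-wise (Zalesak) so the
# result stays within local bounds and hence in [0, 1].
phase_sweep <- function(phi, uf, bf, dt, h, b0, ghost_lo, ghost_hi, scheme) {
  nx <- nrow(phi); np <- ncol(phi)
  G <- uf * bf                               # (nx+1) x np
  k <- dt / (h * b0)
  phiW <- rbind(ghost_lo, phi[-nx, , drop = FALSE])
  phiE <- rbind(phi[-1, , drop = FALSE], ghost_hi)
  cW <- k * pmax(G[1:nx, , drop = FALSE], 0)
  cE <- k * pmax(-G[2:(nx + 1), , drop = FALSE], 0)
  phiL <- phi + cW * (phiW - phi) + cE * (phiE - phi)
  if (scheme == "upwind" || nx < 3) return(phiL)

  f <- 2:nx                                   # interior faces
  s <- G[f, , drop = FALSE] >= 0
  phim1 <- phi[f - 1, , drop = FALSE]; phic <- phi[f, , drop = FALSE]
  U <- ifelse(s, phim1, phic)
  D <- ifelse(s, phic, phim1)
  phim2 <- rbind(ghost_lo, phi[1:(nx - 2), , drop = FALSE])  # phi[f-2]
  phip1 <- rbind(phi[3:nx, , drop = FALSE], ghost_hi)        # phi[f+1]
  UU <- ifelse(s, phim2, phip1)
  d1 <- D - U; d2 <- U - UU
  r <- ifelse(d1 != 0, d2 / d1, 0)
  vl <- (r + abs(r)) / (1 + abs(r))
  phiH <- U + 0.5 * vl * d1
  phiLf <- ifelse(s, phim1, phic)            # upwind face value
  A <- G[f, , drop = FALSE] * (phiH - phiLf) # antidiffusive face flux
  Aw <- rbind(0, A)                          # west-face flux per cell
  Ae <- rbind(A, 0)                          # east-face flux per cell
  Pp <- k * (pmax(Aw, 0) + pmax(-Ae, 0))
  Pm <- k * (pmax(-Aw, 0) + pmax(Ae, 0))
  M <- pmax(phi, phiL); m <- pmin(phi, phiL)
  Mw <- rbind(M[1, ], M[-nx, , drop = FALSE])
  Me <- rbind(M[-1, , drop = FALSE], M[nx, ])
  mw <- rbind(m[1, ], m[-nx, , drop = FALSE])
  me <- rbind(m[-1, , drop = FALSE], m[nx, ])
  phimax <- pmax(M, Mw, Me); phimin <- pmin(m, mw, me)
  Rp <- ifelse(Pp > 0, pmin(1, (phimax - phiL) / Pp), 1)
  Rm <- ifelse(Pm > 0, pmin(1, (phiL - phimin) / Pm), 1)
  # face f lies between cells f-1 (west) and f (east); A > 0 raises cell f
  Cf <- ifelse(A > 0,
               pmin(Rp[f, , drop = FALSE], Rm[f - 1, , drop = FALSE]),
               pmin(Rm[f, , drop = FALSE], Rp[f - 1, , drop = FALSE]))
  CA <- Cf * A
  CAw <- rbind(0, CA); CAe <- rbind(CA, 0)
  phiL + k * (CAw - CAe)
}

# ---- main driver ------------------------------------------------------------

#' Transient chamber simulation
#'
#' Advances the incompressible generalized-Newtonian flow in the chamber (or
#' verification channel) with a fractional-step (projection) method on a
#' staggered grid: explicit upwind advection and explicit diffusion with the
#' cell-wise apparent viscosity, followed by a direct pressure projection
#' that enforces continuity, and a bounded advection step for the
#' filtered-blood phase fraction sourced at value 1 on the catheter venous
#' patch and 0 at the SVC/IVC inlets. Inlets are velocity-driven: the inlet
#' waveform pressure is mapped to inflow velocity through a linear
#' admittance, and the TV outlet absorbs the instantaneous volumetric
#' imbalance (rigid walls force exact balance). Snapshots are emitted at a
#' configurable stride; the final cycle is the analysis cycle.
#'
#' @param geom a [chamber_geometry()] or [channel_geometry()].
#' @param props a [fluid_properties()].
#' @param waveform an [inlet_waveform()] (may be `NULL` for waveform-free
#'   geometries such as the channel).
#' @param catheter optional [catheter_config()]; placed with
#'   [place_catheter()] if the geometry does not already hold one.
#' @param settings a [solver_settings()].
#' @return Object of class `chamber_run` with elements `snapshots` (list of
#'   `field_snapshot`), `monitors` (per-step data frame: time, per-patch
#'   flows, balance, volume-averaged speed and pressure, probe speed,
#'   residual, CFL), `arterial_monitor` (facet-resolved phase fraction and
#'   normal velocity at the catheter arterial patch, for
#'   [recirculation_fraction()]), the geometry, properties, waveform and
#'   settings, and the analysis-cycle index.
#' @export
solve_transient <- function(geom, props = fluid_properties(),
                            waveform = NULL, catheter = NULL,
                            settings = solver_settings()) {
  stopifnot(inherits(geom, "chamber_geometry"),
            inherits(props, "fluid_properties"),
            inherits(settings, "solver_settings"))
  if (!is.null(catheter) && is.null(geom$catheter)) {
    geom <- place_catheter(geom, catheter)
  }
  multiphase <- !is.null(geom$catheter)
  dt0 <- settings$dt %||% if (multiphase) 0.001 else 0.005
  if (geom$kind == "chamber" && is.null(waveform)) {
    stop("a chamber run needs an inlet waveform", call. = FALSE)
  }
  period <- if (!is.null(waveform)) waveform$cycle$period else settings$t_end
  t_end <- settings$t_end %||% (settings$n_cycles * period)
  if (is.null(t_end)) stop("set t_end or supply a waveform", call. = FALSE)
  n_steps <- max(1L, round(t_end / dt0))
  dt0 <- t_end / n_steps

  nx <- geom$nx; ny <- geom$ny; h <- geom$h; rho <- props$rho; b0 <- geom$b0
  ch <- build_poisson(geom)
  fd <- face_depths(geom)
  masks <- port_masks(geom)
  set.seed(settings$seed)

  u <- matrix(0, nx + 1, ny); v <- matrix(0, nx, ny + 1)
  p <- matrix(0, nx, ny); phi <- matrix(0, nx, ny)
  probe <- c(max(1L, round(nx / 2)), max(1L, round(ny / 2)))

  art <- geom$patches[["cath_arterial"]]
  ven_cells_top <- integer(0)
  for (pp in geom$patches) {
    if (pp$kind == "catheter_venous" && pp$side == "ymax") {
      ven_cells_top <- c(ven_cells_top, pp$faces)
    }
  }
  ghost_top_phi <- rep(0, nx); ghost_top_phi[ven_cells_top] <- 1

  snapshots <- list()
  mon <- vector("list", n_steps)
  # facet monitor rows include the t = 0 initial state so the series spans
  # whole cycles
  art_phi <- if (multiphase && !is.null(art)) {
    matrix(0, n_steps + 1L, length(art$faces))
  } else NULL
  art_un <- art_phi

  divergence <- function(u, v) {
    h * (u[2:(nx + 1), ] * fd$bu[2:(nx + 1), ] - u[1:nx, ] * fd$bu[1:nx, ]) +
      h * (v[, 2:(ny + 1)] * fd$bv[, 2:(ny + 1)] - v[, 1:ny] * fd$bv[, 1:ny])
  }

  step_once <- function(u, v, phi, t, dt, sweep_xy) {
    sr <- staggered_shear_rate(u, v, h)
    nu <- apparent_viscosity(sr$gamma, props) / rho
    rhs_mom <- momentum_rhs(u, v, geom, nu, masks, rho)
    us <- u; vs <- v
    if (geom$periodic_x) {
      us[rhs_mom$ii, ] <- u[rhs_mom$ii, ] + dt * rhs_mom$du
      us[nx + 1, ] <- us[1, ]
    } else {
      us[rhs_mom$ii, ] <- u[rhs_mom$ii, ] + dt * rhs_mom$du
    }
    vs[, rhs_mom$jj] <- v[, rhs_mom$jj] + dt * rhs_mom$dv
    bc <- set_normal_bcs(us, vs, geom,
                         if (!is.null(waveform)) sample_waveform(waveform, t + dt) else 0,
                         settings)
    us <- bc$u; vs <- bc$v
    div3 <- divergence(us, vs)
    rhs <- -as.vector(div3) * rho / (dt * b0)
    rhs <- rhs - mean(rhs)
    pv <- as.vector(Matrix::solve(ch, rhs))
    pm <- matrix(pv, nx, ny)
    if (geom$periodic_x) {
      grad_w <- (pm - pm[c(nx, 1:(nx - 1)), , drop = FALSE]) / h
      us[1:nx, ] <- us[1:nx, ] - dt / rho * grad_w
      us[nx + 1, ] <- us[1, ]
    } else if (nx > 1) {
      us[2:nx, ] <- us[2:nx, ] -
        dt / rho * (pm[2:nx, ] - pm[1:(nx - 1), ]) / h
    }
    if (ny > 1) {
      vs[, 2:ny] <- vs[, 2:ny] -
        dt / rho * (pm[, 2:ny] - pm[, 1:(ny - 1)]) / h
    }
    if (multiphase) {
      ghost_zero_y <- rep(0, ny); ghost_zero_x <- rep(0, nx)
      do_x <- function(ph) phase_sweep(ph, us, fd$bu, dt, h, b0,
                                       ghost_zero_y, ghost_zero_y,
                                       settings$scheme)
      do_y <- function(ph) t(phase_sweep(t(ph), t(vs), t(fd$bv), dt, h, b0,
                                         ghost_zero_x, ghost_top_phi,
                                         settings$scheme))
      phi <- if (sweep_xy) do_y(do_x(phi)) else do_x(do_y(phi))
      # the schemes are bound-preserving up to floating-point roundoff;
      # remove that roundoff, never a genuine violation
      if (min(phi) > -1e-12 && max(phi) < 1 + 1e-12) {
        phi <- pmin(pmax(phi, 0), 1)
      }
    }
    res3 <- divergence(us, vs)
    uscale <- max(abs(us), abs(vs), 1e-9)
    list(u = us, v = vs, phi = phi, p = pm, q = bc$q,
         residual = max(abs(res3)) / (b0 * h * uscale),
         numax = max(nu))
  }

  emit_snapshot <- function(time, u, v, phi, pg) {
    uc <- (u[1:nx, ] + u[2:(nx + 1), ]) / 2
    vc <- (v[, 1:ny] + v[, 2:(ny + 1)]) / 2
    field_snapshot(time = time,
                   x = (seq_len(nx) - 0.5) * h, y = (seq_len(ny) - 0.5) * h,
                   u = uc, v = vc, p = pg, phi = phi,
                   gamma_dot = staggered_shear_rate(u, v, h)$gamma, h = h)
  }
  k_snap <- 1L
  snapshots[[1L]] <- emit_snapshot(0, u, v, phi, p)
  for (step in seq_len(n_steps)) {
    t0 <- (step - 1) * dt0
    # stability numbers for this step
    sr <- staggered_shear_rate(u, v, h)
    numax <- max(apparent_viscosity(sr$gamma, props)) / rho
    # boundary speeds at the coming time enter the CFL too
    bc_probe <- set_normal_bcs(u, v, geom,
                               if (!is.null(waveform)) sample_waveform(waveform, t0 + dt0) else 0,
                               settings)
    umax <- max(abs(bc_probe$u), abs(u)); vmax <- max(abs(bc_probe$v), abs(v))
    bfac <- max(fd$bu, fd$bv) / b0
    cfl <- dt0 * (umax + vmax) / h * max(1, bfac)
    dn <- dt0 * numax * (16 / 3) / h^2
    stab <- max(cfl, dn)
    n_sub <- if (stab > settings$cfl_cap) ceiling(stab / settings$cfl_cap) else 1L
    if (n_sub > 1L && !settings$adaptive) {
      stop(sprintf(
        "stability number %.3g exceeds cfl_cap %.3g at t = %.4g s (enable adaptive sub-stepping or reduce dt)",
        stab, settings$cfl_cap, t0), call. = FALSE)
    }
    dts <- dt0 / n_sub
    st <- NULL
    for (ss in seq_len(n_sub)) {
      st <- step_once(u, v, phi, t0 + (ss - 1) * dts, dts,
                      sweep_xy = (step + ss) %% 2L == 0L)
      u <- st$u; v <- st$v; phi <- st$phi
    }
    if (st$residual > settings$residual_tol) {
      stop(sprintf("pressure projection failed: residual %.3g > %.3g at t = %.4g s",
                   st$residual, settings$residual_tol, t0 + dt0), call. = FALSE)
    }
    # gauge pressure relative to the outlet patch
    pg <- st$p
    tvp <- geom$patches[["tv"]]
    if (!is.null(tvp)) pg <- pg - mean(pg[nx, tvp$faces])

    uc <- (u[1:nx, ] + u[2:(nx + 1), ]) / 2
    vc <- (v[, 1:ny] + v[, 2:(ny + 1)]) / 2
    speed <- sqrt(uc^2 + vc^2)
    qv <- st$q
    q_in <- sum(qv[qv > 0]); q_out <- -sum(qv[qv < 0])
    mon[[step]] <- c(time = step * dt0, q_in = q_in, q_out = q_out,
                     balance = abs(q_in - q_out) / max(q_in, 1e-300),
                     mean_speed = mean(speed),
                     mean_p = mean(pg),
                     probe_speed = speed[probe[1], probe[2]],
                     residual = st$residual,
                     cfl = stab, n_sub = n_sub,
                     phi_min = min(phi), phi_max = max(phi),
                     qv)
    if (!is.null(art_phi)) {
      art_phi[step + 1L, ] <- phi[art$faces, ny]
      art_un[step + 1L, ] <- v[art$faces, ny + 1]  # outward (+y) normal velocity
    }
    if (step %% settings$snapshot_stride == 0L || step == n_steps) {
      k_snap <- k_snap + 1L
      snapshots[[k_snap]] <- emit_snapshot(step * dt0, u, v, phi, pg)
    }
  }
  monitors <- as.data.frame(do.call(rbind, mon))
  arterial_monitor <- NULL
  if (!is.null(art_phi)) {
    fac <- patch_facets(geom, "cath_arterial")
    arterial_monitor <- patch_series(
      name = "cath_arterial", time = c(0, monitors$time),
      phi = art_phi, un = art_un, area = fac$area, T = period)
  }
  n_cyc <- if (!is.null(waveform)) settings$n_cycles else 1L
  structure(list(snapshots = snapshots, monitors = monitors,
                 arterial_monitor = arterial_monitor,
                 geometry = geom, props = props, waveform = waveform,
                 settings = settings, dt = dt0, period = period,
                 n_cycles = n_cyc, analysis_cycle = n_cyc,
                 u = u, v = v),
            class = "chamber_run")
}

#' Field snapshot
#'
#' Cell-centred state of the chamber at one instant: velocity components,
#' gauge pressure, filtered-blood phase fraction and shear-rate magnitude on
#' a uniform grid.
#'
#' @param time instant [s].
#' @param x,y cell-centre coordinates [m].
#' @param u,v velocity components [m/s] (matrices `length(x)` x `length(y)`).
#' @param w optional third component for 3D analytic fields.
#' @param z optional third coordinate.
#' @param p gauge pressure [Pa] (may be `NULL` for analytic fields).
#' @param phi phase fraction in `[0, 1]` (or `NULL`).
#' @param gamma_dot shear-rate magnitude [1/s] (or `NULL`).
#' @param h grid spacing [m].
#' @return Object of class `field_snapshot`.
#' @export
field_snapshot <- function(time, x, y, u, v, w = NULL, z = NULL,
                           p = NULL, phi = NULL, gamma_dot = NULL, h) {
  if (!is.null(phi)) {
    if (min(phi) < -1e-12 || max(phi) > 1 + 1e-12) {
      stop("phase fraction must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(list(time = time, x = x, y = y, z = z, u = u, v = v, w = w,
                 p = p, phi = phi, gamma_dot = gamma_dot, h = h),
            class = "field_snapshot")
}

#' @export
print.field_snapshot <- function(x, ...) {
  dims <- paste(dim(as.array(x$u)), collapse = " x ")
  cat(sprintf("Field snapshot at t = %g s (%s cells, h = %g m)\n",
              x$time, dims, x$h))
  cat(sprintf("  max speed %.4g m/s", max(sqrt(x$u^2 + x$v^2))))
  if (!is.null(x$phi)) cat(sprintf(", phi in [%.3g, %.3g]",
                                   min(x$phi), max(x$phi)))
  cat("\n")
  invisible(x)
}

# facet-resolved monitor of a boundary patch over time
patch_series <- function(name, time, phi, un, area, T) {
  structure(list(name = name, time = time, phi = phi, un = un,
                 area = area, T = T),
            class = "patch_series")
}

#' @export
print.chamber_run <- function(x, ...) {
  cat(sprintf("Chamber run: %d steps of %g s (%g cycles of %g s), %d snapshots\n",
              nrow(x$monitors), x$dt, x$n_cycles, x$period,
              length(x$snapshots)))
  cat(sprintf("  geometry %s %d x %d, fluid %s\n", x$geometry$kind,
              x$geometry$nx, x$geometry$ny, x$props$model))
  cat(sprintf("  max |flow imbalance| %.3g, max residual %.3g\n",
              max(x$monitors$balance), max(x$monitors$residual)))
  invisible(x)
}

#' @export
summary.chamber_run <- function(object, ...) {
  m <- object$monitors
  last <- m$time > (object$n_cycles - 1) * object$period + 1e-12
  out <- list(
    n_steps = nrow(m), dt = object$dt, n_cycles = object$n_cycles,
    analysis_cycle = object$analysis_cycle,
    mean_speed_final_cycle = mean(m$mean_speed[last]),
    mean_pressure_final_cycle = mean(m$mean_p[last]),
    max_balance_error = max(m$balance),
    max_residual = max(m$residual),
    phi_range = c(min(m$phi_min), max(m$phi_max)))
  class(out) <- "summary.chamber_run"
  out
}

#' @export
print.summary.chamber_run <- function(x, ...) {
  cat(sprintf("Chamber run summary (%d steps, dt = %g s, %g cycles)\n",
              x$n_steps, x$dt, x$n_cycles))
  cat(sprintf("  analysis cycle:                 %d\n", x$analysis_cycle))
  cat(sprintf("  mean speed, final cycle:        %.4g m/s\n",
              x$mean_speed_final_cycle))
  cat(sprintf("  mean gauge pressure, final cyc: %.4g Pa\n",
              x$mean_pressure_final_cycle))
  cat(sprintf("  worst flow imbalance:           %.3g\n", x$max_balance_error))
  cat(sprintf("  worst continuity residual:      %.3g\n", x$max_residual))
  cat(sprintf("  phase fraction range:           [%.3g, %.3g]\n",
              x$phi_range[1], x$phi_range[2]))
  invisible(x)
}

#' @export
plot.chamber_run <- function(x, which = c("monitors", "field"), ...) {
  which <- match.arg(which)
  m <- x$monitors
  if (which == "monitors") {
    op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op))
    graphics::plot(m$time, m$mean_speed, type = "l", xlab = "time [s]",
                   ylab = "volume-avg speed [m/s]", main = "Chamber monitors")
    graphics::plot(m$time, m$q_in * 6e7, type = "l", xlab = "time [s]",
                   ylab = "inflow [ml/min]")
  } else {
    s <- x$snapshots[[length(x$snapshots)]]
    graphics::image(s$x, s$y, sqrt(s$u^2 + s$v^2), xlab = "x [m]",
                    ylab = "y [m]", main = sprintf("speed at t = %g s", s$time),
                    col = grDevices::hcl.colors(64, "viridis"), useRaster = TRUE)
  }
  invisible(x)
}

#' @export
residuals.chamber_run <- function(object, ...) {
  object$monitors$residual
}

# ---- temporal convergence ---------------------------------------------------

#' Per-cycle summaries of a chamber run
#'
#' Trapezoid time averages, per cardiac cycle, of the volume-averaged speed
#' and gauge pressure and of the probe speed, the quantities used for
#' temporal-convergence assessment.
#'
#' @param run a `chamber_run`.
#' @return Data frame with one row per cycle.
#' @export
cycle_summaries <- function(run) {
  m <- run$monitors
  T <- run$period
  cyc <- pmin(ceiling(m$time / T - 1e-12), run$n_cycles)
  out <- lapply(split(seq_len(nrow(m)), cyc), function(idx) {
    data.frame(cycle = cyc[idx[1]],
               velocity = mean(m$mean_speed[idx]),
               pressure = mean(m$mean_p[idx]),
               probe_velocity = mean(m$probe_speed[idx]))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Cycle-to-cycle relative convergence errors
#'
#' For each cycle's summary value \eqn{v_B} the relative error against the
#' reference cycle's value \eqn{v_L} is
#' \eqn{E = |(v_B - v_L)/v_L| \cdot 100\%}. The first cycle whose errors on
#' all quantities fall at or below `threshold` is flagged.
#'
#' @param summaries data frame with a `cycle` column plus one column per
#'   quantity (e.g. from [cycle_summaries()]), or a plain numeric vector of
#'   per-cycle values.
#' @param ref_cycle reference cycle index; default the last cycle.
#' @param threshold acceptance threshold [%] used for the flag.
#' @return Data frame of class `convergence_table` with columns `cycle`,
#'   `quantity`, `value`, `E` (percent), and attribute `converged_cycle`
#'   (NA if none qualifies).
#' @export
check_temporal_convergence <- function(summaries, ref_cycle = NULL,
                                       threshold = 5) {
  if (is.numeric(summaries) && is.null(dim(summaries))) {
    summaries <- data.frame(cycle = seq_along(summaries), value = summaries)
  }
  if (nrow(summaries) < 2L) {
    stop("need at least two cycles for a convergence check", call. = FALSE)
  }
  ref_cycle <- ref_cycle %||% max(summaries$cycle)
  qcols <- setdiff(names(summaries), "cycle")
  ref_row <- summaries[summaries$cycle == ref_cycle, , drop = FALSE]
  if (nrow(ref_row) != 1L) stop("reference cycle not found", call. = FALSE)
  out <- list()
  for (q in qcols) {
    vL <- ref_row[[q]]
    if (vL == 0) {
      stop(sprintf("reference value for '%s' is zero: relative error undefined", q),
           call. = FALSE)
    }
    out[[q]] <- data.frame(cycle = summaries$cycle, quantity = q,
                           value = summaries[[q]],
                           E = abs((summaries[[q]] - vL) / vL) * 100)
  }
  tab <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  byc <- split(tab$E, tab$cycle)
  ok <- vapply(byc, function(e) all(e <= threshold), logical(1))
  conv <- suppressWarnings(min(as.numeric(names(byc))[ok]))
  attr(tab, "converged_cycle") <- if (is.finite(conv)) conv else NA_real_
  attr(tab, "ref_cycle") <- ref_cycle
  class(tab) <- c("convergence_table", "data.frame")
  tab
}
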