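# shared fixtures; expensive solver runs are memoised across test files
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# plane-Poiseuille verification case: Newtonian test fluid with nu = 0.01
# m^2/s so the start-up transient decays within H^2/nu of simulated time
poiseuille_case <- function(ny) {
  memo(paste0("poiseuille_", ny), {
    props <- fluid_properties(rho = 1, model = "newtonian", mu_newt = 0.01)
    H <- 0.02; G <- 1
    geom <- channel_geometry(H = H, ny = ny, nx = 4, dpdx = G)
    t_end <- H^2 / (props$mu_newt / props$rho)
    run <- solve_transient(geom, props, waveform = NULL,
                           settings = solver_settings(dt = 1e-3,
                                                      t_end = t_end,
                                                      snapshot_stride = 1e9))
    U <- G * H^2 / (8 * props$mu_newt)
    prof <- run$u[1, ]
    snap <- run$snapshots[[length(run$snapshots)]]
    wss <- wall_shear_stress(snap, "ymin", props)$average
    wss_an <- 4 * props$mu_newt * U / H
    Q <- sum(prof) * geom$h
    Q_an <- 2 / 3 * U * H
    list(run = run, props = props, geom = geom, H = H, U = U, snap = snap,
         err_Q = abs(Q - Q_an) / Q_an,
         err_wss = abs(wss - wss_an) / wss_an,
         err_umax = abs(max(prof) - U * (1 - 1 / ny^2)) / U)
  })
}

# one-cycle chamber run with the step-with-side-holes catheter (full phase
# tracking machinery: multiple venous sub-patches, arterial monitor)
chamber_run_A <- function() {
  memo("chamber_A", {
    solve_transient(chamber_geometry(), fluid_properties(),
                    build_default_waveform(), catheter_config("A"),
                    solver_settings(n_cycles = 1, snapshot_stride = 40))
  })
}

# brute-force facet-loop recirculation oracle, written directly from the
# mass-weighted-average definition (independent of the package path)
rf_brute_force <- function(ps, rho = 1060) {
  t <- ps$time
  keep <- which(t >= t[length(t)] - ps$T - 1e-9)
  num <- 0; den <- 0
  for (k in seq_len(ncol(ps$phi))) {
    phi_int <- 0; un_int <- 0
    for (i in keep[-length(keep)]) {
      dt <- t[i + 1] - t[i]
      phi_int <- phi_int + dt * (ps$phi[i, k] + ps$phi[i + 1, k]) / 2
      un_int <- un_int + dt * (ps$un[i, k] + ps$un[i + 1, k]) / 2
    }
    dur <- t[keep[length(keep)]] - t[keep[1]]
    mdot_k <- rho * (un_int / dur) * ps$area[k]
    num <- num + (phi_int / dur) * mdot_k
    den <- den + mdot_k
  }
  num / den * 100
}

# minimal ASCII STL cube fixture written on the fly
write_cube_stl <- function(path) {
  tri <- function(a, b, c) {
    c("  facet normal 0 0 0", "    outer loop",
      paste("      vertex", paste(a, collapse = " ")),
      paste("      vertex", paste(b, collapse = " ")),
      paste("      vertex", paste(c, collapse = " ")),
      "    endloop", "  endfacet")
  }
  quads <- list(
    list(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
    list(c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)),
    list(c(0, 0, 0), c(1, 0, 0), c(1, 0, 1), c(0, 0, 1)),
    list(c(0, 1, 0), c(1, 1, 0), c(1, 1, 1), c(0, 1, 1)),
    list(c(0, 0, 0), c(0, 1, 0), c(0, 1, 1), c(0, 0, 1)),
    list(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1), c(1, 0, 1)))
  lines <- "solid cube"
  for (q in quads) {
    lines <- c(lines, tri(q[[1]], q[[2]], q[[3]]), tri(q[[1]], q[[3]], q[[4]]))
  }
  writeLines(c(lines, "endsolid cube"), path)
  path
}
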