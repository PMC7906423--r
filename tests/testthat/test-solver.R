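test_that("a quiescent chamber with zero inlet pressure stays at rest", {
  w0 <- build_default_waveform(mean_p = 0, pulse_amplitude = 0)
  run <- solve_transient(chamber_geometry(), fluid_properties(), w0,
                         settings = solver_settings(n_cycles = 1,
                                                    snapshot_stride = 80))
  expect_identical(max(abs(run$u)), 0)
  expect_identical(max(abs(run$v)), 0)
  s <- run$snapshots[[length(run$snapshots)]]
  expect_identical(max(abs(s$phi)), 0)
})

test_that("pressure-driven channel flow converges to plane Poiseuille", {
  c16 <- poiseuille_case(16)
  expect_lt(c16$err_Q, 0.02)
  expect_lt(c16$err_wss, 0.02)
  expect_lt(c16$err_umax, 0.02)
})

test_that("halving the grid improves the channel solution at the scheme's order", {
  e <- vapply(c(8, 16, 32), function(ny) poiseuille_case(ny)$err_Q, numeric(1))
  expect_gt(e[1] / e[2], 1.7)
  expect_gt(e[2] / e[3], 1.7)
})

test_that("Bird-Carreau with equal plateaus reproduces the Newtonian solution", {
  g <- chamber_geometry(Lx = 0.08, Ly = 0.06, h = 0.004)
  w <- build_default_waveform()
  st <- solver_settings(dt = 1e-3, t_end = 0.05, snapshot_stride = 1e9)
  p_bc <- fluid_properties(mu0 = 0.004, mu_inf = 0.004)
  p_nw <- fluid_properties(model = "newtonian", mu_newt = 0.004)
  r1 <- solve_transient(g, p_bc, w, settings = st)
  r2 <- solve_transient(g, p_nw, w, settings = st)
  scale <- max(abs(r2$u), abs(r2$v))
  expect_lt(max(abs(r1$u - r2$u), abs(r1$v - r2$v)) / scale, 1e-10)
})

test_that("chamber runs conserve mass instantaneously and satisfy continuity", {
  run <- chamber_run_A()
  m <- run$monitors
  # rigid walls: inflow equals outflow at every output step
  expect_lt(max(m$balance), 0.01)
  expect_lt(max(m$residual), run$settings$residual_tol)
})

test_that("the filtered-blood fraction stays in [0, 1] at every step", {
  run <- chamber_run_A()
  expect_gte(min(run$monitors$phi_min), 0)
  expect_lte(max(run$monitors$phi_max), 1)
  # the tracked phase actually enters the chamber
  expect_gt(max(run$monitors$phi_max), 0.1)
})

test_that("identical configuration and seed reproduce the run bit for bit", {
  g <- chamber_geometry(h = 0.004)
  w <- build_default_waveform()
  st <- solver_settings(dt = 1e-3, t_end = 0.1, snapshot_stride = 50)
  r1 <- solve_transient(g, fluid_properties(), w, catheter_config("D"), st)
  r2 <- solve_transient(g, fluid_properties(), w, catheter_config("D"), st)
  expect_identical(r1$u, r2$u)
  expect_identical(r1$v, r2$v)
  expect_identical(r1$monitors, r2$monitors)
})

test_that("the CFL guard aborts without adaptivity and sub-steps with it", {
  g <- chamber_geometry(h = 0.004)
  w <- build_default_waveform()
  expect_error(
    solve_transient(g, fluid_properties(), w, catheter_config("D"),
                    solver_settings(dt = 0.02, t_end = 0.04,
                                    adaptive = FALSE)),
    "cfl_cap")
  r <- solve_transient(g, fluid_properties(), w, catheter_config("D"),
                       solver_settings(dt = 0.02, t_end = 0.04,
                                       adaptive = TRUE, snapshot_stride = 10))
  expect_gt(max(r$monitors$n_sub), 1)
  expect_lt(max(r$monitors$residual), 1e-4)
})

test_that("cycle-to-cycle errors follow the relative-error definition", {
  tab <- check_temporal_convergence(c(10, 10.5), ref_cycle = 2)
  expect_identical(tab$E[2], 0)
  expect_equal(tab$E[1], abs((10 - 10.5) / 10.5) * 100, tolerance = 1e-12)
  expect_equal(round(tab$E[1], 2), 4.76)
  # identical values give zero error everywhere
  expect_true(all(check_temporal_convergence(c(3, 3, 3))$E == 0))
  expect_error(check_temporal_convergence(c(1, 0), ref_cycle = 2), "zero")
  expect_error(check_temporal_convergence(5), "two cycles")
  # scale invariance of the error table
  v <- c(9.5, 10.2, 10.05, 10)
  e1 <- check_temporal_convergence(v)$E
  e2 <- check_temporal_convergence(v * 137.5)$E
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("per-cycle summaries flag the first converged cycle", {
  run <- chamber_run_A()
  cs <- cycle_summaries(run)
  expect_identical(nrow(cs), 1L)
  fake <- data.frame(cycle = 1:4, velocity = c(0.21, 0.2018, 0.2005, 0.2),
                     pressure = c(160, 151.2, 150.4, 150))
  tab <- check_temporal_convergence(fake, threshold = 1)
  expect_identical(attr(tab, "converged_cycle"), 2)
})
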