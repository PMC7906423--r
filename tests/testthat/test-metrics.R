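test_that("vorticity is exact on solid-body rotation and zero on uniform flow", {
  f <- make_field("rigid_rotation", n = c(24, 24), params = list(omega = 5))
  om <- vorticity(f)
  expect_equal(max(abs(om$magnitude - 10)), 0, tolerance = 1e-11)
  fu <- make_field("uniform_jet")
  expect_equal(max(vorticity(fu)$magnitude), 0, tolerance = 1e-14)
})

test_that("vorticity converges at second order on the Taylor-Green vortex", {
  errs <- vapply(c(32, 64), function(n) {
    f <- make_field("taylor_green", n = c(n, n))
    gt <- attr(f, "ground_truth")$wz(f$x, f$y)
    i <- 3:(n - 2)
    max(abs((vorticity(f)$wz - gt)[i, i]))
  }, numeric(1))
  expect_gt(errs[1] / errs[2], 3)
})

test_that("divergence of the discrete curl vanishes in the interior", {
  n <- 16; h <- 2 * pi / n
  x <- (seq_len(n) - 0.5) * h
  grid <- expand.grid(x = x, y = x, z = x)
  mk <- function(u, v, w) {
    field_snapshot(0, x, x, array(u, c(n, n, n)), array(v, c(n, n, n)),
                   w = array(w, c(n, n, n)), z = x, h = h)
  }
  fields <- list(
    make_field("beltrami", n = c(n, n, n)),
    mk(sin(grid$y) * cos(grid$z), sin(grid$z), cos(grid$x) * sin(grid$y)),
    mk(grid$x^2 - grid$y * grid$z, grid$y * grid$x, grid$z * grid$y))
  for (f in fields) {
    om <- vorticity(f)
    dv <- atriaflow:::d_dx_centered(om$wx, f$h) +
      atriaflow:::d_dy_centered(om$wy, f$h) +
      atriaflow:::d_dz_centered(om$wz, f$h)
    i <- 2:(n - 1)
    expect_lt(max(abs(dv[i, i, i])), 1e-10)
  }
})

test_that("helicity density is zero for planar and rigid-body flow, |u|^2 for Beltrami", {
  f2 <- make_field("taylor_green", n = c(16, 16))
  expect_identical(max(abs(helicity_density(f2))), 0)
  fb <- make_field("beltrami", n = c(24, 24, 24))
  hel <- helicity_density(fb)
  gt <- attr(fb, "ground_truth")$helicity
  i <- 3:22
  expect_lt(max(abs(hel - gt)[i, i, i]) / max(abs(gt)), 0.02)
})

test_that("strain magnitude reduces to the 1-D law on simple shear and vanishes in rotation", {
  f <- make_field("simple_shear", params = list(gamma0 = 100))
  ss <- strain_and_stress(f)
  expect_equal(max(abs(ss$magnitude - 100)), 0, tolerance = 1e-9)
  mu100 <- apparent_viscosity(100, fluid_properties())
  expect_equal(unique(round(as.vector(ss$tau), 10)), round(mu100 * 100, 10))
  fr <- make_field("rigid_rotation", params = list(omega = 7))
  sr <- strain_and_stress(fr)
  expect_equal(max(abs(sr$magnitude)), 0, tolerance = 1e-9)
  expect_equal(max(sr$tau), 0, tolerance = 1e-9)
})

test_that("strain assembly matches the brute-force tensor oracle on random linear fields", {
  for (seed in 1:5) {
    f <- make_field("random_linear", seed = seed)
    gt <- attr(f, "ground_truth")
    ss <- strain_and_stress(f)
    # brute force: assemble the tensor directly from the known coefficients
    S <- gt$strain_tensor
    mag <- sqrt(2 * (S[1, 1]^2 + S[2, 2]^2 + 2 * S[1, 2]^2))
    expect_lt(max(abs(ss$magnitude - mag)), 1e-10)
    expect_lt(max(abs(vorticity(f)$wz - gt$vorticity_z)), 1e-10)
  }
})

test_that("wall shear stress is exact on sampled Poiseuille and linear in viscosity", {
  f <- make_field("poiseuille", params = list(U_max = 0.5, H = 0.02,
                                              mu = 0.004))
  pn <- fluid_properties(model = "newtonian", mu_newt = 0.004)
  w <- wall_shear_stress(f, "ymin", pn)
  expect_equal(w$average, 0.4, tolerance = 1e-12)
  expect_equal(wall_shear_stress(f, "ymax", pn)$average, 0.4,
               tolerance = 1e-12)
  p2 <- fluid_properties(model = "newtonian", mu_newt = 0.008)
  expect_equal(wall_shear_stress(f, "ymin", p2)$average, 0.8,
               tolerance = 1e-12)
  f0 <- make_field("uniform_jet", params = list(speed_x = 0, speed_y = 0))
  expect_identical(wall_shear_stress(f0, "ymin", pn)$average, 0)
})

test_that("boundary flow rates follow u.A in ml/s", {
  d <- data.frame(velocity = 0.1, area = 2e-4)
  expect_equal(boundary_flow_rate(d), 20)
  d0 <- data.frame(velocity = numeric(0), area = numeric(0))
  expect_error(boundary_flow_rate(d0), "empty")
  expect_error(boundary_flow_rate(data.frame(u = 1)), "velocity")
})

test_that("recirculation fraction equals the facet-loop oracle and hand arithmetic", {
  # two facets, mdot (1, 3) kg/s, phi (1, 0) -> 25 %
  t <- seq(0, 0.8, length.out = 21)
  mk_ps <- function(phi_k, un_k, area) {
    atriaflow:::patch_series("p", t,
                             matrix(rep(phi_k, each = 21), ncol = 2),
                             matrix(rep(un_k, each = 21), ncol = 2),
                             area, 0.8)
  }
  rho <- 1000
  area <- c(1e-3, 1e-3)
  un <- c(1, 3) / (rho * area)
  ps <- mk_ps(c(1, 0), un, area)
  expect_equal(recirculation_fraction(ps, rho)$Rf, 25, tolerance = 1e-12)
  # random heterogeneous patterns match the brute-force loop
  for (seed in 1:4) {
    ps <- make_phase_pattern(Rf = runif(1, 5, 95), K = 5, seed = seed)
    got <- recirculation_fraction(ps, 1060)$Rf
    expect_equal(got, rf_brute_force(ps, 1060), tolerance = 1e-12)
  }
})

test_that("recirculation fraction is invariant to density rescaling and facet order", {
  ps <- make_phase_pattern(Rf = 40, K = 6, seed = 9)
  r1 <- recirculation_fraction(ps, 1060)$Rf
  expect_identical(r1, recirculation_fraction(ps, 531)$Rf)
  perm <- c(4, 2, 6, 1, 5, 3)
  ps2 <- atriaflow:::patch_series("p", ps$time, ps$phi[, perm],
                                  ps$un[, perm], ps$area[perm], ps$T)
  expect_equal(recirculation_fraction(ps2, 1060)$Rf, r1, tolerance = 1e-12)
  # degenerate all-0 / all-1 patterns and zero mass flow
  ps0 <- make_phase_pattern(Rf = 0, K = 3, seed = 1)
  expect_identical(max(abs(ps0$phi)), 0)
  expect_equal(recirculation_fraction(ps0)$Rf, 0)
  ps1 <- make_phase_pattern(Rf = 100, K = 3, seed = 1)
  expect_equal(recirculation_fraction(ps1)$Rf, 100)
  psz <- ps
  psz$un[] <- 0
  expect_error(recirculation_fraction(psz), "zero")
})

test_that("tip statistics integrate the prism and are monotone in the threshold", {
  # synthetic snapshots with a controlled gamma_dot field
  h <- 0.002; nx <- 40; ny <- 30
  x <- (seq_len(nx) - 0.5) * h; y <- (seq_len(ny) - 0.5) * h
  mk_snap <- function(time, gd) {
    field_snapshot(time, x, y, matrix(0, nx, ny), matrix(0, nx, ny),
                   gamma_dot = gd, h = h)
  }
  pn <- fluid_properties(model = "newtonian", mu_newt = 1)  # tau == gamma
  tip <- tip_volume(10, 10, 6)
  anchor <- c(0.04, 0.06)
  # uniform tau = 5 Pa
  snaps <- lapply(seq(0, 0.8, by = 0.2), function(tt)
    mk_snap(tt, matrix(5, nx, ny)))
  ts <- tip_statistics(snaps, tip, pn, anchor = anchor, T = 0.8)
  expect_equal(ts$tau_bar_avg, 5)
  expect_identical(ts$frac_above_avg, 0)
  # half the prism at 20, half at 0 -> mean 10, fraction 50 %
  gd <- matrix(0, nx, ny)
  gd[x <= 0.04, ] <- 20
  snaps2 <- lapply(seq(0, 0.8, by = 0.2), function(tt) mk_snap(tt, gd))
  ts2 <- tip_statistics(snaps2, tip_volume(10, 8, 6), pn,
                        anchor = c(0.04, 0.06), T = 0.8)
  expect_equal(ts2$tau_bar_avg, 10)
  expect_equal(ts2$frac_above_avg, 50)
  # brute-force cell loop on a random field
  set.seed(5)
  gdr <- matrix(runif(nx * ny, 0, 30), nx, ny)
  snaps3 <- lapply(c(0, 0.4, 0.8), function(tt) mk_snap(tt, gdr))
  ts3 <- tip_statistics(snaps3, tip, pn, anchor = anchor, T = 0.8)
  in_x <- which(x >= anchor[1] - 5e-3 & x <= anchor[1] + 5e-3)
  in_y <- which(y >= anchor[2] - 10e-3)
  acc <- 0; nc <- 0
  for (i in in_x) for (j in in_y) { acc <- acc + gdr[i, j]; nc <- nc + 1 }
  expect_equal(ts3$tau_bar_avg, acc / nc, tolerance = 1e-12)
  # monotone non-increasing in the threshold
  f1 <- tip_statistics(snaps3, tip, pn, anchor = anchor, T = 0.8,
                       threshold = 5)$frac_above_avg
  f2 <- tip_statistics(snaps3, tip, pn, anchor = anchor, T = 0.8,
                       threshold = 15)$frac_above_avg
  expect_gte(f1, f2)
  expect_error(tip_statistics(snaps3, tip, pn, anchor = c(10, 10), T = 0.8),
               "outside")
})

test_that("time averaging, Pearson correlation and percent change behave as defined", {
  ts <- time_series("c", seq(0, 0.8, by = 0.1), rep(4.2, 9), 0.8)
  expect_identical(time_average(ts), 4.2)
  set.seed(3)
  x <- rnorm(200); y <- rnorm(200)
  expect_equal(pearson_r(x, x), 1, tolerance = 1e-12)
  expect_equal(pearson_r(x, -x), -1, tolerance = 1e-12)
  # affine invariance
  expect_equal(pearson_r(2.5 * x - 3, y), pearson_r(x, y), tolerance = 1e-12)
  expect_equal(pearson_r(x, -0.4 * y + 7), -pearson_r(x, y),
               tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 10), x[1:10]), "zero-variance")
  expect_equal(percent_change(57.20, 44.10), 29.71, tolerance = 1e-3)
  expect_equal(percent_change(6.45, 9.32), -30.79, tolerance = 1e-3)
  expect_error(percent_change(1, 0), "zero")
})

test_that("the report table keeps input order, passes values through and marks absences", {
  res <- list(RA = list(vorticity = 44.1, wss = 1.89),
              D1 = list(Rf = 0.26, vorticity = 55.8, wss = 2.15,
                        tip_shear = 11.6, tip_volume_pct = 28.7))
  rep <- build_report(res)
  expect_identical(rep$model, c("RA", "D1"))
  expect_true(is.na(rep$Rf[1]))
  expect_identical(rep$Rf[2], 0.26)
  expect_identical(rep$vorticity, c(44.1, 55.8))
  txt <- capture.output(print(rep))
  expect_true(any(grepl("-", txt, fixed = TRUE)))
  empty <- build_report(list())
  expect_identical(nrow(empty), 0L)
  md <- report_markdown(rep)
  expect_match(md[1], "Model")
  expect_length(md, 4)
})
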