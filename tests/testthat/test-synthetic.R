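test_that("every generator is reproducible under a fixed seed", {
  for (kind in c("poiseuille", "rigid_rotation", "taylor_green",
                 "uniform_jet", "simple_shear", "random_linear")) {
    f1 <- make_field(kind, seed = 7)
    f2 <- make_field(kind, seed = 7)
    expect_identical(f1$u, f2$u)
    expect_identical(f1$v, f2$v)
  }
  b1 <- make_field("beltrami", n = c(12, 12, 12), seed = 1)
  b2 <- make_field("beltrami", n = c(12, 12, 12), seed = 1)
  expect_identical(b1$w, b2$w)
  p1 <- make_phase_pattern(Rf = 30, seed = 5)
  p2 <- make_phase_pattern(Rf = 30, seed = 5)
  expect_identical(p1$phi, p2$phi)
  s1 <- make_pulsatile_series(seed = 3)
  s2 <- make_pulsatile_series(seed = 3)
  expect_identical(s1$velocity$values, s2$velocity$values)
})

test_that("ground-truth closures agree with numerical differentiation of the samples", {
  f <- make_field("poiseuille", params = list(U_max = 0.5, H = 0.02,
                                              mu = 0.004))
  gt <- attr(f, "ground_truth")
  expect_equal(gt$wss, 0.4)
  pn <- fluid_properties(model = "newtonian", mu_newt = gt$mu)
  expect_equal(wall_shear_stress(f, "ymin", pn)$average, gt$wss,
               tolerance = 1e-10)
  fr <- make_field("rigid_rotation", params = list(omega = 5))
  expect_equal(max(abs(vorticity(fr)$magnitude -
                         attr(fr, "ground_truth")$vorticity_mag)), 0,
               tolerance = 1e-10)
  # Taylor-Green is divergence-free: sampled divergence is O(h^2)
  ft <- make_field("taylor_green", n = c(48, 48))
  dv <- atriaflow:::d_dx_centered(ft$u, ft$h) +
    atriaflow:::d_dy_centered(ft$v, ft$h)
  i <- 3:46
  expect_lt(max(abs(dv[i, i])), (ft$h)^2)
})

test_that("planted recirculation fractions are recovered exactly", {
  for (rf in c(0, 25, 100)) {
    ps <- make_phase_pattern(Rf = rf, K = 7, seed = 2)
    expect_equal(recirculation_fraction(ps)$Rf, rf, tolerance = 1e-9)
  }
  expect_error(make_phase_pattern(Rf = 120), "\\[0, 100\\]")
  # facet traces stay inside the physical range
  ps <- make_phase_pattern(Rf = 85, K = 9, seed = 3)
  expect_gte(min(ps$phi), 0)
  expect_lte(max(ps$phi), 1)
})

test_that("planted convergence-error sequences are recovered exactly", {
  planted <- list(velocity = c(5, 2, 0), pressure = c(8, 3.5, 0))
  ser <- make_pulsatile_series(planted,
                               ref_values = c(velocity = 0.192,
                                              pressure = 157),
                               seed = 6)
  cyc <- atriaflow:::cycle_index(ser$velocity$t, 0.8)
  agg <- stats::aggregate(data.frame(velocity = ser$velocity$values,
                                     pressure = ser$pressure$values),
                          list(cycle = cyc), mean)
  tab <- check_temporal_convergence(agg, ref_cycle = 3)
  for (q in names(planted)) {
    expect_equal(tab$E[tab$quantity == q], planted[[q]], tolerance = 1e-9)
  }
  # a single repeated constant cycle gives zero error everywhere
  flat <- make_pulsatile_series(list(velocity = c(0, 0, 0)), seed = 1)
  aggf <- stats::aggregate(flat$velocity$values,
                           list(cycle = atriaflow:::cycle_index(flat$velocity$t, 0.8)),
                           mean)
  expect_true(all(abs(check_temporal_convergence(aggf$x)$E) < 1e-9))
  expect_error(make_pulsatile_series(list(velocity = c(-1, 0))), "non-negative")
  expect_error(make_pulsatile_series(list(velocity = c(1, 1))), "must be 0")
})

test_that("the Gaussian mixing construction plants the target correlation", {
  ser <- make_pulsatile_series(target_r = 0.5, n_pair = 1000, seed = 4)
  expect_equal(pearson_r(ser$pair_a, ser$pair_b), 0.5, tolerance = 0.02)
  # near-zero target at large n stays within the CLT bound
  s0 <- make_pulsatile_series(target_r = 0, n_pair = 1e5, seed = 8)
  expect_lt(abs(pearson_r(s0$pair_a, s0$pair_b)), 0.02)
  expect_error(make_pulsatile_series(target_r = 1.2), "\\(-1, 1\\)")
})
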