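test_that("mesh convergence applies the 0.5 %% WSS and 3 %% probe thresholds", {
  # identical levels: all errors zero, everything passes
  same <- data.frame(n_elements = c(1e5, 5e5, 1e6),
                     probe_velocity = 0.2, avg_wss = 1.9)
  tab <- mesh_convergence(same)
  expect_true(all(tab$E_probe == 0) && all(tab$E_wss == 0))
  expect_identical(attr(tab, "pass_level"), 1e5)

  # WSS errors (0.4 %, 0.6 %) at probe error 2 %: only the 0.4 % level passes
  lv <- data.frame(n_elements = c(1e5, 5e5, 2e6),
                   probe_velocity = c(0.204, 0.204, 0.2),
                   avg_wss = c(1.9 * 1.006, 1.9 * 1.004, 1.9))
  tab2 <- mesh_convergence(lv)
  expect_identical(tab2$pass, c(FALSE, TRUE, TRUE))
  expect_identical(attr(tab2, "pass_level"), 5e5)

  # a published-style refinement table passes only above a million elements
  s6 <- data.frame(
    n_elements = c(2e5, 5e5, 8e5, 1.14e6, 2.1e6),
    probe_velocity = c(0.23, 0.212, 0.208, 0.201, 0.2),
    avg_wss = c(1.95, 1.93, 1.915, 1.905, 1.9))
  tab3 <- mesh_convergence(s6)
  expect_identical(attr(tab3, "pass_level"), 1.14e6)
  expect_false(any(tab3$pass[s6$n_elements < 1e6]))

  expect_error(mesh_convergence(same[1, ]), "two")
  zero <- data.frame(n_elements = 1:2, probe_velocity = c(1, 0),
                     avg_wss = c(1, 1))
  expect_error(mesh_convergence(zero), "zero")
})

test_that("validation bands use closed intervals and report rather than assert", {
  bands <- default_validation_bands()
  res <- validate_bands(c(vorticity = 44.1), bands)
  expect_identical(res$status, "inside")
  # value at the band edge is inside
  res2 <- validate_bands(c(vorticity = 54, velocity = 0.147), bands)
  expect_identical(res2$status, c("inside", "inside"))
  res3 <- validate_bands(c(vorticity = 60), bands)
  expect_identical(res3$status, "outside")
  expect_warning(res4 <- validate_bands(c(vorticity = NaN), bands), "finite")
  expect_identical(res4$status, "unchecked")
  res5 <- validate_bands(c(unheard_of = 1), bands)
  expect_identical(res5$status, "unchecked")
})

test_that("supplementary recomputation recovers every planted statistic", {
  dir <- withr::local_tempdir()
  make_supplementary_mock(dir, seed = 11)
  res <- recompute_supplementary(dir)
  expect_equal(res$pearson_wss_vorticity, 0.87, tolerance = 1e-9)
  expect_equal(res$velocity_error_pct, 1.28, tolerance = 1e-9)
  expect_equal(res$pressure_error_pct, 4.12, tolerance = 1e-9)
  expect_equal(res$vorticity_cycle_avg, 44.1, tolerance = 1e-9)
  expect_equal(res$flow_peak_IVC, 106, tolerance = 1e-9)
  expect_equal(res$flow_peak_SVC, 120, tolerance = 1e-9)
  expect_equal(res$tip_shear_A1, 12.90, tolerance = 1e-9)
  expect_equal(res$vorticity_avg_B, 57.20, tolerance = 1e-9)
})

test_that("schema violations and degenerate series surface as clean errors", {
  dir <- withr::local_tempdir()
  utils::write.csv(data.frame(time = 1:3, wss = 1:3),
                   file.path(dir, "s11_broken.csv"), row.names = FALSE)
  expect_error(recompute_supplementary(list(s11 = file.path(dir, "s11_broken.csv"))),
               "vorticity")
  # constant pair: correlation undefined, surfaced cleanly
  t <- seq(0.008, 3.2, by = 0.008)
  utils::write.csv(data.frame(time = t, wss = 1, vorticity = 1 + 0 * t),
                   file.path(dir, "s11_const.csv"), row.names = FALSE)
  expect_error(recompute_supplementary(list(s11 = file.path(dir, "s11_const.csv"))),
               "zero-variance")
  expect_error(recompute_supplementary(list()), "no recognised")
})

test_that("statistics recomputed from generator output match the plants across seeds", {
  for (seed in c(2, 17)) {
    dir <- withr::local_tempdir()
    make_supplementary_mock(dir, seed = seed, pearson = 0.5,
                            vorticity_avg = 40)
    res <- recompute_supplementary(dir)
    expect_equal(res$pearson_wss_vorticity, 0.5, tolerance = 0.02)
    expect_equal(res$vorticity_cycle_avg, 40, tolerance = 1e-9)
  }
})
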