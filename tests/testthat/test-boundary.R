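test_that("cardiac cycle defaults to 0.8 = 0.5 + 0.3 and enforces additivity", {
  cyc <- cardiac_cycle()
  expect_identical(cyc$period, 0.8)
  expect_identical(cyc$diastole, 0.5)
  expect_identical(cyc$systole, 0.3)
  cyc2 <- cardiac_cycle(0.62, 0.41)
  expect_equal(cyc2$period, 0.62 + 0.41)
  expect_error(cardiac_cycle(-0.1, 0.3), "positive")
})

test_that("default waveform has the prescribed period and mean pressure", {
  w <- build_default_waveform()
  expect_equal(w$t[length(w$t)] - w$t[1], 0.8)
  mean_mmHg <- atriaflow:::trapz_mean(w$t, w$p) / 133.322
  expect_equal(mean_mmHg, 3, tolerance = 0.01)
  # two-peaked morphology: at least two local maxima over one period
  p <- w$p[-length(w$p)]
  peaks <- sum(diff(sign(diff(c(p[length(p)], p, p[1])))) < 0)
  expect_gte(peaks, 2)
  # amplitude 0 collapses onto the constant mean
  w0 <- build_default_waveform(mean_p = 2, pulse_amplitude = 0)
  expect_true(all(abs(w0$p - 2 * 133.322) < 1e-9))
  # arbitrary valid cycles preserve period = diastole + systole
  for (dd in c(0.45, 0.55)) {
    wc <- build_default_waveform(cardiac_cycle(dd, 0.3))
    expect_equal(wc$cycle$period, dd + 0.3)
    expect_equal(wc$t[length(wc$t)], dd + 0.3)
  }
})

test_that("waveform sampling is exactly periodic and exact at grid points", {
  w <- build_default_waveform()
  expect_identical(sample_waveform(w, 0), sample_waveform(w, 0.8))
  set.seed(1)
  t0 <- runif(1000, 0, 0.8)
  for (k in c(1, 3, 7)) {
    expect_equal(sample_waveform(w, t0 + k * 0.8), sample_waveform(w, t0),
                 tolerance = 1e-12)
  }
  # brute-force modular lookup at grid points
  i <- c(1, 40, 161)
  expect_equal(sample_waveform(w, w$t[i] + 2 * 0.8), w$p[i])
  expect_error(sample_waveform(w, -0.1), "non-negative")
  ws <- build_default_waveform(interpolation = "periodic_spline")
  expect_equal(sample_waveform(ws, ws$t[i]), ws$p[i], tolerance = 1e-9)
})

test_that("waveforms outside the physiological band are rejected", {
  expect_error(build_default_waveform(mean_p = 9), "band")
  cyc <- cardiac_cycle()
  t <- seq(0, 0.8, length.out = 11)
  expect_error(inlet_waveform(cyc, t, rep(10 * 133.322, 11)), "band")
  expect_error(inlet_waveform(cyc, t, seq(0, 400, length.out = 11)),
               "periodic")
})

test_that("unit conversions are exact, linear and invertible", {
  expect_equal(convert_units(1, "Fr_to_mm"), 0.33)
  expect_equal(convert_units(15.5, "Fr_to_mm"), 5.115)
  expect_identical(convert_units(0, "mmHg_to_Pa"), 0)
  expect_equal(convert_units(1, "mmHg_to_Pa"), 133.322)
  expect_equal(convert_units(400, "mlmin_to_m3s"), 400e-6 / 60)
  set.seed(2)
  x <- runif(50, -500, 500)
  for (pair in list(c("mmHg_to_Pa", "Pa_to_mmHg"),
                    c("mlmin_to_m3s", "m3s_to_mlmin"),
                    c("Fr_to_mm", "mm_to_Fr"))) {
    back <- convert_units(convert_units(x, pair[1]), pair[2])
    expect_equal(back, x, tolerance = 1e-12)
  }
  expect_error(convert_units(1, "furlongs"), "unknown")
  expect_error(convert_units(Inf, "Fr_to_mm"), "finite")
})

test_that("operating points carry the clinical defaults and reject inverted pressures", {
  op <- catheter_operating_point()
  expect_identical(op$venous_flow, 400)
  expect_identical(op$venous_gauge_pressure, 248)
  expect_error(catheter_operating_point(arterial_gauge_pressure = 300),
               "below")
})

test_that("waveform CSV round trips in both declared units", {
  w <- build_default_waveform(n_samples = 81)
  for (unit in c("mmHg", "Pa")) {
    f <- withr::local_tempfile(fileext = ".csv")
    write_waveform_csv(w, f, unit = unit)
    w2 <- read_waveform_csv(f)
    expect_equal(w2$p, w$p, tolerance = 1e-9)
  }
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time = 1:3, pressure = 1:3), f2,
                   row.names = FALSE)
  expect_error(read_waveform_csv(f2), "pressure_Pa")
})
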