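test_that("chamber ports carry their physiological areas exactly", {
  g <- chamber_geometry()
  expect_equal(g$patches$svc$area, pi * 17.06e-3^2 / 4, tolerance = 1e-12)
  expect_equal(g$patches$ivc$area, pi * 16.89e-3^2 / 4, tolerance = 1e-12)
  expect_equal(g$patches$tv$area, 9.95e-4, tolerance = 1e-12)
  expect_equal(g$b0 * g$Lx * g$Ly, 175.27e-6, tolerance = 1e-12)
  # facet areas sum to the patch area
  for (nm in names(g$patches)) {
    fac <- atriaflow:::patch_facets(g, nm)
    expect_equal(sum(fac$area), g$patches[[nm]]$area, tolerance = 1e-12)
    expect_true(all(abs(fac$nx^2 + fac$ny^2 - 1) < 1e-12))
  }
})

test_that("catheter placement produces the clinical jet speed and per-design patches", {
  # 400 ml/min across 7.8 mm^2
  expect_equal(lumen_jet_speed(400, 7.8), 0.8547, tolerance = 1e-4)
  g <- chamber_geometry()
  gD <- place_catheter(g, catheter_config("D"))
  expect_equal(gD$jet_speed, 0.8547009, tolerance = 1e-6)
  expect_equal(gD$patches$cath_venous$area, 7.8e-6, tolerance = 1e-12)
  # design B has no side-hole sub-patches, A has side_hole_count of them
  gB <- place_catheter(g, catheter_config("B"))
  expect_length(grep("cath_side", names(gB$patches)), 0)
  gA <- place_catheter(g, catheter_config("A"))
  expect_length(grep("cath_side", names(gA$patches)), 2)
  # A's venous sub-patches split the lumen area in the flow proportions
  expect_equal(gA$patches$cath_venous$area, 7.8e-6 * 0.5, tolerance = 1e-12)
  expect_equal(gA$patches$cath_side_1$area, 7.8e-6 * 0.25, tolerance = 1e-12)
})

test_that("tip positions translate or mirror the tip and respect design symmetry", {
  g <- chamber_geometry()
  g1 <- place_catheter(g, catheter_config("A", tip_position = "position1"))
  g2 <- place_catheter(g, catheter_config("A", tip_position = "position2"))
  f1 <- atriaflow:::patch_facets(g1, "cath_venous")
  f2 <- atriaflow:::patch_facets(g2, "cath_venous")
  # position2 only translates the tip (same size, shifted toward the wall)
  expect_identical(nrow(f1), nrow(f2))
  expect_gt(mean(f2$x), mean(f1$x))
  g3 <- place_catheter(g, catheter_config("A", tip_position = "position3"))
  f3v <- atriaflow:::patch_facets(g3, "cath_venous")
  f3a <- atriaflow:::patch_facets(g3, "cath_arterial")
  f1a <- atriaflow:::patch_facets(g1, "cath_arterial")
  # rotation mirrors the venous/arterial ordering about the tip axis
  expect_equal(sign(mean(f3v$x) - mean(f3a$x)),
               -sign(mean(f1$x) - mean(f1a$x)))
  expect_error(catheter_config("D", tip_position = "position3"), "symmetric")
  expect_error(catheter_config("B", side_hole_count = 2), "design A")
})

test_that("per-design dimensions follow the catalogue", {
  dims <- list(A = c(290, 15.5, 7.8), B = c(290, 15.5, 7.8),
               C = c(152, 15, 3.5), D = c(240, 16, 7.8))
  flows <- c(A = 350, B = 380, C = 360, D = 370)
  press <- c(A = -250, B = -250, C = -250, D = -188)
  for (d in names(dims)) {
    cc <- catheter_config(d)
    expect_identical(cc$tip_length, dims[[d]][1])
    expect_identical(cc$outer_diameter, dims[[d]][2])
    expect_identical(cc$lumen_area, dims[[d]][3])
    expect_identical(cc$operating$arterial_flow, unname(flows[d]))
    expect_identical(cc$operating$arterial_gauge_pressure, unname(press[d]))
  }
  # step designs run in reverse mode by default, C and D standard
  expect_identical(catheter_config("A")$operating$mode, "reverse")
  expect_identical(catheter_config("D")$operating$mode, "standard")
})

test_that("tip volumes default to the per-design prisms", {
  expect_equal(unlist(catheter_config("A")$tip[c("length", "width", "height")]),
               c(length = 4.5, width = 25, height = 6))
  expect_equal(unlist(catheter_config("B")$tip[c("length", "width", "height")]),
               c(length = 8, width = 10, height = 6))
  expect_equal(unlist(catheter_config("C")$tip[c("length", "width", "height")]),
               c(length = 7, width = 7, height = 7))
  expect_equal(unlist(catheter_config("D")$tip[c("length", "width", "height")]),
               c(length = 13, width = 9, height = 5.5))
  expect_error(tip_volume(0, 1, 1), "positive")
})

test_that("overlapping or out-of-domain patches are rejected", {
  g <- chamber_geometry()
  expect_error(atriaflow:::add_slot_patch(g, "bad", "xmin", 0.045, 0.02,
                                          kind = "wall"),
               "overlap")
  expect_error(atriaflow:::add_slot_patch(g, "bad", "ymin", 0.3, 0.01,
                                          kind = "wall"),
               "outside|fit")
})
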