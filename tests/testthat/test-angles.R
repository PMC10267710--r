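test_that("the bone frame is anchored at DTC with axes from the named landmarks", {
  lms <- tibia_landmarks(list(
    TRCAx_med = c(-15, 10, 95), TRCAx_lat = c(15, 10, 95),
    TACAx_med = c(-10, -5, 5), TACAx_lat = c(10, -5, 5),
    DTC = c(0, 0, 0), PTC = c(0, 0, 100)
  ), side = "right")
  fr <- build_bone_frame(lms)
  expect_equal(fr$origin, c(0, 0, 0), ignore_attr = TRUE)
  expect_equal(fr$ez, c(0, 0, 1))
  expect_equal(fr$ey, c(1, 0, 0))
  expect_equal(fr$ex, c(0, -1, 0))
  # the retrocondylar axis enters only through its direction
  lifted <- lms$landmarks
  lifted[c("TRCAx_med", "TRCAx_lat"), 3] <- lifted[c("TRCAx_med", "TRCAx_lat"), 3] + 7
  fr2 <- build_bone_frame(tibia_landmarks(lifted, side = "right"))
  expect_equal(fr2$ey, fr$ey)
  expect_equal(fr2$ex, fr$ex)
  # a longitudinal component of the retrocondylar direction is removed
  tilted <- lms$landmarks
  tilted["TRCAx_lat", ] <- tilted["TRCAx_med", ] + c(30, 0, 9)
  fr3 <- build_bone_frame(tibia_landmarks(tilted, side = "right"))
  expect_equal(fr3$ey, c(1, 0, 0), tolerance = 1e-12)
  # retrocondylar axis parallel to the shaft axis is degenerate
  degen <- lms$landmarks
  degen["TRCAx_lat", ] <- degen["TRCAx_med", ] + c(0, 0, 20)
  expect_error(build_bone_frame(tibia_landmarks(degen, side = "right")),
               class = "tibia3d_degenerate_frame")
})

test_that("torsion readouts are 180-neutral with external rotation positive", {
  t <- tibia_template()
  expect_equal(tibial_torsion_angle(t)$readout, 180)
  expect_identical(tibial_torsion_angle(t)$direction, "neutral")
  ext <- tibial_torsion_angle(apply_torsion(t, 25))
  expect_equal(ext$readout, 205, tolerance = 1e-9)
  expect_identical(ext$direction, "external")
  int <- tibial_torsion_angle(apply_torsion(t, -40))
  expect_equal(int$readout, 140, tolerance = 1e-9)
  expect_identical(int$direction, "internal")
})

test_that("varus/valgus readouts are 180-neutral with valgus positive", {
  t <- tibia_template()
  expect_equal(tibial_varus_valgus_angle(t)$readout, 180)
  valgus <- tibial_varus_valgus_angle(apply_frontal_angulation(t, 3.9))
  expect_equal(valgus$readout, 183.9, tolerance = 1e-9)
  expect_identical(valgus$direction, "valgus")
  varus <- tibial_varus_valgus_angle(apply_frontal_angulation(t, -6))
  expect_equal(varus$readout, 174, tolerance = 1e-9)
  expect_identical(varus$direction, "varus")
})

test_that("deformity presets are recovered exactly across the tested range", {
  t <- tibia_template()
  for (theta in seq(-80, 80, by = 20)) {
    expect_equal(tibial_torsion_angle(apply_torsion(t, theta))$readout,
                 180 + theta, tolerance = 1e-9)
  }
  for (phi in seq(-30, 30, by = 10)) {
    expect_equal(tibial_varus_valgus_angle(apply_frontal_angulation(t, phi))$readout,
                 180 + phi, tolerance = 1e-9)
  }
  # pure torsion does not leak into the frontal-plane angle
  for (theta in c(-85, -40, 15, 60)) {
    expect_equal(tibial_varus_valgus_angle(apply_torsion(t, theta))$readout,
                 180, tolerance = 1e-9)
  }
  # combined deformity at the 0.1-degree reporting resolution
  m <- measure_tibia(apply_frontal_angulation(apply_torsion(t, 20), 5))
  expect_equal(round(m$TTA$readout, 1), 200)
  expect_equal(round(m$TVA$readout, 1), 185)
})

test_that("measurements are invariant under rigid repositioning", {
  deformed <- apply_frontal_angulation(apply_torsion(tibia_template(), 28), -7.5)
  ref <- measure_tibia(deformed)
  for (preset in c("oblique15", "oblique45")) {
    posed <- apply_rigid_pose(deformed, preset = preset,
                              translation = c(30, -12, 80))
    m <- measure_tibia(posed)
    expect_equal(m$TTA$readout, ref$TTA$readout, tolerance = 1e-9)
    expect_equal(m$TVA$readout, ref$TVA$readout, tolerance = 1e-9)
  }
  set.seed(21)
  for (i in 1:200) {
    moved <- transform_set(deformed, random_rotation(), rnorm(3, sd = 100))
    m <- measure_tibia(moved)
    expect_equal(m$TTA$readout, ref$TTA$readout, tolerance = 1e-9)
    expect_equal(m$TVA$readout, ref$TVA$readout, tolerance = 1e-9)
  }
})

test_that("mirrored bones with flipped side labels read out identically", {
  right <- apply_frontal_angulation(apply_torsion(tibia_template(), 33), 4.5)
  left <- mirror_set(right)
  mr <- measure_tibia(right)
  ml <- measure_tibia(left)
  expect_equal(ml$TTA$readout, mr$TTA$readout, tolerance = 1e-9)
  expect_equal(ml$TVA$readout, mr$TVA$readout, tolerance = 1e-9)
  expect_identical(ml$TTA$direction, mr$TTA$direction)
  expect_identical(ml$TVA$direction, mr$TVA$direction)
  # and the left template deforms with the same sign convention
  lt <- tibia_template(side = "left")
  expect_equal(tibial_torsion_angle(apply_torsion(lt, 25))$readout, 205,
               tolerance = 1e-9)
  expect_equal(tibial_varus_valgus_angle(apply_frontal_angulation(lt, 3.9))$readout,
               183.9, tolerance = 1e-9)
})

test_that("direction labels switch from neutral at the 0.05-degree threshold", {
  t <- tibia_template()
  expect_identical(tibial_torsion_angle(apply_torsion(t, 0.04))$direction, "neutral")
  expect_identical(tibial_torsion_angle(apply_torsion(t, 0.06))$direction, "external")
  expect_identical(tibial_varus_valgus_angle(apply_frontal_angulation(t, -0.06))$direction,
                   "varus")
})

test_that("the varus/valgus angle requires the joint-surface landmarks", {
  core <- tibia_template()$landmarks[landmark_names("torsion"), ]
  tta_only <- tibia_landmarks(core, side = "right")
  expect_equal(tibial_torsion_angle(tta_only)$readout, 180)
  err <- expect_error(tibial_varus_valgus_angle(tta_only),
                      class = "tibia3d_validation_error")
  expect_match(conditionMessage(err), "LTCC")
})
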