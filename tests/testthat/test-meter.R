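test_that("the annulus image realizes the meter geometry", {
  geom <- meter_geometry()          # radii 0.8 and 11 deg
  ann <- make_annulus_image(geom, side_px = 255, deg_per_px = 0.18)
  centre <- (255 + 1) / 2
  expect_identical(ann[centre, centre], 0)          # blocked field
  mid_px <- centre + round(((geom$a_deg + geom$b_deg) / 2) / 0.18)
  expect_identical(ann[centre, mid_px], 1)          # inside the ring
  ## pixel-count oracle for the mean intensity
  ax <- (seq_len(255) - centre) * 0.18
  r <- sqrt(outer(ax^2, ax^2, "+"))
  expect_equal(mean(ann), sum(r >= geom$a_deg & r <= geom$b_deg) / 255^2)
  expect_error(make_annulus_image(geom, 64, 0.09), "field of view too small")
})

test_that("radial profiles summarize images by angular radius", {
  const <- angular_image(matrix(0.42, 128, 128), 0.18)
  prof <- radial_profile(const, n_bins = 16)
  expect_true(all(abs(prof$intensity - 0.42) < 1e-12))
  expect_true(all(diff(prof$alpha_deg) > 0))

  ann <- make_annulus_image(side_px = 255, deg_per_px = 0.18)
  p <- radial_profile(ann)
  expect_true(all(p$intensity[p$alpha_deg < 0.7] == 0))
  inner <- p$intensity[p$alpha_deg > 1.5 & p$alpha_deg < 10]
  expect_true(all(inner > 0.99))

  blurred <- apply_glare(ann, build_kernel(4, 0.18, max_side_px = 255))
  pb <- radial_profile(blurred)
  expect_true(all(pb$intensity[pb$alpha_deg < 0.8] > 0))

  expect_error(radial_profile(const, n_bins = 7), ">= 8")
  expect_error(radial_profile(angular_image(matrix(1, 32, 32), 0.05),
                              n_bins = 500), "empty radial bins")
})

test_that("straylight index spans 0 (pristine) to 1 (fully veiled)", {
  ann <- make_annulus_image(side_px = 255, deg_per_px = 0.18)
  expect_identical(straylight_index(ann), 0)
  uniform <- angular_image(matrix(0.6, 255, 255), 0.18)
  expect_equal(straylight_index(uniform), 1)
  expect_error(straylight_index(angular_image(matrix(0, 255, 255), 0.18)),
               "no illumination")
  expect_error(straylight_index(angular_image(matrix(1, 32, 32), 0.09)),
               "does not cover")
})

test_that("more glare spread produces a larger straylight index", {
  ann <- make_annulus_image(side_px = 255, deg_per_px = 0.18)
  si <- vapply(c(4, 8, 16), function(theta) {
    straylight_index(apply_glare(ann,
      build_kernel(theta, 0.18, max_side_px = 255)))
  }, 0)
  expect_true(all(diff(si) > 0))
  expect_true(all(si >= 0 & si <= 1))
})

test_that("the default calibration sweep is monotone and self-consistent", {
  cal <- default_calibration()
  expect_length(cal$si, 20L)
  expect_true(all(diff(cal$si) > 0))
  expect_true(all(cal$si >= 0 & cal$si <= 1))
  ## least-squares self-consistency: evaluating the fitted cubic at the
  ## measured SI values reproduces the theta grid up to the residuals
  cf <- coef(cal)
  fitted <- cf[["A"]] * cal$si^3 + cf[["B"]] * cal$si^2 +
    cf[["C"]] * cal$si + cf[["D"]]
  expect_equal(sqrt(mean((fitted - cal$theta_grid)^2)), cal$rms_residual,
               tolerance = 1e-9)
  ## determinism
  cal2 <- si_calibrate()
  expect_identical(cal$si, cal2$si)
  expect_identical(coef(cal), coef(cal2))
})

test_that("the calibration cubic inverts the sweep it was fitted on", {
  cal <- default_calibration()
  err <- abs(predict(cal, cal$si) - cal$theta_grid)
  ## the round trip is good to 10% of theta or one degree, whichever is
  ## larger: the unweighted cubic fit leaves sub-degree residuals on the
  ## steep small-theta toe and sub-10% residuals above it
  expect_true(all(err <= pmax(1, 0.10 * cal$theta_grid)))
  expect_true(all((err / cal$theta_grid)[cal$si >= 0.2] <= 0.10))
})

test_that("the published cubic inverts as printed", {
  ref <- reference_calibration()
  expect_equal(si_to_theta(0.5, ref), 14.451, tolerance = 1e-4)
  expect_identical(si_to_theta(0, ref), 0.1)     # raw -0.58 deg clamped
  sg <- seq(0.05, 1, by = 0.005)
  expect_true(all(diff(si_to_theta(sg, ref)) >= 0))
  expect_error(si_to_theta(1.2, ref), "\\[0, 1\\]")
  expect_error(si_to_theta(-0.1, ref), "\\[0, 1\\]")
})

test_that("calibrations persist as JSON and tabulate as data frames", {
  cal <- default_calibration()
  path <- file.path(tempdir(), "cal-roundtrip.json")
  write_calibration(cal, path)
  cal2 <- read_calibration(path)
  expect_equal(coef(cal2), coef(cal), tolerance = 1e-12)
  expect_equal(cal2$si, cal$si, tolerance = 1e-12)
  expect_equal(predict(cal2, 0.4), predict(cal, 0.4), tolerance = 1e-12)
  tab <- calibration_table(cal)
  expect_identical(nrow(tab), 20L)
  expect_identical(tab$si, cal$si)
  expect_error(calibration_table(reference_calibration()), "no sweep data")
})

test_that("calibration validates its grid", {
  expect_error(si_calibrate(theta_grid = c(1, 2, 3)), ">= 6 points")
  expect_error(si_calibrate(theta_grid = seq(0.5, 10, length.out = 8)),
               "within \\[1, 90\\]")
})
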