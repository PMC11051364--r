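test_that("letter height follows decimal acuity sizing", {
  expect_identical(letter_height_px(1.0, 60), 5L)    # 5 arcmin at 1 px/arcmin
  expect_identical(letter_height_px(0.5, 60), 10L)
  expect_identical(letter_height_px(0.3, 120), 33L)  # 16.67 arcmin * 2 px
  expect_error(letter_height_px(1.2, 60), "resolution too low")
  ## strictly decreasing letter size with acuity at fixed sampling
  hs <- vapply(seq(0.3, 1.2, 0.1), letter_height_px, 0L,
               px_per_degree = 120)
  expect_true(all(diff(hs) < 0))
})

test_that("rendered charts are full-contrast and deterministic", {
  spec <- chart_spec(0.5, px_per_degree = 120)
  ch <- render_chart(spec, side_px = 384)
  expect_identical(michelson_contrast(ch$image), 1)
  expect_identical(ch$si_label, 0)
  expect_identical(range(unclass(ch$image)), c(0, 1))
  ## ink rows span exactly the computed letter height
  ink_rows <- which(apply(unclass(ch$image) == 0, 1, any))
  expect_identical(diff(range(ink_rows)) + 1L, letter_height_px(0.5, 120))
  expect_identical(render_chart(spec, side_px = 384), ch)
  expect_error(render_chart(chart_spec(0.3, px_per_degree = 120), 64),
               "too many letters")
})

test_that("inverse polarity and tumbling-E mode render correctly", {
  e <- render_chart(chart_spec(0.6, letters = rep("E", 5),
                               px_per_degree = 120), side_px = 384)
  expect_identical(michelson_contrast(e$image), 1)
  inv <- render_chart(chart_spec(0.6, polarity = "light-on-dark",
                                 px_per_degree = 120), side_px = 384)
  expect_gt(mean(inv$image < 0.5), 0.5)    # mostly dark field
  expect_error(chart_spec(0.5, letters = "Q"), "unsupported glyphs")
})

test_that("chart contrast falls strictly as the target SI rises", {
  base <- render_chart(chart_spec(0.5, px_per_degree = 72), side_px = 256)
  cal <- reference_calibration()
  contrasts <- vapply(c(0.1, 0.2, 0.6), function(si) {
    d <- degrade_chart(base, si, cal)
    expect_identical(dim(d$image), dim(base$image))
    expect_true(all(d$image >= 0 & d$image <= 1))
    expect_identical(d$si_label, si)
    michelson_contrast(d$image)
  }, 0)
  expect_true(all(diff(contrasts) < 0))
})

test_that("a vanishing SI leaves the chart essentially untouched", {
  base <- render_chart(chart_spec(0.8, px_per_degree = 72), side_px = 256)
  d <- degrade_chart(base, 0.01, reference_calibration())  # theta clamps to 0.1
  expect_lt(abs(mean(d$image) - mean(base$image)) / mean(base$image), 0.01)
})

test_that("degrade_chart validates its inputs", {
  base <- render_chart(chart_spec(0.8, px_per_degree = 72), side_px = 256)
  cal <- reference_calibration()
  expect_error(degrade_chart(base, 0, cal), "in \\(0, 1\\]")
  expect_error(degrade_chart(base, 1.2, cal), "in \\(0, 1\\]")
  expect_error(degrade_chart(base, 1, cal, max_theta_deg = 50),
               "exceeds the cap")
})

test_that("the chart factory writes a consistent, reproducible set", {
  out1 <- file.path(tempdir(), "chartset-a")
  out2 <- file.path(tempdir(), "chartset-b")
  mf <- generate_chart_set(out1, va_levels = c(0.4, 0.8),
                           si_levels = c(0.2, 0.5),
                           side_px = 256, px_per_degree = 72, force = TRUE)
  expect_identical(nrow(mf), 6L)                 # 2 VA x (2 SI + 1 free)
  pngs <- dir(out1, pattern = "[.]png$")
  expect_identical(length(pngs), 6L)
  expect_setequal(pngs, mf$filename)
  ## round trip: re-read files and recompute contrast
  for (i in seq_len(nrow(mf))) {
    img <- read_angular_image(file.path(out1, mf$filename[i]),
                              mf$deg_per_px[i])
    expect_lt(abs(michelson_contrast(img) - mf$contrast[i]), 1 / 255)
  }
  ## bit-identical regeneration
  mf2 <- generate_chart_set(out2, va_levels = c(0.4, 0.8),
                            si_levels = c(0.2, 0.5),
                            side_px = 256, px_per_degree = 72, force = TRUE)
  expect_identical(mf2$contrast, mf$contrast)
  for (fn in mf$filename) {
    expect_identical(readBin(file.path(out1, fn), "raw", 1e6),
                     readBin(file.path(out2, fn), "raw", 1e6))
  }
  ## refuses to clobber without force
  expect_error(generate_chart_set(out1, va_levels = 0.4, si_levels = 0.2,
                                  side_px = 256, px_per_degree = 72),
               "force")
})

test_that("angular images round-trip through PNG and TIFF", {
  set.seed(3)
  img <- angular_image(matrix(round(runif(32 * 32) * 255) / 255, 32, 32),
                       0.05)
  for (ext in c("png", "tiff")) {
    p <- file.path(tempdir(), paste0("io-roundtrip.", ext))
    write_angular_image(img, p)
    back <- read_angular_image(p, 0.05)
    expect_equal(unclass(back), unclass(img), tolerance = 1e-9)
  }
})
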