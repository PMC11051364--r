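make_responses <- function(va_grid, si_grid, rule) {
  r <- expand.grid(va = va_grid, si = si_grid)
  r$tolerated <- as.integer(rule(r$va, r$si))
  r
}

test_that("the SSF records the largest tolerated SI per acuity level", {
  va <- seq(0.3, 1.2, 0.1); si <- seq(0.1, 1.0, 0.1)
  all_yes <- build_ssf(make_responses(va, si, function(v, s) TRUE))
  expect_true(all(all_yes$max_si == 1.0))
  expect_identical(all_yes$va, va)

  none_high <- build_ssf(make_responses(va, si,
    function(v, s) v < 1.15))    # nothing tolerated at VA 1.2
  expect_identical(none_high$max_si[none_high$va == 1.2], 0)

  ## step-shaped tolerance profile reconstructs exactly
  step <- build_ssf(make_responses(va, si,
    function(v, s) s <= ifelse(v < 0.65, 0.6, 0.2) + 1e-9))
  expect_equal(step$max_si, ifelse(va < 0.65, 0.6, 0.2))
})

test_that("the SSF builder validates and deduplicates responses", {
  expect_error(build_ssf(data.frame(va = 1.5, si = 0.1, tolerated = 1)),
               "VA outside")
  expect_error(build_ssf(data.frame(va = 0.5, si = 0.1)), "missing")
  dup <- data.frame(va = c(0.5, 0.5, 0.5), si = c(0.4, 0.4, 0.2),
                    tolerated = c(1, 0, 1))
  expect_warning(curve <- build_ssf(dup), "duplicate")
  expect_identical(curve$max_si, 0.2)   # last response at SI 0.4 was "no"
})

test_that("SSI integrates the SSF over the acuity range", {
  va <- seq(0.3, 1.2, 0.1)
  expect_equal(compute_ssi(data.frame(va = va, max_si = 1))$ssi, 0.9)
  expect_equal(compute_ssi(data.frame(va = va, max_si = 0))$ssi, 0)
  ## step curve: 0.6 on [0.3, 0.6], 0.2 on [0.7, 1.2]
  step <- data.frame(va = va, max_si = ifelse(va < 0.65, 0.6, 0.2))
  expect_equal(compute_ssi(step)$ssi,
               oracle_trapz(va, step$max_si), tolerance = 1e-12)
  expect_equal(compute_ssi(step)$ssi, 0.32, tolerance = 1e-12)
  ## flat extension when the grid stops short of the bounds
  short <- data.frame(va = seq(0.5, 1.0, 0.1), max_si = 0.4)
  expect_equal(compute_ssi(short)$ssi, 0.9 * 0.4, tolerance = 1e-12)
  ## normalized variant
  expect_equal(compute_ssi(step, normalized = TRUE)$ssi, 0.32 / 0.9,
               tolerance = 1e-12)
  expect_error(compute_ssi(data.frame(va = 0.5, max_si = 1)), "at least 2")
})

test_that("raising any tolerated SI never decreases the SSI", {
  set.seed(21)
  va <- seq(0.3, 1.2, 0.1)
  for (rep in 1:20) {
    y <- runif(length(va))
    base <- compute_ssi(data.frame(va = va, max_si = y))$ssi
    i <- sample(length(va), 1)
    y2 <- y; y2[i] <- min(1, y2[i] + runif(1))
    expect_gte(compute_ssi(data.frame(va = va, max_si = y2))$ssi, base)
  }
})

test_that("SSI is invariant to interpolated grid refinement", {
  va <- seq(0.3, 1.2, 0.1)
  set.seed(9)
  y <- runif(length(va))
  fine <- sort(unique(c(va, seq(0.3, 1.2, 0.025))))
  yf <- approx(va, y, xout = fine)$y
  expect_equal(compute_ssi(data.frame(va = fine, max_si = yf))$ssi,
               compute_ssi(data.frame(va = va, max_si = y))$ssi,
               tolerance = 1e-12)
})

test_that("SSF comparison ranks by area under the curve", {
  va <- seq(0.3, 1.2, 0.1)
  lo <- data.frame(va = va, max_si = 0.3)
  hi <- data.frame(va = va, max_si = 0.5)
  cmp <- compare_ssf(list(low = lo, high = hi))
  expect_identical(cmp$ranking$subject, c("high", "low"))
  expect_equal(cmp$pairwise["high", "low"], 0.9 * 0.2, tolerance = 1e-12)
  ## identical curves tie at zero difference
  cmp2 <- compare_ssf(list(a = lo, b = lo))
  expect_equal(cmp2$pairwise["a", "b"], 0)
  ## crossing curves (similar below VA 0.6, collapse above): the integral
  ## decides, checked against the longhand quadrature
  collapse <- data.frame(va = va, max_si = ifelse(va < 0.65, 0.58, 0.05))
  steady <- data.frame(va = va, max_si = ifelse(va < 0.65, 0.52, 0.45))
  cmp3 <- compare_ssf(list(collapse = collapse, steady = steady))
  better <- if (oracle_trapz(va, collapse$max_si) >
                oracle_trapz(va, steady$max_si)) "collapse" else "steady"
  expect_identical(cmp3$ranking$subject[1], better)
  ## mismatched grids are resampled with a warning
  part <- data.frame(va = seq(0.3, 1.2, 0.3), max_si = 0.4)
  expect_warning(compare_ssf(list(lo, part)), "resampling")
  expect_error(compare_ssf(list(lo)), "at least 2")
})

test_that("response tables score into per-subject SSF and SSI", {
  va <- seq(0.3, 1.2, 0.1); si <- seq(0.1, 1.0, 0.1)
  r1 <- make_responses(va, si, function(v, s) s <= 0.5 + 1e-9)
  r2 <- make_responses(va, si, function(v, s) TRUE)
  r1$subject_id <- "weak"; r2$subject_id <- "strong"
  path <- file.path(tempdir(), "responses.csv")
  write.csv(rbind(r1, r2), path, row.names = FALSE)
  scored <- score_responses(read_responses(path))
  expect_equal(scored$ssi[scored$subject_id == "strong"], 0.9)
  expect_equal(scored$ssi[scored$subject_id == "weak"], 0.45,
               tolerance = 1e-12)
  expect_length(attr(scored, "curves"), 2L)
})
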