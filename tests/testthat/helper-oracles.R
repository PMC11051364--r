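## Independent oracles and shared fixtures. Everything here is computed
## from first principles, deliberately not reusing the package internals.

## Term-by-term transcription of the CIE disability-glare formula.
oracle_gsf <- function(theta, age, pf) {
  af <- (age / 70)^4
  term_small_1 <- 9.2e6 / (1 + (theta / 0.046)^2)^(3 / 2)
  term_small_2 <- 1.5e5 / (1 + (theta / 0.045)^2)^(3 / 2)
  term_wide <- 400 / (1 + (theta / 0.1)^2)
  term_quad <- 3e-8 * theta * theta
  term_pf_1 <- 1300 / (1 + (theta / 0.1)^2)^(3 / 2)
  term_pf_2 <- 0.8 / sqrt(1 + (theta / 0.1)^2)
  (1 - 0.08 * af) * (term_small_1 + term_small_2) +
    (1 + 1.6 * af) * term_wide +
    term_quad +
    pf * (term_pf_1 + term_pf_2) +
    2.5e-3 * pf
}

## Only the pigment-dependent part of the formula (the PF bracket plus
## the additive pedestal), for finite-difference checks.
oracle_gsf_pf_part <- function(theta, pf) {
  pf * (1300 / (1 + (theta / 0.1)^2)^1.5 +
        0.8 / (1 + (theta / 0.1)^2)^0.5) + 2.5e-3 * pf
}

## Direct spatial-domain convolution with edge-replicate boundary
## handling: the kernel is swept tap by tap (vectorized over pixels).
oracle_conv <- function(img, ker) {
  n1 <- nrow(img); n2 <- ncol(img)
  ks <- nrow(ker); half <- (ks - 1L) %/% 2L
  out <- matrix(0, n1, n2)
  for (di in -half:half) {
    ri <- pmin(pmax(seq_len(n1) - di, 1L), n1)
    for (dj in -half:half) {
      w <- ker[di + half + 1L, dj + half + 1L]
      if (w == 0) next
      ci <- pmin(pmax(seq_len(n2) - dj, 1L), n2)
      out <- out + w * img[ri, ci]
    }
  }
  out
}

## Trapezoidal quadrature written out longhand.
oracle_trapz <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1L)) {
    s <- s + (x[i + 1L] - x[i]) * (y[i] + y[i + 1L]) / 2
  }
  s
}

## A bare unit-impulse "kernel" for identity-convolution checks.
delta_kernel <- function(deg_per_px) {
  v <- matrix(0, 3, 3); v[2, 2] <- 1
  structure(v, deg_per_px = deg_per_px, theta_deg = deg_per_px,
            eye = eye_params(), tail_fraction = 0, normalized = TRUE,
            class = c("gsf_kernel", "matrix", "array"))
}

## Small E-letter test image (dark E on a bright field), plain matrix.
e_letter_image <- function(side = 64) {
  img <- matrix(1, side, side)
  h <- side %/% 2
  r0 <- (side - h) %/% 2; c0 <- (side - h) %/% 2
  glyph <- matrix(as.integer(strsplit(
    "111111000011110100001111100000", "")[[1]])[1:25], 5, 5, byrow = TRUE)
  idx <- pmin(5L, pmax(1L, ceiling(seq_len(h) * 5 / h)))
  block <- glyph[idx, idx]
  sub <- img[(r0 + 1):(r0 + h), (c0 + 1):(c0 + h)]
  sub[block == 1L] <- 0
  img[(r0 + 1):(r0 + h), (c0 + 1):(c0 + h)] <- sub
  img
}

## Memoized expensive fixtures (built once per test run).
.fixtures <- new.env(parent = emptyenv())

## Default-condition meter calibration (20 log-spaced theta in [1, 60],
## 512 px at 0.09 deg/px, age 20, PF 0.5).
default_calibration <- function() {
  if (is.null(.fixtures$cal)) .fixtures$cal <- si_calibrate()
  .fixtures$cal
}

## Full default chart set (110 charts, 512 px at 120 px/degree).
full_chart_set <- function() {
  if (is.null(.fixtures$full_manifest)) {
    dir <- file.path(tempdir(), "straylight-full-charts")
    .fixtures$full_manifest <- generate_chart_set(dir, force = TRUE)
    .fixtures$full_dir <- dir
  }
  .fixtures$full_manifest
}

full_chart_dir <- function() {
  full_chart_set()
  .fixtures$full_dir
}

## Reduced chart set for observer-level tests: full VA and SI grids on a
## 256 px / 72 px-per-degree canvas (small enough to stay fast).
small_chart_set <- function() {
  if (is.null(.fixtures$small_manifest)) {
    dir <- file.path(tempdir(), "straylight-small-charts")
    .fixtures$small_manifest <- generate_chart_set(
      dir, cal = reference_calibration(), side_px = 256,
      px_per_degree = 72, force = TRUE)
    .fixtures$small_dir <- dir
  }
  .fixtures$small_manifest
}
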