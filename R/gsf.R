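#' Observer eye parameters for the CIE disability-glare formula
#'
#' Bundles the two observer-dependent inputs of the CIE general
#' disability-glare formula: age in years and the ocular pigment factor
#' `PF` (0 for very dark eyes, about 0.5 for brown, up to ~1.2 for
#' light-blue/depigmented eyes).
#'
#' @param age Observer age in years, in `[0, 120]`.
#' @param pigment_factor Dimensionless pigment factor, `>= 0`
#'   (typical range 0--1.2).
#' @return An object of class `eye_params`.
#' @examples
#' eye_params(age = 20, pigment_factor = 0.5)
#' @export
eye_params <- function(age = 20, pigment_factor = 0.5) {
  if (!is.numeric(age) || length(age) != 1L || !is.finite(age) ||
      age < 0 || age > 120) {
    stop("'age' must be a single finite number in [0, 120]", call. = FALSE)
  }
  if (!is.numeric(pigment_factor) || length(pigment_factor) != 1L ||
      !is.finite(pigment_factor) || pigment_factor < 0) {
    stop("'pigment_factor' must be a single finite non-negative number",
         call. = FALSE)
  }
  structure(list(age = age, pigment_factor = pigment_factor),
            class = "eye_params")
}

#' @export
print.eye_params <- function(x, ...) {
  cat(sprintf("CIE standard glare observer: age %g y, pigment factor %g\n",
              x$age, x$pigment_factor))
  invisible(x)
}

as_eye_params <- function(eye) {
  if (inherits(eye, "eye_params")) return(eye)
  if (is.list(eye) && all(c("age", "pigment_factor") %in% names(eye))) {
    return(eye_params(eye$age, eye$pigment_factor))
  }
  stop("'eye' must be an eye_params object", call. = FALSE)
}

#' CIE general disability-glare formula
#'
#' Evaluates the CIE standard-glare-observer glare spread function
#' GSF(theta): the equivalent veiling luminance per unit glare-source
#' illuminance (units sr^-1) at glare angle `theta_deg` from a point
#' source, for an observer of given age and ocular pigmentation.
#'
#' The formula is a sum of inverse-power terms in `theta`:
#' an age-attenuated small-angle pair with angular constants 0.046 and
#' 0.045 deg, an age-amplified wide-angle term with constant 0.1 deg plus
#' a tiny quadratic term, and pigment-dependent terms (constant 0.1 deg)
#' plus an additive pedestal `2.5e-3 * PF`. Its stated validity domain is
#' `theta` in [0.1, 100] degrees.
#'
#' @param theta_deg Glare angle(s) in degrees, each in `[0.1, 100]`
#'   (values below 0.1 are a domain error; use [build_kernel()] for the
#'   clamped small-angle handling used in kernels).
#' @param eye An [eye_params()] object.
#' @return Numeric vector of glare-spread-function values (sr^-1),
#'   strictly positive.
#' @examples
#' gsf_value(1, eye_params(20, 0))
#' gsf_value(c(1, 5, 50), eye_params(70, 1))
#' @export
gsf_value <- function(theta_deg, eye = eye_params()) {
  eye <- as_eye_params(eye)
  if (!is.numeric(theta_deg) || length(theta_deg) < 1L) {
    stop("'theta_deg' must be numeric", call. = FALSE)
  }
  if (any(!is.finite(theta_deg)) || any(theta_deg < 0)) {
    stop("'theta_deg' must be finite and non-negative", call. = FALSE)
  }
  if (any(theta_deg < 0.1 - 1e-12) || any(theta_deg > 100 + 1e-12)) {
    stop("'theta_deg' outside the formula's validity domain [0.1, 100] degrees",
         call. = FALSE)
  }
  .gsf_raw(theta_deg, eye$age, eye$pigment_factor)
}

## Unchecked scalar/vector core of the CIE formula; theta assumed >= 0.1.
.gsf_raw <- function(theta, age, pf) {
  a4 <- (age / 70)^4
  (1 - 0.08 * a4) *
    (9.2e6 / (1 + (theta / 0.046)^2)^1.5 +
     1.5e5 / (1 + (theta / 0.045)^2)^1.5) +
    (1 + 1.6 * a4) * (400 / (1 + (theta / 0.1)^2)) +
    3e-8 * theta^2 +
    pf * (1300 / (1 + (theta / 0.1)^2)^1.5 +
          0.8 / (1 + (theta / 0.1)^2)^0.5) +
    2.5e-3 * pf
}

#' Classical straylight parameter s = theta^2 * PSF
#'
#' The classical scatter quantifier: the point-spread-function (or GSF)
#' value at glare angle `theta`, multiplied by `theta^2`. Healthy eyes
#' have `log10(s)` near 0.9 at mid glare angles.
#'
#' @param theta_deg Glare angle in degrees, `> 0`.
#' @param psf_value PSF/GSF value at that angle (sr^-1), `>= 0`.
#' @return `theta_deg^2 * psf_value` (dimensionless).
#' @examples
#' straylight_parameter(1, 1)
#' straylight_parameter(3, gsf_value(3, eye_params(20, 0.5)))
#' @export
straylight_parameter <- function(theta_deg, psf_value) {
  if (!is.numeric(theta_deg) || any(!is.finite(theta_deg)) ||
      any(theta_deg <= 0)) {
    stop("'theta_deg' must be finite and positive", call. = FALSE)
  }
  if (!is.numeric(psf_value) || any(!is.finite(psf_value)) ||
      any(psf_value < 0)) {
    stop("'psf_value' must be finite and non-negative", call. = FALSE)
  }
  theta_deg^2 * psf_value
}

#' Build a two-dimensional glare-spread-function kernel
#'
#' Discretizes the CIE glare spread function as a square, radially
#' symmetric convolution kernel for a given glare angle `theta_deg`.
#'
#' The kernel for glare angle `theta` is the CIE profile over its
#' small-angle window `[0.1, 4]` degrees, dilated so that its support
#' equals `theta`: the entry at angular radius `r` is
#' `GSF(max(4 r / theta, 0.1))` for `r <= theta` and 0 beyond. At
#' `theta = 4` the kernel is the undilated GSF itself; larger glare
#' angles redistribute kernel mass outward, producing progressively more
#' veiling. This scaling convention was identified as the one that
#' reproduces the published glare-angle/straylight-index calibration
#' curve; see the package vignette for the analysis.
#'
#' When the natural support (`2 theta`) exceeds `max_side_px` pixels the
#' grid is capped: values beyond the capped radius are not stored, and
#' their total weight (computed by radial quadrature of the same profile)
#' is carried in the kernel's `tail_fraction`. [apply_glare()] adds that
#' far-field weight back as a uniform veil scaled by the image's border
#' intensity, which is exact for images with a uniform border.
#'
#' @param theta_deg Glare angle (kernel support radius) in degrees, `> 0`.
#' @param deg_per_px Angular sampling of the kernel grid, degrees per
#'   pixel, `> 0`.
#' @param eye An [eye_params()] object.
#' @param side_px Kernel side in pixels (odd, `>= 3`). Default: smallest
#'   odd integer covering `2 * theta_deg`.
#' @param max_side_px Optional cap on `side_px` (odd). `Inf` (default)
#'   disables capping.
#' @return A `gsf_kernel` object: the matrix of non-negative weights with
#'   attributes `deg_per_px`, `theta_deg`, `eye`, `tail_fraction` and
#'   `normalized`. In-grid weights sum to `1 - tail_fraction`.
#' @examples
#' k <- build_kernel(4, deg_per_px = 0.1, eye = eye_params(20, 0.5))
#' sum(k)
#' @export
build_kernel <- function(theta_deg, deg_per_px, eye = eye_params(),
                         side_px = NULL, max_side_px = Inf) {
  eye <- as_eye_params(eye)
  if (!is.numeric(theta_deg) || length(theta_deg) != 1L ||
      !is.finite(theta_deg) || theta_deg <= 0) {
    stop("'theta_deg' must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(deg_per_px) || length(deg_per_px) != 1L ||
      !is.finite(deg_per_px) || deg_per_px <= 0) {
    stop("'deg_per_px' must be a single positive number", call. = FALSE)
  }
  if (theta_deg < deg_per_px) {
    stop("kernel support below resolution: theta_deg < deg_per_px",
         call. = FALSE)
  }
  natural <- 2L * as.integer(ceiling(theta_deg / deg_per_px)) + 1L
  if (is.null(side_px)) side_px <- natural
  side_px <- as.integer(side_px)
  if (side_px < 3L || side_px %% 2L == 0L) {
    stop("'side_px' must be an odd integer >= 3", call. = FALSE)
  }
  if (is.finite(max_side_px)) {
    max_side_px <- as.integer(max_side_px)
    if (max_side_px %% 2L == 0L) max_side_px <- max_side_px - 1L
    side_px <- min(side_px, max_side_px)
    if (side_px < 3L) stop("'max_side_px' too small", call. = FALSE)
  }
  half <- (side_px - 1L) / 2L
  ax <- (-half:half) * deg_per_px
  r <- sqrt(outer(ax^2, ax^2, "+"))
  capped <- half * deg_per_px < theta_deg
  r_cap <- if (capped) half * deg_per_px else theta_deg
  v <- .gsf_raw(pmax(4 * r / theta_deg, 0.1), eye$age, eye$pigment_factor)
  v[r > r_cap] <- 0
  s_in <- sum(v)
  tail_raw <- 0
  if (capped) {
    ## Weight of the discarded annulus [r_cap, theta], continuum limit of
    ## the pixel sum: (1/dpp^2) * Int 2 pi r gsf(4 r / theta) dr.
    f <- function(r) 2 * pi * r *
      .gsf_raw(pmax(4 * r / theta_deg, 0.1), eye$age, eye$pigment_factor)
    tail_raw <- stats::integrate(f, r_cap, theta_deg,
                                 rel.tol = 1e-9)$value / deg_per_px^2
  }
  z <- s_in + tail_raw
  structure(v / z,
            deg_per_px = deg_per_px,
            theta_deg = theta_deg,
            eye = eye,
            tail_fraction = tail_raw / z,
            normalized = TRUE,
            class = c("gsf_kernel", "matrix", "array"))
}

#' @export
print.gsf_kernel <- function(x, ...) {
  cat(sprintf(
    "GSF kernel: theta = %g deg, %d x %d px at %g deg/px\n",
    attr(x, "theta_deg"), nrow(x), ncol(x), attr(x, "deg_per_px")))
  tf <- attr(x, "tail_fraction")
  cat(sprintf("  in-grid weight %.6f, far-field tail %.6f\n", sum(x), tf))
  invisible(x)
}

#' Export a GSF kernel as CSV with a JSON sidecar
#'
#' Writes the kernel weights as a plain CSV matrix plus a `.json` sidecar
#' carrying the angular scale, glare angle, observer parameters and tail
#' fraction, so the kernel can be rebuilt or consumed elsewhere.
#'
#' @param kernel A [build_kernel()] result.
#' @param path Output CSV path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_kernel <- function(kernel, path) {
  stopifnot(inherits(kernel, "gsf_kernel"))
  utils::write.table(unclass(kernel), path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  eye <- attr(kernel, "eye")
  meta <- list(deg_per_px = attr(kernel, "deg_per_px"),
               theta_deg = attr(kernel, "theta_deg"),
               age = eye$age, pigment_factor = eye$pigment_factor,
               tail_fraction = attr(kernel, "tail_fraction"))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GSF kernel written by [write_kernel()]
#'
#' @param path CSV path previously passed to [write_kernel()].
#' @return A `gsf_kernel` object.
#' @export
read_kernel <- function(path) {
  v <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(v) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(v,
            deg_per_px = meta$deg_per_px,
            theta_deg = meta$theta_deg,
            eye = eye_params(meta$age, meta$pigment_factor),
            tail_fraction = meta$tail_fraction,
            normalized = TRUE,
            class = c("gsf_kernel", "matrix", "array"))
}
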