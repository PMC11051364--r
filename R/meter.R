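#' Wide-field straylight-meter geometry
#'
#' Geometry of the simulated straylight meter: a bright annulus
#' illuminating the retinal field with a dark central measurement field.
#' The defaults follow the instrument's full angular subtenses of 1.6 deg
#' (central field) and 22 deg (annulus), interpreted as diameters, hence
#' radii `a = 0.8` and `b = 11` degrees. Set `subtense = "radius"` to
#' interpret the two numbers as radii instead.
#'
#' @param a_deg Central (blocked) measurement-field radius, degrees.
#' @param b_deg Annulus outer radius, degrees; must exceed `a_deg`.
#' @param subtense Either `"diameter"` (default; inputs are full
#'   subtenses, radii are half) or `"radius"`.
#' @return A `meter_geometry` object with fields `a_deg`, `b_deg`
#'   (always radii) and `ring_inner_deg = a_deg`.
#' @examples
#' meter_geometry()                       # radii 0.8 and 11 deg
#' meter_geometry(1.6, 22, "radius")      # radii 1.6 and 22 deg
#' @export
meter_geometry <- function(a_deg = 1.6, b_deg = 22,
                           subtense = c("diameter", "radius")) {
  subtense <- match.arg(subtense)
  if (subtense == "diameter") {
    a_deg <- a_deg / 2
    b_deg <- b_deg / 2
  }
  if (!is.finite(a_deg) || !is.finite(b_deg) || a_deg <= 0 ||
      b_deg <= a_deg) {
    stop("need 0 < a_deg < b_deg", call. = FALSE)
  }
  structure(list(a_deg = a_deg, b_deg = b_deg, ring_inner_deg = a_deg),
            class = "meter_geometry")
}

#' @export
print.meter_geometry <- function(x, ...) {
  cat(sprintf(
    "straylight meter: central field radius %g deg, ring [%g, %g] deg\n",
    x$a_deg, x$ring_inner_deg, x$b_deg))
  invisible(x)
}

#' Render the straylight-meter annulus image
#'
#' Bright ring at intensity 1 covering angular radii `[a, b]`, dark
#' (blocked) central measurement field and dark surround.
#'
#' @param geom A [meter_geometry()].
#' @param side_px Image side in pixels.
#' @param deg_per_px Angular sampling, degrees per pixel.
#' @return An [angular_image()].
#' @examples
#' ann <- make_annulus_image(meter_geometry(), 256, 0.18)
#' @export
make_annulus_image <- function(geom = meter_geometry(), side_px = 512,
                               deg_per_px = 0.09) {
  stopifnot(inherits(geom, "meter_geometry"))
  if (side_px * deg_per_px < 2 * geom$b_deg) {
    stop(sprintf(
      "field of view too small: %.1f deg < 2*b = %.1f deg",
      side_px * deg_per_px, 2 * geom$b_deg), call. = FALSE)
  }
  img <- angular_image(matrix(0, side_px, side_px), deg_per_px)
  r <- .radius_map(img)
  img[r >= geom$a_deg & r <= geom$b_deg] <- 1
  img
}

#' Radial intensity profile of an image
#'
#' Mean intensity in equal-width annular bins of angular radius about the
#' image center, from 0 to the corner-free maximum radius (the largest
#' radius at which a full circle fits along the image axes).
#'
#' @param image An [angular_image()].
#' @param n_bins Number of radial bins, `>= 8`.
#' @return A data frame of class `radial_profile` with columns
#'   `alpha_deg` (bin centers, increasing) and `intensity`.
#' @export
radial_profile <- function(image, n_bins = NULL) {
  stopifnot(inherits(image, "angular_image"))
  dpp <- deg_per_px(image)
  rmax <- min(max(abs(.axis_deg(nrow(image), dpp))),
              max(abs(.axis_deg(ncol(image), dpp))))
  if (is.null(n_bins)) n_bins <- max(8L, floor(rmax / dpp))
  if (n_bins < 8L) stop("'n_bins' must be >= 8", call. = FALSE)
  breaks <- seq(0, rmax, length.out = n_bins + 1L)
  r <- .radius_map(image)
  keep <- r <= rmax
  idx <- .bincode(r[keep], breaks, include.lowest = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  if (any(counts == 0L)) {
    stop(sprintf(
      "empty radial bins at n_bins = %d; use fewer bins", n_bins),
      call. = FALSE)
  }
  sums <- as.vector(tapply(unclass(image)[keep], idx, sum))
  structure(data.frame(
    alpha_deg = (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2,
    intensity = sums / counts),
    class = c("radial_profile", "data.frame"))
}

#' Straylight index of a meter image
#'
#' Ratio of the mean radial-profile intensity inside the central
#' measurement field (`alpha < a`) to the mean over the bright reference
#' ring (`a <= alpha <= b`), clipped to `[0, 1]`. A pristine annulus
#' scores 0 (dark center); a fully veiled (uniform) field scores 1.
#'
#' @param image An [angular_image()] covering the ring (`b_deg`).
#' @param geom A [meter_geometry()].
#' @return The straylight index, a number in `[0, 1]`.
#' @examples
#' straylight_index(make_annulus_image(side_px = 256, deg_per_px = 0.18))
#' @export
straylight_index <- function(image, geom = meter_geometry()) {
  stopifnot(inherits(image, "angular_image"), inherits(geom, "meter_geometry"))
  dpp <- deg_per_px(image)
  rmax <- min(max(abs(.axis_deg(nrow(image), dpp))),
              max(abs(.axis_deg(ncol(image), dpp))))
  if (rmax < geom$b_deg) {
    stop("image does not cover the reference ring", call. = FALSE)
  }
  prof <- radial_profile(image)
  num <- mean(prof$intensity[prof$alpha_deg < geom$a_deg])
  den <- mean(prof$intensity[prof$alpha_deg >= geom$a_deg &
                             prof$alpha_deg <= geom$b_deg])
  if (!is.finite(den) || den <= 0) {
    stop("no illumination in the reference ring", call. = FALSE)
  }
  min(max(num / den, 0), 1)
}

#' Calibrate the glare-angle / straylight-index relationship
#'
#' Runs the simulated meter through a sweep of glare angles: for each
#' `theta` a GSF kernel is built ([build_kernel()]), the annulus image is
#' veiled with it ([apply_glare()]) and the straylight index of the
#' result is measured ([straylight_index()]). The sweep is then
#' summarized by an ordinary-least-squares cubic
#' `theta = A SI^3 + B SI^2 + C SI + D`, the form in which the mapping is
#' reported and inverted.
#'
#' @param theta_grid Increasing grid of glare angles in `[1, 90]` degrees,
#'   at least 6 points. Default: 20 log-spaced points in `[1, 60]`.
#' @param geom A [meter_geometry()].
#' @param eye An [eye_params()] object.
#' @param deg_per_px Meter-image sampling, degrees per pixel.
#' @param side_px Meter-image side in pixels.
#' @return An object of class `si_calibration` with components
#'   `theta_grid`, `si`, `coefficients` (named `A`--`D`), `residuals`,
#'   `rms_residual` and the generation parameters. Methods: `print`,
#'   `coef`, `predict` (SI to theta), `residuals`, `plot`.
#' @examples
#' \donttest{
#' cal <- si_calibrate()
#' coef(cal)
#' predict(cal, si = 0.5)
#' }
#' @export
si_calibrate <- function(theta_grid = exp(seq(log(1), log(60),
                                              length.out = 20)),
                         geom = meter_geometry(), eye = eye_params(),
                         deg_per_px = 0.09, side_px = 512) {
  eye <- as_eye_params(eye)
  if (length(theta_grid) < 6L || is.unsorted(theta_grid, strictly = TRUE)) {
    stop("'theta_grid' must be strictly increasing with >= 6 points",
         call. = FALSE)
  }
  if (min(theta_grid) < 1 || max(theta_grid) > 90) {
    stop("'theta_grid' must lie within [1, 90] degrees", call. = FALSE)
  }
  ann <- make_annulus_image(geom, side_px, deg_per_px)
  cap <- side_px + (side_px %% 2L == 0L)
  si <- vapply(theta_grid, function(th) {
    k <- build_kernel(th, deg_per_px, eye, max_side_px = cap)
    straylight_index(apply_glare(ann, k), geom)
  }, 0)
  if (any(diff(si) < -1e-6)) {
    warning("SI(theta) is not monotone over the requested grid")
  }
  fit <- stats::lm(theta_grid ~ si + I(si^2) + I(si^3))
  cf <- stats::coef(fit)
  if (any(!is.finite(cf))) stop("singular cubic fit", call. = FALSE)
  coefficients <- c(A = unname(cf[4L]), B = unname(cf[3L]),
                    C = unname(cf[2L]), D = unname(cf[1L]))
  res <- unname(stats::residuals(fit))
  structure(list(
    theta_grid = theta_grid,
    si = si,
    coefficients = coefficients,
    residuals = res,
    rms_residual = sqrt(mean(res^2)),
    params = list(deg_per_px = deg_per_px, side_px = side_px,
                  a_deg = geom$a_deg, b_deg = geom$b_deg,
                  age = eye$age, pigment_factor = eye$pigment_factor)),
    class = "si_calibration")
}

#' Calibration object from explicit cubic coefficients
#'
#' Builds an `si_calibration` carrying only the cubic coefficients of
#' `theta = A SI^3 + B SI^2 + C SI + D`, for use with [si_to_theta()] and
#' [degrade_chart()] when the mapping is known rather than re-simulated.
#'
#' @param A,B,C,D Cubic coefficients (degrees).
#' @return An `si_calibration` object without sweep data.
#' @seealso [reference_calibration()] for the published coefficients.
#' @export
si_calibration <- function(A, B, C, D) {
  structure(list(theta_grid = NULL, si = NULL,
                 coefficients = c(A = A, B = B, C = C, D = D),
                 residuals = NULL, rms_residual = NA_real_,
                 params = NULL),
            class = "si_calibration")
}

#' Published reference coefficients of the theta--SI cubic
#'
#' The cubic coefficients reported in the literature for this simulated
#' meter methodology: `A = 130.25`, `B = -85.92`, `C = 40.46`,
#' `D = -0.58` (degrees).
#'
#' @return An `si_calibration` object carrying those coefficients.
#' @examples
#' si_to_theta(0.5, reference_calibration())   # 14.451 degrees
#' @export
reference_calibration <- function() {
  si_calibration(A = 130.25, B = -85.92, C = 40.46, D = -0.58)
}

#' Glare angle corresponding to a straylight index
#'
#' Evaluates the calibration cubic at `si`. Raw values below 0.1 deg
#' (possible near `si = 0`, where the cubic's intercept is negative) are
#' clamped to 0.1 deg, the lower validity bound of the glare formula.
#'
#' @param si Straylight index value(s) in `[0, 1]`.
#' @param cal An `si_calibration` (from [si_calibrate()],
#'   [si_calibration()] or [reference_calibration()]).
#' @param theta_min Lower clamp in degrees (default 0.1).
#' @return Glare angle(s) in degrees.
#' @export
si_to_theta <- function(si, cal, theta_min = 0.1) {
  stopifnot(inherits(cal, "si_calibration"))
  if (any(!is.finite(si)) || any(si < 0) || any(si > 1)) {
    stop("'si' must lie in [0, 1]", call. = FALSE)
  }
  cf <- cal$coefficients
  pmax(cf[["A"]] * si^3 + cf[["B"]] * si^2 + cf[["C"]] * si + cf[["D"]],
       theta_min)
}

#' @export
print.si_calibration <- function(x, digits = 2, ...) {
  cat("theta-SI calibration (theta = A*SI^3 + B*SI^2 + C*SI + D)\n")
  cat("  coefficients:",
      paste(sprintf("%s = %.*f", names(x$coefficients), digits,
                    x$coefficients), collapse = ", "), "\n")
  if (!is.null(x$si)) {
    cat(sprintf("  sweep: %d points, theta in [%g, %g] deg, SI in [%.3f, %.3f]\n",
                length(x$si), min(x$theta_grid), max(x$theta_grid),
                min(x$si), max(x$si)))
    cat(sprintf("  RMS fit residual: %.3f deg\n", x$rms_residual))
  }
  invisible(x)
}

#' @export
coef.si_calibration <- function(object, ...) object$coefficients

#' @export
residuals.si_calibration <- function(object, ...) object$residuals

#' @rdname si_to_theta
#' @param object An `si_calibration`.
#' @param ... Ignored.
#' @export
predict.si_calibration <- function(object, si, theta_min = 0.1, ...) {
  si_to_theta(si, object, theta_min)
}

#' @export
plot.si_calibration <- function(x, ...) {
  if (is.null(x$si)) {
    sg <- seq(0, 1, length.out = 101)
    graphics::plot(sg, si_to_theta(sg, x), type = "l",
                   xlab = "straylight index", ylab = "glare angle (deg)",
                   main = "theta-SI calibration", ...)
    return(invisible(x))
  }
  graphics::plot(x$si, x$theta_grid, pch = 16,
                 xlab = "straylight index", ylab = "glare angle (deg)",
                 main = "theta-SI calibration", ...)
  sg <- seq(min(x$si), max(x$si), length.out = 201)
  graphics::lines(sg, si_to_theta(sg, x), col = "red")
  invisible(x)
}

#' Persist / restore a calibration as JSON
#'
#' `write_calibration()` stores the sweep, coefficients, residuals and
#' generation parameters; `read_calibration()` restores the object.
#' `calibration_table()` returns the theta--SI sweep as a data frame
#' (convenient for CSV export).
#'
#' @param cal An `si_calibration`.
#' @param path JSON file path.
#' @return `write_calibration()`: `path`, invisibly.
#'   `read_calibration()`: an `si_calibration`.
#'   `calibration_table()`: a data frame with columns `theta_deg`, `si`.
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "si_calibration"))
  out <- unclass(cal)
  out$coefficients <- as.list(out$coefficients)   # keep names in JSON
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cf <- unlist(x$coefficients)
  out <- si_calibration(cf[["A"]], cf[["B"]], cf[["C"]], cf[["D"]])
  out$theta_grid <- x$theta_grid
  out$si <- x$si
  out$residuals <- x$residuals
  out$rms_residual <- if (is.null(x$rms_residual)) NA_real_ else x$rms_residual
  out$params <- x$params
  out
}

#' @rdname write_calibration
#' @export
calibration_table <- function(cal) {
  stopifnot(inherits(cal, "si_calibration"))
  if (is.null(cal$si)) stop("calibration carries no sweep data", call. = FALSE)
  data.frame(theta_deg = cal$theta_grid, si = cal$si)
}
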