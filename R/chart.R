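## Procedural Sloan-style glyphs on the 5x5 stroke grid (1 = ink).
## Letter height = 5 strokes, the construction behind decimal acuity
## sizing; includes the tumbling-E glyph for E-chart mode.
.sloan_glyphs <- local({
  g <- function(...) matrix(as.integer(strsplit(paste0(...), "")[[1]]),
                            5, 5, byrow = TRUE)
  list(
    C = g("11111", "10000", "10000", "10000", "11111"),
    D = g("11110", "10001", "10001", "10001", "11110"),
    H = g("10001", "10001", "11111", "10001", "10001"),
    K = g("10001", "10010", "11100", "10010", "10001"),
    N = g("10001", "11001", "10101", "10011", "10001"),
    O = g("11111", "10001", "10001", "10001", "11111"),
    R = g("11110", "10001", "11110", "10010", "10001"),
    S = g("11111", "10000", "11111", "00001", "11111"),
    V = g("10001", "10001", "10001", "01010", "00100"),
    Z = g("11111", "00010", "00100", "01000", "11111"),
    E = g("11111", "10000", "11110", "10000", "11111")
  )
})

#' Sloan letter set used by the chart factory
#' @return Character vector of the ten Sloan letters (plus "E" available
#'   for tumbling-E charts).
#' @export
sloan_letters <- function() c("C", "D", "H", "K", "N", "O", "R", "S", "V", "Z")

## Deterministic per-VA letter selection: rotate the Sloan set by the
## VA decimal step so successive lines differ but runs are reproducible.
.default_letters <- function(va_decimal, n = 5L) {
  set <- sloan_letters()
  off <- (round(va_decimal * 10) - 1L) %% length(set)
  set[((off + seq_len(n) - 1L) %% length(set)) + 1L]
}

#' Specification of a visual-acuity chart
#'
#' @param va_decimal Decimal visual acuity of the line, in `[0.3, 1.2]`
#'   by convention (a VA 1.0 letter subtends 5 arcmin).
#' @param letters Character vector of glyphs to draw (Sloan set or
#'   `"E"`); default: five letters chosen deterministically from the
#'   Sloan set by VA level.
#' @param viewing_distance_m Nominal viewing distance, metres (metadata;
#'   sizing is angular).
#' @param px_per_degree Display sampling, pixels per degree.
#' @param polarity `"dark-on-light"` (default) or `"light-on-dark"`.
#' @return A `chart_spec` object.
#' @export
chart_spec <- function(va_decimal, letters = NULL,
                       viewing_distance_m = 4, px_per_degree = 120,
                       polarity = c("dark-on-light", "light-on-dark")) {
  polarity <- match.arg(polarity)
  if (!is.finite(va_decimal) || va_decimal <= 0) {
    stop("'va_decimal' must be positive", call. = FALSE)
  }
  if (is.null(letters)) letters <- .default_letters(va_decimal)
  letters <- toupper(letters)
  unknown <- setdiff(letters, names(.sloan_glyphs))
  if (length(letters) == 0L || length(unknown)) {
    stop("unsupported glyphs: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (px_per_degree <= 0) stop("'px_per_degree' must be positive",
                               call. = FALSE)
  structure(list(va_decimal = va_decimal, letters = letters,
                 viewing_distance_m = viewing_distance_m,
                 px_per_degree = px_per_degree, polarity = polarity),
            class = "chart_spec")
}

#' Letter height in pixels for a decimal acuity
#'
#' A decimal-VA `v` letter subtends `5 / v` arcmin (five stroke widths of
#' `1 / v` arcmin each). Returns that height at the given display
#' sampling, rounded to the nearest integer; an error is raised if fewer
#' than 5 pixels remain, since the 5-stroke glyph grid is then
#' unrenderable.
#'
#' @param va_decimal Decimal visual acuity, `> 0`.
#' @param px_per_degree Display sampling, pixels per degree.
#' @return Integer letter height in pixels (`>= 5`).
#' @examples
#' letter_height_px(1.0, 60)    # 5 px: 5 arcmin at 1 px/arcmin
#' letter_height_px(0.3, 120)   # 33 px
#' @export
letter_height_px <- function(va_decimal, px_per_degree) {
  if (!is.finite(va_decimal) || va_decimal <= 0) {
    stop("'va_decimal' must be positive", call. = FALSE)
  }
  h <- as.integer(round((5 / va_decimal) / 60 * px_per_degree))
  if (h < 5L) {
    stop(sprintf(
      "resolution too low to render 5 strokes at VA %.2f (%d px)",
      va_decimal, h), call. = FALSE)
  }
  h
}

## Rasterize one glyph into an h x h block by nearest stroke-cell lookup.
.raster_glyph <- function(glyph, h) {
  idx <- pmin(5L, pmax(1L, ceiling(seq_len(h) * 5 / h)))
  glyph[idx, idx, drop = FALSE]
}

#' Render a straylight-free visual-acuity chart
#'
#' Draws the spec's letters as a single centred row of 5x5-stroke-grid
#' Sloan-style glyphs (spacing one letter width), dark letters
#' (intensity 0) on a light field (intensity 1) unless the polarity is
#' inverted. Rendering is purely procedural and bit-deterministic.
#'
#' @param spec A [chart_spec()].
#' @param side_px Canvas side in pixels.
#' @return An `optotype_image`: an [angular_image()] with fields
#'   `va_decimal`, `si_label` (0 here) and `provenance`.
#' @examples
#' ch <- render_chart(chart_spec(0.5, letters = "E"), side_px = 128)
#' michelson_contrast(ch$image)
#' @export
render_chart <- function(spec, side_px = 512) {
  stopifnot(inherits(spec, "chart_spec"))
  h <- letter_height_px(spec$va_decimal, spec$px_per_degree)
  n <- length(spec$letters)
  width <- n * h + (n - 1L) * h          # letters + one-letter gaps
  if (width > side_px || h > side_px) {
    stop(sprintf("too many letters for the frame: need %d px, have %d",
                 width, side_px), call. = FALSE)
  }
  canvas <- matrix(1, side_px, side_px)
  row0 <- (side_px - h) %/% 2L
  col <- (side_px - width) %/% 2L
  for (L in spec$letters) {
    block <- .raster_glyph(.sloan_glyphs[[L]], h)
    sub <- canvas[(row0 + 1L):(row0 + h), (col + 1L):(col + h)]
    sub[block == 1L] <- 0
    canvas[(row0 + 1L):(row0 + h), (col + 1L):(col + h)] <- sub
    col <- col + 2L * h
  }
  if (spec$polarity == "light-on-dark") canvas <- 1 - canvas
  optotype_image(angular_image(canvas, 1 / spec$px_per_degree),
                 va_decimal = spec$va_decimal, si_label = 0,
                 provenance = list(letters = spec$letters,
                                   px_per_degree = spec$px_per_degree,
                                   side_px = side_px,
                                   polarity = spec$polarity))
}

#' Optotype image container
#'
#' @param image An [angular_image()] with values in `[0, 1]`.
#' @param va_decimal Decimal visual acuity of the chart.
#' @param si_label Straylight-index level applied (0 = straylight-free).
#' @param provenance List of generation parameters.
#' @return An `optotype_image` object.
#' @export
optotype_image <- function(image, va_decimal, si_label = 0,
                           provenance = list()) {
  stopifnot(inherits(image, "angular_image"))
  if (si_label < 0 || si_label > 1) stop("'si_label' must be in [0, 1]",
                                         call. = FALSE)
  if (max(image) > 1 + 1e-9) stop("optotype intensities must be in [0, 1]",
                                  call. = FALSE)
  structure(list(image = image, va_decimal = va_decimal,
                 si_label = si_label, provenance = provenance),
            class = "optotype_image")
}

#' @export
print.optotype_image <- function(x, ...) {
  cat(sprintf("optotype chart: VA %.1f, SI %.1f, %d x %d px at %g deg/px\n",
              x$va_decimal, x$si_label, nrow(x$image), ncol(x$image),
              deg_per_px(x$image)))
  invisible(x)
}

#' Degrade a chart to a prescribed straylight index
#'
#' Maps the requested SI to its glare angle through the calibration
#' ([si_to_theta()]), builds the GSF kernel at the chart's own angular
#' sampling, and veils the chart with it ([apply_glare()]). The kernel
#' grid is capped at the chart frame; the far-field kernel weight is
#' applied as a uniform veil at the chart's border intensity (exact for
#' the uniform chart background).
#'
#' @param chart An [optotype_image()] (normally straylight-free).
#' @param si Target straylight index in `(0, 1]`.
#' @param cal An `si_calibration`.
#' @param eye An [eye_params()] object.
#' @param max_theta_deg Cap on the implied glare angle (default 90 deg);
#'   beyond it the request is refused.
#' @return An `optotype_image` with `si_label = si`, same dimensions and
#'   `[0, 1]` range as the input.
#' @export
degrade_chart <- function(chart, si, cal, eye = eye_params(),
                          max_theta_deg = 90) {
  stopifnot(inherits(chart, "optotype_image"),
            inherits(cal, "si_calibration"))
  if (length(si) != 1L || !is.finite(si) || si <= 0 || si > 1) {
    stop("'si' must be a single value in (0, 1]", call. = FALSE)
  }
  theta <- si_to_theta(si, cal)
  if (theta > max_theta_deg) {
    stop(sprintf("kernel support %.1f deg exceeds the cap of %g deg",
                 theta, max_theta_deg), call. = FALSE)
  }
  dpp <- deg_per_px(chart$image)
  cap <- min(dim(chart$image))
  cap <- cap + (cap %% 2L == 0L)
  kern <- build_kernel(theta, dpp, eye, max_side_px = cap)
  veiled <- apply_glare(chart$image, kern)
  veiled <- angular_image(pmin(unclass(veiled), 1), dpp)
  optotype_image(veiled, va_decimal = chart$va_decimal, si_label = si,
                 provenance = c(chart$provenance,
                                list(theta_deg = theta,
                                     age = as_eye_params(eye)$age,
                                     pigment_factor =
                                       as_eye_params(eye)$pigment_factor)))
}

#' Generate the full straylight-degraded chart set
#'
#' For every acuity level writes one straylight-free chart plus one chart
#' per SI level (defaults: VA 0.3--1.2 in steps of 0.1 and SI 0.1--1.0 in
#' steps of 0.1, i.e. 10 x 11 = 110 PNG files), together with a CSV
#' manifest listing filename, VA, SI, glare angle, Michelson contrast and
#' the generation parameters.
#'
#' @param out_dir Output directory; must be empty or absent unless
#'   `force = TRUE`.
#' @param va_levels Decimal acuity levels.
#' @param si_levels Straylight-index levels (excluding the
#'   straylight-free charts, which are always produced).
#' @param cal An `si_calibration` used for the SI-to-theta mapping.
#' @param eye An [eye_params()] object.
#' @param side_px Chart canvas side in pixels.
#' @param px_per_degree Display sampling.
#' @param letters Optional fixed letter vector (e.g. `"E"` for a
#'   tumbling-E set); default chooses Sloan letters per VA level.
#' @param force Overwrite a non-empty `out_dir`.
#' @return The manifest as a data frame, invisibly; also written to
#'   `file.path(out_dir, "manifest.csv")`.
#' @export
generate_chart_set <- function(out_dir,
                               va_levels = seq(0.3, 1.2, by = 0.1),
                               si_levels = seq(0.1, 1.0, by = 0.1),
                               cal = reference_calibration(),
                               eye = eye_params(),
                               side_px = 512, px_per_degree = 120,
                               letters = NULL, force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0L && !force) {
    stop("output directory exists and is not empty (use force = TRUE)",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  eye <- as_eye_params(eye)
  rows <- vector("list", length(va_levels) * (length(si_levels) + 1L))
  i <- 0L
  for (va in va_levels) {
    spec <- chart_spec(va, letters = letters, px_per_degree = px_per_degree)
    base <- render_chart(spec, side_px = side_px)
    dpp <- deg_per_px(base$image)
    for (si in c(0, si_levels)) {
      ch <- if (si == 0) base else degrade_chart(base, si, cal, eye)
      fn <- sprintf("VA%.1f_SI%.1f.png", va, si)
      write_angular_image(ch$image, file.path(out_dir, fn))
      i <- i + 1L
      rows[[i]] <- data.frame(
        filename = fn, va = va, si = si,
        theta_deg = if (si == 0) 0 else si_to_theta(si, cal),
        contrast = michelson_contrast(ch$image),
        side_px = side_px, px_per_degree = px_per_degree,
        deg_per_px = dpp, age = eye$age,
        pigment_factor = eye$pigment_factor,
        letters = paste(spec$letters, collapse = ""))
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
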