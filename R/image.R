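#' Grayscale image with a known angular scale
#'
#' Thin wrapper pairing a matrix of non-negative intensities with its
#' angular sampling in degrees per pixel. All simulation routines in the
#' package operate on these.
#'
#' @param values Numeric matrix of finite, non-negative intensities
#'   (internally images live in `[0, 1]`; 8-bit quantization happens only
#'   at PNG/TIFF export).
#' @param deg_per_px Degrees subtended by one pixel, `> 0`.
#' @return An `angular_image` object.
#' @examples
#' angular_image(matrix(1, 32, 32), deg_per_px = 0.05)
#' @export
angular_image <- function(values, deg_per_px) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("image intensities must be finite and non-negative", call. = FALSE)
  }
  if (!is.numeric(deg_per_px) || length(deg_per_px) != 1L ||
      !is.finite(deg_per_px) || deg_per_px <= 0) {
    stop("'deg_per_px' must be a single positive number", call. = FALSE)
  }
  structure(values, deg_per_px = deg_per_px,
            class = c("angular_image", "matrix", "array"))
}

#' @export
print.angular_image <- function(x, ...) {
  cat(sprintf(
    "angular image: %d x %d px at %g deg/px (field %.2f x %.2f deg), range [%.3g, %.3g]\n",
    nrow(x), ncol(x), attr(x, "deg_per_px"),
    nrow(x) * attr(x, "deg_per_px"), ncol(x) * attr(x, "deg_per_px"),
    min(x), max(x)))
  invisible(x)
}

deg_per_px <- function(x) attr(x, "deg_per_px")

## Pixel-center angular coordinates of rows/cols about the image center.
.axis_deg <- function(n, dpp) ((seq_len(n)) - (n + 1) / 2) * dpp

## Radius map (degrees) of an image about its center.
.radius_map <- function(img) {
  dpp <- deg_per_px(img)
  rx <- .axis_deg(nrow(img), dpp)
  cx <- .axis_deg(ncol(img), dpp)
  sqrt(outer(rx^2, cx^2, "+"))
}

## Edge-replicate padding: rows padded by (pt, pb), cols by (pl, pr).
.pad_replicate <- function(m, pt, pb, pl, pr) {
  ri <- c(rep(1L, pt), seq_len(nrow(m)), rep(nrow(m), pb))
  ci <- c(rep(1L, pl), seq_len(ncol(m)), rep(ncol(m), pr))
  m[ri, ci, drop = FALSE]
}

## Frequency-domain 2-D convolution with edge-replicate padding of at
## least half the kernel side; output cropped to the input size.
.conv_fft <- function(img, ker) {
  n1 <- nrow(img); n2 <- ncol(img)
  ks <- nrow(ker); half <- (ks - 1L) %/% 2L
  t1 <- stats::nextn(n1 + ks - 1L, c(2, 3, 5))
  t2 <- stats::nextn(n2 + ks - 1L, c(2, 3, 5))
  p1 <- (t1 - n1) %/% 2L
  p2 <- (t2 - n2) %/% 2L
  A <- .pad_replicate(img, p1, t1 - n1 - p1, p2, t2 - n2 - p2)
  K <- matrix(0, t1, t2)
  K[seq_len(ks), seq_len(ks)] <- ker
  if (half > 0L) {
    K <- K[c((half + 1L):t1, seq_len(half)),
           c((half + 1L):t2, seq_len(half)), drop = FALSE]
  }
  out <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) /
    (t1 * t2)
  out[(p1 + 1L):(p1 + n1), (p2 + 1L):(p2 + n2), drop = FALSE]
}

## Mean intensity of the one-pixel border frame of an image.
.border_mean <- function(img) {
  n1 <- nrow(img); n2 <- ncol(img)
  if (n1 <= 2L || n2 <= 2L) return(mean(img))
  mean(c(img[1L, ], img[n1, ], img[2:(n1 - 1L), 1L], img[2:(n1 - 1L), n2]))
}

#' Convolve an image with a glare-spread-function kernel
#'
#' Applies veiling glare to an image: the two-dimensional convolution of
#' the image with a unit-sum GSF kernel, computed in the frequency domain
#' with edge-replicate padding of half the kernel side and cropped back to
#' the input size. If the kernel carries a far-field `tail_fraction`
#' (support capped by [build_kernel()]), that weight is added back as a
#' uniform veil at the image's mean border intensity — exact when the
#' border is uniform, since every far tap lands on replicated edge pixels.
#'
#' @param image An [angular_image()].
#' @param kernel A [build_kernel()] result with the same `deg_per_px`
#'   (within 1e-6 relative).
#' @return An [angular_image()] of the same dimensions; intensities are
#'   clipped at 0 to remove FFT round-off.
#' @examples
#' img <- angular_image(matrix(runif(64^2), 64, 64), 0.05)
#' k <- build_kernel(1, 0.05)
#' blurred <- apply_glare(img, k)
#' @export
apply_glare <- function(image, kernel) {
  if (!inherits(image, "angular_image")) {
    stop("'image' must be an angular_image", call. = FALSE)
  }
  if (!inherits(kernel, "gsf_kernel")) {
    stop("'kernel' must be a gsf_kernel", call. = FALSE)
  }
  if (!isTRUE(attr(kernel, "normalized")) ||
      abs(sum(kernel) + attr(kernel, "tail_fraction") - 1) > 1e-9) {
    stop("kernel is not normalized", call. = FALSE)
  }
  di <- deg_per_px(image); dk <- deg_per_px(kernel)
  if (abs(di - dk) > 1e-6 * max(di, dk)) {
    stop(sprintf(
      "angular scales differ: image %g deg/px vs kernel %g deg/px", di, dk),
      call. = FALSE)
  }
  out <- .conv_fft(unclass(image), unclass(kernel))
  tf <- attr(kernel, "tail_fraction")
  if (tf > 0) out <- out + tf * .border_mean(image)
  angular_image(pmax(out, 0), di)
}

#' Michelson contrast of an image
#'
#' `(max - min) / (max + min)` over all pixels; 0 for a uniform image
#' (including an all-black one, by convention).
#'
#' @param image Numeric matrix or [angular_image()].
#' @return Contrast in `[0, 1]`.
#' @export
michelson_contrast <- function(image) {
  hi <- max(image); lo <- min(image)
  if (hi + lo == 0) return(0)
  (hi - lo) / (hi + lo)
}

#' Read a grayscale image with an angular scale
#'
#' Reads a PNG or TIFF (by extension), averaging channels if the file is
#' not already single-channel.
#'
#' @param path PNG or TIFF file path.
#' @param deg_per_px Angular sampling to attach, degrees per pixel.
#' @return An [angular_image()] with values in `[0, 1]`.
#' @export
read_angular_image <- function(path, deg_per_px) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
              png = png::readPNG(path),
              tif = ,
              tiff = tiff::readTIFF(path),
              stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3L, dim(a)[3L])], c(1, 2), mean)
  angular_image(a, deg_per_px)
}

#' Write an angular image as 8-bit grayscale PNG or TIFF
#'
#' Values are clipped to `[0, 1]`; quantization to 8 bits happens here
#' and only here.
#'
#' @param image An [angular_image()] (or plain matrix).
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_angular_image <- function(image, path) {
  m <- pmin(pmax(unclass(image), 0), 1)
  ## quantize explicitly so files round-trip bit-identically
  m <- round(m * 255) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(m, path),
         tif = ,
         tiff = tiff::writeTIFF(m, path, bits.per.sample = 8L,
                                compression = "none"),
         stop("unsupported image format: ", ext, call. = FALSE))
  invisible(path)
}
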