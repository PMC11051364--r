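#' Gaussian peak fit to an SSI histogram
#'
#' Bins the SSI values into equal-width intervals spanning their range
#' and fits `count = amplitude * exp(-(center - peak)^2 / (2 width^2))`
#' to the bin counts by nonlinear least squares. Reported R^2 is
#' `1 - SS_res / SS_tot` on the counts. A skew-normal-shaped variant
#' (Gaussian times a logistic asymmetry factor) is available for
#' visibly asymmetric histograms but is not the default.
#'
#' @param ssi_values Numeric vector, `n >= 8`, not all equal.
#' @param n_bins Number of histogram intervals, `>= 3` (default 4, the
#'   conventional choice for a cohort of ~30).
#' @param skew If `TRUE` fit the asymmetric variant.
#' @return A `gaussian_fit` list: `peak_location`, `amplitude`, `width`,
#'   `r_squared`, `n_bins`, `bin_centers`, `counts`, `skew`.
#' @examples
#' set.seed(1)
#' fit <- ssi_histogram_fit(rnorm(1000, 0.46, 0.07), n_bins = 12)
#' fit$peak_location
#' @export
ssi_histogram_fit <- function(ssi_values, n_bins = 4, skew = FALSE) {
  ssi_values <- ssi_values[is.finite(ssi_values)]
  if (length(ssi_values) < 8L) stop("need at least 8 SSI values",
                                    call. = FALSE)
  if (n_bins < 3L) stop("'n_bins' must be >= 3", call. = FALSE)
  if (diff(range(ssi_values)) == 0) {
    stop("degenerate input: all SSI values equal", call. = FALSE)
  }
  h <- graphics::hist(ssi_values,
                      breaks = seq(min(ssi_values), max(ssi_values),
                                   length.out = n_bins + 1L),
                      plot = FALSE)
  x <- h$mids; y <- h$counts
  start <- list(amplitude = max(y),
                peak = sum(x * y) / sum(y),
                width = max(stats::sd(ssi_values), diff(range(x)) / 10))
  fit <- if (skew) {
    minpack.lm::nlsLM(
      y ~ amplitude * exp(-(x - peak)^2 / (2 * width^2)) *
        (2 / (1 + exp(-alpha * (x - peak)))),
      start = c(start, list(alpha = 0)),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    minpack.lm::nlsLM(
      y ~ amplitude * exp(-(x - peak)^2 / (2 * width^2)),
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  cf <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(peak_location = unname(cf["peak"]),
                 amplitude = unname(cf["amplitude"]),
                 width = abs(unname(cf["width"])),
                 r_squared = max(0, min(1, 1 - ss_res / ss_tot)),
                 n_bins = n_bins, bin_centers = x, counts = y,
                 skew = skew),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf(
    "%s fit to %d-bin histogram: peak %.3f, width %.3f, R^2 = %.2f\n",
    if (x$skew) "skewed gaussian" else "gaussian", x$n_bins,
    x$peak_location, x$width, x$r_squared))
  invisible(x)
}

#' Pearson correlation between two cohort variables
#'
#' Thin wrapper around [stats::cor.test()] returning the coefficient,
#' its square, the two-sided p-value and `n`, with input validation
#' (at least 3 complete pairs, non-zero variance in both variables).
#'
#' @param table Data frame.
#' @param x_label,y_label Column names to correlate.
#' @return A `correlation_result` one-row data frame: `pair`, `r`,
#'   `r_squared`, `p_value`, `n`.
#' @examples
#' correlate(data.frame(a = 1:5, b = c(2, 1, 4, 3, 5)), "a", "b")
#' @export
correlate <- function(table, x_label, y_label) {
  miss <- setdiff(c(x_label, y_label), names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  x <- table[[x_label]]; y <- table[[y_label]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 paired finite observations",
                           call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in '",
         if (stats::sd(x) == 0) x_label else y_label, "'", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(data.frame(pair = paste(x_label, "vs", y_label),
                       r = unname(ct$estimate),
                       r_squared = unname(ct$estimate)^2,
                       p_value = ct$p.value, n = length(x)),
            class = c("correlation_result", "data.frame"))
}

#' Population analysis of a straylight cohort
#'
#' Reproduces the cohort-level analysis template: a Gaussian peak fit to
#' the SSI histogram, Pearson correlations of SSI with every aberration
#' RMS term (LOA, HOA, defocus, coma, spherical, trefoil) and with the
#' photostress recovery time at each of the five target contrasts
#' (100/50/25/10/5%), each flagged for significance at `alpha`.
#' P-values are reported raw; set `adjust = "holm"` for a clearly
#' labelled family-wise correction (off by default, matching the
#' convention of reporting unadjusted Pearson tests).
#'
#' @param cohort Cohort data frame ([generate_population()] /
#'   [read_cohort()] schema) or a CSV path.
#' @param n_bins Histogram intervals for the SSI fit.
#' @param alpha Significance level for flagging.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return A `straylight_study` list: `gaussian_fit`, `correlations`
#'   (data frame with `pair`, `r`, `r_squared`, `p_value`, optional
#'   `p_adjusted`, `significant`, `n`), `alpha`, `n_subjects`.
#' @examples
#' run_study(generate_population(40, seed = 2))
#' @export
run_study <- function(cohort, n_bins = 4, alpha = 0.05,
                      adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  if (is.character(cohort) && length(cohort) == 1L) {
    cohort <- read_cohort(cohort)
  }
  need <- c("ssi", "rms_loa", "rms_hoa", "defocus", "coma", "spherical",
            "trefoil", "rt_100", "rt_50", "rt_25", "rt_10", "rt_5")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  gfit <- ssi_histogram_fit(cohort$ssi, n_bins = n_bins)
  vars <- setdiff(need, "ssi")
  cors <- do.call(rbind, lapply(vars, function(v) {
    correlate(cohort, "ssi", v)
  }))
  cors <- as.data.frame(cors)
  if (adjust == "holm") {
    cors$p_adjusted <- stats::p.adjust(cors$p_value, method = "holm")
    cors$significant <- cors$p_adjusted < alpha
  } else {
    cors$significant <- cors$p_value < alpha
  }
  structure(list(gaussian_fit = gfit, correlations = cors, alpha = alpha,
                 adjust = adjust, n_subjects = nrow(cohort)),
            class = "straylight_study")
}

#' @export
print.straylight_study <- function(x, digits = 3, ...) {
  cat(sprintf("straylight cohort analysis (n = %d)\n", x$n_subjects))
  print(x$gaussian_fit)
  cat(sprintf("\nPearson correlations with SSI (alpha = %g%s):\n",
              x$alpha, if (x$adjust == "holm") ", Holm-adjusted" else ""))
  d <- x$correlations
  d$r <- round(d$r, digits); d$r_squared <- round(d$r_squared, digits)
  d$p_value <- signif(d$p_value, digits)
  print.data.frame(d, row.names = FALSE)
  invisible(x)
}

#' Markdown summary of a study report
#'
#' Renders the correlation table of a [run_study()] report as a small
#' Markdown table (one row per variable), mirroring the usual layout of
#' cohort aberrometry tables.
#'
#' @param study A `straylight_study`.
#' @return Character vector of Markdown lines, invisibly; also printed.
#' @export
study_markdown <- function(study) {
  stopifnot(inherits(study, "straylight_study"))
  d <- study$correlations
  lines <- c(
    sprintf("SSI gaussian peak: %.3f (R^2 = %.2f, %d bins)",
            study$gaussian_fit$peak_location, study$gaussian_fit$r_squared,
            study$gaussian_fit$n_bins),
    "",
    "| variable | r | R^2 | p | significant |",
    "|---|---|---|---|---|",
    sprintf("| %s | %.3f | %.3f | %.3g | %s |",
            sub("^ssi vs ", "", d$pair), d$r, d$r_squared, d$p_value,
            ifelse(d$significant, "yes", "no")))
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Persist a study report as JSON
#'
#' @param study A `straylight_study`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_study <- function(study, path) {
  stopifnot(inherits(study, "straylight_study"))
  out <- list(
    gaussian_fit = study$gaussian_fit[c("peak_location", "amplitude",
                                        "width", "r_squared", "n_bins")],
    correlations = study$correlations,
    alpha = study$alpha, adjust = study$adjust,
    n_subjects = study$n_subjects)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
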