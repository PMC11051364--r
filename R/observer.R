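#' Simulated chart observer
#'
#' A minimal mechanistic observer linking chart tolerance to retinal
#' image contrast: a chart is tolerated when its acuity does not exceed
#' the observer's acuity limit and the degraded chart's Michelson
#' contrast is at least `contrast_threshold` plus an optional per-VA
#' increment (`threshold_slope`, anchored at VA 0.3).
#'
#' @param contrast_threshold Minimum whole-frame Michelson contrast
#'   required at VA 0.3, in `(0, 1]`. Veiled charts retain a bright
#'   surround, so frame contrasts are far below classic letter-contrast
#'   thresholds; the default 0.02 places an average observer mid-range on
#'   the default chart set.
#' @param acuity_limit Best resolvable decimal acuity, in `(0, 2]`.
#' @param threshold_slope Extra contrast required per decimal-VA unit
#'   above 0.3 (`>= 0`).
#' @return An `observer_model` object.
#' @examples
#' observer_model(contrast_threshold = 0.02, acuity_limit = 1.2)
#' @export
observer_model <- function(contrast_threshold = 0.02, acuity_limit = 1.2,
                           threshold_slope = 0) {
  if (!is.finite(contrast_threshold) || contrast_threshold <= 0 ||
      contrast_threshold > 1) {
    stop("'contrast_threshold' must lie in (0, 1]", call. = FALSE)
  }
  if (!is.finite(acuity_limit) || acuity_limit <= 0 || acuity_limit > 2) {
    stop("'acuity_limit' must lie in (0, 2]", call. = FALSE)
  }
  if (!is.finite(threshold_slope) || threshold_slope < 0) {
    stop("'threshold_slope' must be >= 0", call. = FALSE)
  }
  structure(list(contrast_threshold = contrast_threshold,
                 acuity_limit = acuity_limit,
                 threshold_slope = threshold_slope),
            class = "observer_model")
}

#' @export
print.observer_model <- function(x, ...) {
  cat(sprintf(
    "simulated observer: contrast threshold %.2f (+%.2f per VA unit), acuity limit %.2f\n",
    x$contrast_threshold, x$threshold_slope, x$acuity_limit))
  invisible(x)
}

.required_contrast <- function(observer, va) {
  observer$contrast_threshold + observer$threshold_slope * (va - 0.3)
}

#' Does the observer tolerate a chart?
#'
#' @param observer An [observer_model()].
#' @param chart An [optotype_image()] (its `va_decimal` and image
#'   contrast drive the decision).
#' @return `TRUE` if tolerated.
#' @export
observe_chart <- function(observer, chart) {
  stopifnot(inherits(observer, "observer_model"),
            inherits(chart, "optotype_image"))
  if (chart$va_decimal > observer$acuity_limit) return(FALSE)
  michelson_contrast(chart$image) >=
    .required_contrast(observer, chart$va_decimal)
}

#' Simulate a full chart-set session
#'
#' Produces one tolerance response per chart of a generated set. The
#' manifest's stored Michelson contrasts drive the decision, so a session
#' over an in-memory manifest needs no file I/O; passing the chart-set
#' directory re-reads `manifest.csv`. Deterministic given observer and
#' charts.
#'
#' @param observer An [observer_model()].
#' @param charts Either the manifest data frame returned by
#'   [generate_chart_set()] (columns `va`, `si`, `contrast`) or the
#'   chart-set directory containing `manifest.csv`.
#' @param subject_id Label copied into the response table.
#' @return A response data frame (`subject_id`, `va`, `si`, `tolerated`)
#'   suitable for [build_ssf()].
#' @export
simulate_session <- function(observer, charts, subject_id = "sim") {
  stopifnot(inherits(observer, "observer_model"))
  if (is.character(charts) && length(charts) == 1L) {
    mf <- file.path(charts, "manifest.csv")
    if (!file.exists(mf)) stop("no manifest.csv in ", charts, call. = FALSE)
    charts <- utils::read.csv(mf, stringsAsFactors = FALSE)
  }
  need <- c("va", "si", "contrast")
  miss <- setdiff(need, names(charts))
  if (length(miss)) stop("manifest lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  tol <- charts$va <= observer$acuity_limit &
    charts$contrast >= .required_contrast(observer, charts$va)
  data.frame(subject_id = subject_id, va = charts$va, si = charts$si,
             tolerated = as.integer(tol))
}
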