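#' Build a subjective straylight function from tolerance responses
#'
#' The subjective straylight function (SSF) records, for each acuity
#' level, the largest straylight index the observer still tolerated (the
#' chart remained resolvable); acuity levels where no degraded chart was
#' tolerated score 0. Duplicate responses for the same (VA, SI) pair are
#' resolved last-wins with a warning. No monotonicity in VA is imposed
#' and no smoothing is applied.
#'
#' @param responses Data frame with columns `va` (decimal acuity in
#'   `[0.3, 1.2]`), `si` (straylight index of the chart) and `tolerated`
#'   (logical or 0/1).
#' @param subject_id Optional label attached to the curve.
#' @return An `ssf_curve`: a data frame with columns `va` (strictly
#'   increasing) and `max_si`, with attribute `subject_id`.
#' @examples
#' r <- expand.grid(va = c(0.4, 0.8), si = c(0.2, 0.4, 0.6))
#' r$tolerated <- r$si <= ifelse(r$va <= 0.5, 0.6, 0.2)
#' build_ssf(r)
#' @export
build_ssf <- function(responses, subject_id = NA_character_) {
  need <- c("va", "si", "tolerated")
  miss <- setdiff(need, names(responses))
  if (length(miss)) stop("missing response columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(responses) == 0L) stop("no responses", call. = FALSE)
  va <- responses$va
  if (any(va < 0.3 - 1e-9) || any(va > 1.2 + 1e-9)) {
    stop("VA outside [0.3, 1.2]", call. = FALSE)
  }
  key <- paste(round(va, 6), round(responses$si, 6))
  if (anyDuplicated(key)) {
    warning("duplicate (va, si) responses; keeping the last of each")
    keep <- !duplicated(key, fromLast = TRUE)
    responses <- responses[keep, , drop = FALSE]
  }
  tol <- as.logical(responses$tolerated)
  grid <- sort(unique(responses$va))
  max_si <- vapply(grid, function(v) {
    s <- responses$si[responses$va == v & tol]
    if (length(s)) max(s) else 0
  }, 0)
  structure(data.frame(va = grid, max_si = max_si),
            subject_id = subject_id,
            class = c("ssf_curve", "data.frame"))
}

#' @export
print.ssf_curve <- function(x, ...) {
  sid <- attr(x, "subject_id")
  cat(sprintf("subjective straylight function%s: %d VA levels\n",
              if (is.na(sid)) "" else paste0(" [", sid, "]"), nrow(x)))
  print.data.frame(x, row.names = FALSE)
  ssi <- tryCatch(compute_ssi(x)$ssi, error = function(e) NA_real_)
  if (!is.na(ssi)) cat(sprintf("SSI = %.3f\n", ssi))
  invisible(x)
}

#' @export
plot.ssf_curve <- function(x, ...) {
  graphics::plot(x$va, x$max_si, type = "b", pch = 16,
                 xlim = c(0.3, 1.2), ylim = c(0, 1),
                 xlab = "decimal visual acuity",
                 ylab = "maximum tolerated SI",
                 main = "subjective straylight function", ...)
  invisible(x)
}

## Trapezoidal area under (x, y); x increasing.
.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + y[-1])) / 2

#' Subjective straylight index: area under the SSF
#'
#' Trapezoidal integral of the maximum tolerated SI over decimal acuity
#' `[va_min, va_max]` (defaults 0.3 and 1.2). If the curve's grid does
#' not reach the bounds it is extended flat. The result lies in
#' `[0, (va_max - va_min)]`, i.e. `[0, 0.9]` at the defaults; an
#' optional normalized variant divides by that width.
#'
#' @param curve An `ssf_curve` (or data frame with `va`, `max_si`),
#'   at least 2 grid points.
#' @param va_min,va_max Integration bounds in decimal VA.
#' @param normalized If `TRUE`, divide by `va_max - va_min` (off by
#'   default; population values are conventionally reported
#'   unnormalized).
#' @return An `ssi_value` list: `ssi`, `va_min`, `va_max`, `normalized`.
#' @examples
#' curve <- data.frame(va = seq(0.3, 1.2, 0.1), max_si = 1)
#' compute_ssi(curve)$ssi    # 0.9
#' @export
compute_ssi <- function(curve, va_min = 0.3, va_max = 1.2,
                        normalized = FALSE) {
  if (nrow(curve) < 2L) stop("need at least 2 SSF grid points",
                             call. = FALSE)
  va <- curve$va; y <- curve$max_si
  if (is.unsorted(va, strictly = TRUE)) stop("'va' must be strictly increasing",
                                             call. = FALSE)
  if (any(y < 0) || any(y > 1)) stop("'max_si' must lie in [0, 1]",
                                     call. = FALSE)
  if (va[1L] > va_min) { va <- c(va_min, va); y <- c(y[1L], y) }
  n <- length(va)
  if (va[n] < va_max) { va <- c(va, va_max); y <- c(y, y[n]) }
  ssi <- .trapz(va, y)
  if (normalized) ssi <- ssi / (va_max - va_min)
  structure(list(ssi = ssi, va_min = va_min, va_max = va_max,
                 normalized = normalized),
            class = "ssi_value")
}

#' @export
print.ssi_value <- function(x, ...) {
  cat(sprintf("SSI = %.4f%s (area under SSF over VA [%g, %g])\n", x$ssi,
              if (x$normalized) " (normalized)" else "", x$va_min, x$va_max))
  invisible(x)
}

#' Rank SSF curves by their subjective straylight index
#'
#' Orders two or more SSF curves by SSI (largest first: greater area
#' under the curve means greater tolerance to veiling straylight) and
#' reports all pairwise SSI differences. Curves on different VA grids
#' are linearly resampled onto the union grid first, with a warning.
#'
#' @param curves A list of `ssf_curve` objects (named or not).
#' @return An `ssf_comparison` list: `ranking` (data frame of subject,
#'   SSI) and `pairwise` (matrix of row-minus-column SSI differences).
#' @export
compare_ssf <- function(curves) {
  if (!is.list(curves) || length(curves) < 2L) {
    stop("need at least 2 SSF curves", call. = FALSE)
  }
  ids <- names(curves)
  if (is.null(ids)) ids <- rep(NA_character_, length(curves))
  ids <- ifelse(is.na(ids) | ids == "",
                vapply(seq_along(curves), function(i) {
                  sid <- attr(curves[[i]], "subject_id")
                  if (is.null(sid) || is.na(sid)) paste0("curve", i) else sid
                }, ""), ids)
  grids <- lapply(curves, `[[`, "va")
  union_grid <- sort(unique(unlist(grids)))
  same <- all(vapply(grids, function(g) identical(as.numeric(g),
                                                  as.numeric(union_grid)),
                     TRUE))
  if (!same) {
    warning("SSF grids differ; resampling to the union grid")
    curves <- lapply(curves, function(cv) {
      y <- stats::approx(cv$va, cv$max_si, xout = union_grid, rule = 2)$y
      data.frame(va = union_grid, max_si = y)
    })
  }
  ssi <- vapply(curves, function(cv) compute_ssi(cv)$ssi, 0)
  ord <- order(ssi, decreasing = TRUE)
  pair <- outer(ssi, ssi, "-")
  dimnames(pair) <- list(ids, ids)
  structure(list(
    ranking = data.frame(subject = ids[ord], ssi = ssi[ord]),
    pairwise = pair),
    class = "ssf_comparison")
}

#' @export
print.ssf_comparison <- function(x, ...) {
  cat("SSF comparison (ranked by SSI):\n")
  print.data.frame(x$ranking, row.names = FALSE)
  invisible(x)
}

#' Read / write SSF response tables
#'
#' Response CSVs have columns `subject_id`, `va`, `si`, `tolerated`
#' (0/1). `read_responses()` validates the columns; `score_responses()`
#' builds one SSF and SSI per subject.
#'
#' @param path CSV file path.
#' @return `read_responses()`: the validated data frame.
#'   `score_responses()`: a data frame with one row per subject
#'   (`subject_id`, `ssi`) and the curves in attribute `"curves"`.
#' @export
read_responses <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "va", "si", "tolerated")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing response columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  d
}

#' @rdname read_responses
#' @param responses A response data frame (see `read_responses()`).
#' @export
score_responses <- function(responses) {
  split_r <- split(responses, responses$subject_id)
  curves <- lapply(names(split_r), function(sid) {
    build_ssf(split_r[[sid]], subject_id = sid)
  })
  names(curves) <- names(split_r)
  out <- data.frame(
    subject_id = names(split_r),
    ssi = vapply(curves, function(cv) compute_ssi(cv)$ssi, 0))
  attr(out, "curves") <- curves
  out
}
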