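#' Default effect sizes for the synthetic cohort
#'
#' The generative model behind [generate_population()]:
#' aberration RMS terms are Gaussian with the reported population moments
#' (6-mm pupil, micrometres): LOA 1.82 +/- 1.50, HOA 0.44 +/- 0.59,
#' defocus -1.29 +/- 1.73, coma 0.25 +/- 0.40, spherical 0.01 +/- 0.33,
#' trefoil 0.18 +/- 0.14. SSI is a linear function of defocus and
#' trefoil (both slopes negative) plus Gaussian noise, clipped to
#' `[0, 0.9]`; the intercept is set so the population mean SSI is 0.46.
#' Photostress recovery times at 100% and 50% Michelson contrast depend
#' positively on SSI with population means 4.41 s and 4.38 s; recovery
#' times at 25/10/5% contrast are independent of SSI.
#'
#' Slopes and noise are chosen to reproduce the qualitative population
#' findings (R^2 near 0.4 for the negative defocus and trefoil
#' correlations, a clearly positive high-contrast RT correlation), not
#' any subject-level record.
#'
#' @return Named list of generator parameters; override entries via the
#'   `effects` argument of [generate_population()].
#' @export
cohort_effects <- function() {
  list(
    ## aberration moments (mean, sd) in micrometres RMS
    loa = c(1.82, 1.50), hoa = c(0.44, 0.59),
    defocus = c(-1.29, 1.73), coma = c(0.25, 0.40),
    spherical = c(0.01, 0.33), trefoil = c(0.18, 0.14),
    ## SSI linear model
    ssi_mean = 0.46, slope_defocus = -0.035, slope_trefoil = -0.45,
    ssi_noise_sd = 0.045,
    ## recovery times (seconds)
    rt_mean_100 = 4.41, rt_mean_50 = 4.38,
    rt_slope_100 = 3.0, rt_slope_50 = 3.0, rt_noise_sd = 0.2,
    rt_low_mean = 5.0, rt_low_sd = 0.8)
}

#' Generate a synthetic subject cohort
#'
#' Draws `n` subject records with the statistical structure described in
#' [cohort_effects()]: Zernike RMS aberration terms with the reported
#' population moments, an SSI negatively driven by defocus and trefoil,
#' and photostress recovery times positively driven by SSI at 100% and
#' 50% target contrast but independent of it at 25/10/5%. All randomness
#' flows from `seed`; re-running with identical arguments is
#' bit-reproducible.
#'
#' @param n Number of subjects, `>= 2`.
#' @param seed Integer seed.
#' @param effects Optional list overriding entries of [cohort_effects()].
#' @return A data frame (class `straylight_cohort`) with columns
#'   `subject_id`, `ssi`, `rms_loa`, `rms_hoa`, `defocus`, `coma`,
#'   `spherical`, `trefoil`, `rt_100`, `rt_50`, `rt_25`, `rt_10`, `rt_5`.
#' @examples
#' head(generate_population(30, seed = 7))
#' @export
generate_population <- function(n, seed = 1, effects = list()) {
  if (!is.numeric(n) || n < 2) stop("'n' must be >= 2", call. = FALSE)
  n <- as.integer(n)
  eff <- utils::modifyList(cohort_effects(), effects)
  sds <- c(eff$loa[2], eff$hoa[2], eff$defocus[2], eff$coma[2],
           eff$spherical[2], eff$trefoil[2], eff$ssi_noise_sd,
           eff$rt_noise_sd, eff$rt_low_sd)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("invalid (negative or non-finite) SD in 'effects'", call. = FALSE)
  }
  set.seed(as.integer(seed))
  draw <- function(mo) stats::rnorm(n, mo[1], mo[2])
  loa <- draw(eff$loa); hoa <- draw(eff$hoa)
  defocus <- draw(eff$defocus); coma <- draw(eff$coma)
  spherical <- draw(eff$spherical); trefoil <- draw(eff$trefoil)
  ## intercept chosen so E[SSI] equals ssi_mean at the aberration means
  intercept <- eff$ssi_mean - eff$slope_defocus * eff$defocus[1] -
    eff$slope_trefoil * eff$trefoil[1]
  ssi <- intercept + eff$slope_defocus * defocus +
    eff$slope_trefoil * trefoil + stats::rnorm(n, 0, eff$ssi_noise_sd)
  ssi <- pmin(pmax(ssi, 0), 0.9)
  rt_int_100 <- eff$rt_mean_100 - eff$rt_slope_100 * eff$ssi_mean
  rt_int_50 <- eff$rt_mean_50 - eff$rt_slope_50 * eff$ssi_mean
  rt_100 <- rt_int_100 + eff$rt_slope_100 * ssi +
    stats::rnorm(n, 0, eff$rt_noise_sd)
  rt_50 <- rt_int_50 + eff$rt_slope_50 * ssi +
    stats::rnorm(n, 0, eff$rt_noise_sd)
  rt_25 <- stats::rnorm(n, eff$rt_low_mean, eff$rt_low_sd)
  rt_10 <- stats::rnorm(n, eff$rt_low_mean, eff$rt_low_sd)
  rt_5 <- stats::rnorm(n, eff$rt_low_mean, eff$rt_low_sd)
  out <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    ssi = ssi, rms_loa = loa, rms_hoa = hoa, defocus = defocus,
    coma = coma, spherical = spherical, trefoil = trefoil,
    rt_100 = pmax(rt_100, 0.1), rt_50 = pmax(rt_50, 0.1),
    rt_25 = pmax(rt_25, 0.1), rt_10 = pmax(rt_10, 0.1),
    rt_5 = pmax(rt_5, 0.1))
  class(out) <- c("straylight_cohort", "data.frame")
  attr(out, "seed") <- as.integer(seed)
  attr(out, "effects") <- eff
  out
}

#' Read / write cohort tables
#'
#' One row per subject, columns as in [generate_population()].
#'
#' @param cohort A cohort data frame.
#' @param path CSV file path.
#' @return `write_cohort()`: `path`, invisibly. `read_cohort()`: the
#'   cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(d) <- c("straylight_cohort", "data.frame")
  d
}
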