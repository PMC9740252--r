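# Epithelial barrier metrics (transepithelial electrical resistance,
# apparent permeability of paracellular tracers) and the small statistical
# procedures used for the strand morphometry (pooled two-proportion Z-test,
# Bonferroni-Holm adjustment). TER and flux records are tabular and flow
# through tibbles so plate layouts can be processed with ordinary dplyr
# pipelines.

#' Transepithelial electrical resistance per unit area
#'
#' Blank-corrected resistance times filter area:
#' `(r_sample - r_blank) * filter_area` in Ω·cm². The default filter area is
#' 0.33 cm², the growth area of a 24-well format Transwell insert. A
#' negative blank-corrected resistance is reported with a flag, never
#' silently dropped.
#'
#' @param data Tibble with columns `r_sample` and `r_blank` (Ω); an optional
#'   `filter_area` column overrides the argument.
#' @param filter_area Filter growth area in cm² (default 0.33).
#' @return The input with `ter_ohm_cm2` and logical `flagged` columns.
#' @export
ter_unit_area <- function(data, filter_area = 0.33) {
  if (!all(c("r_sample", "r_blank") %in% names(data))) {
    stop("`data` needs columns r_sample and r_blank", call. = FALSE)
  }
  area <- if ("filter_area" %in% names(data)) data$filter_area else filter_area
  if (any(area <= 0)) stop("filter area must be > 0", call. = FALSE)
  out <- tibble::as_tibble(data)
  out$ter_ohm_cm2 <- (out$r_sample - out$r_blank) * area
  out$flagged <- out$r_sample < out$r_blank
  out
}

#' Apparent permeability coefficient from a receiver time course
#'
#' Fluorescence readings of the receiver compartment are converted to
#' concentrations by linear interpolation on a standard curve, to tracer
#' amounts via the receiver volume, and the transfer rate `dQ/dt` is the
#' least-squares slope of amount versus time. Then
#' `Papp = (dQ/dt) / (area * donor_c0)` in cm/s (with volume in mL = cm³ and
#' `donor_c0` in the same concentration units per mL as the standard curve,
#' the concentration units cancel). No sink-condition correction is applied:
#' receiver accumulation in these assays stays far below the donor
#' concentration. The fit R² is reported.
#'
#' @param readings Tibble with columns `time_s` (ascending) and
#'   `fluorescence`.
#' @param standard_curve Tibble with columns `fluorescence` and
#'   `concentration`, strictly monotone in fluorescence.
#' @param donor_c0 Donor concentration (same units as the standard curve).
#' @param volume_ml Receiver volume in mL.
#' @param area_cm2 Filter area in cm² (default 0.33).
#' @return One-row tibble: `papp_cm_per_s`, `slope_amount_per_s`,
#'   `r_squared`, `n_points`.
#' @export
apparent_permeability <- function(readings, standard_curve, donor_c0,
                                  volume_ml, area_cm2 = 0.33) {
  if (nrow(readings) < 2L) {
    stop("need at least two time points", call. = FALSE)
  }
  if (is.unsorted(readings$time_s, strictly = TRUE)) {
    stop("`readings$time_s` must be strictly increasing", call. = FALSE)
  }
  sc <- standard_curve[order(standard_curve$fluorescence), ]
  dc <- diff(sc$concentration)
  if (any(diff(sc$fluorescence) <= 0) || !(all(dc > 0) || all(dc < 0))) {
    stop("standard curve must be strictly monotone", call. = FALSE)
  }
  conc <- stats::approx(sc$fluorescence, sc$concentration,
                        xout = readings$fluorescence, rule = 2)$y
  amount <- conc * volume_ml
  fit <- stats::lm(amount ~ readings$time_s)
  slope <- stats::coef(fit)[[2]]
  sst <- sum((amount - mean(amount))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  tibble::tibble(
    papp_cm_per_s = slope / (area_cm2 * donor_c0),
    slope_amount_per_s = slope,
    r_squared = r2,
    n_points = nrow(readings)
  )
}

#' Pooled two-proportion Z-test
#'
#' Two-sided Z-test for the difference of two proportions using the pooled
#' proportion, `z = (p1 - p2) / sqrt(p (1 - p) (1/n1 + 1/n2))` with
#' `p = (k1 + k2) / (n1 + n2)`; the p-value comes from the standard normal
#' distribution. Used for proportions of strand appearance types.
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @return One-row tibble: `p1`, `p2`, `z`, `p_value`.
#' @export
two_proportion_z <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("`n` must be > 0", call. = FALSE)
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) {
    stop("counts must satisfy 0 <= k <= n", call. = FALSE)
  }
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  tibble::tibble(p1 = p1, p2 = p2, z = z,
                 p_value = 2 * stats::pnorm(-abs(z)))
}

#' Bonferroni-Holm adjustment of p-values
#'
#' Step-down Holm adjustment: with m p-values sorted ascending, the i-th
#' adjusted value is `max_{j <= i} min(1, (m - j + 1) p_(j))`, returned in
#' the original order. Delegates to [stats::p.adjust()] after validation;
#' adjusting a single p-value is the identity.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @export
holm_bonferroni <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "holm")
}
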