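# Sensitized-emission FRET for intramolecular tension sensors: crossover
# calibration from single-fluorophore reference samples and per-pixel
# apparent-efficiency maps. Channel naming follows the three-filter
# convention: DD = donor excitation / donor emission, DA = donor excitation /
# acceptor emission (the raw FRET channel), AA = acceptor excitation /
# acceptor emission.

#' Calibrate crossover coefficients from single-fluorophore references
#'
#' `beta` (donor bleed-through into the acceptor emission filter) is the
#' least-squares slope through the origin of DA versus DD over
#' above-background pixels of a donor-only sample; `gamma` (acceptor direct
#' cross-excitation) likewise from DA versus AA of an acceptor-only sample.
#'
#' @param donor_only List with elements `dd` and `da` ([intensity_image()]s
#'   of a donor-only sample).
#' @param acceptor_only List with elements `aa` and `da` (acceptor-only
#'   sample).
#' @param background_quantile Pixels above this quantile of the direct
#'   channel are used for the regression (default 0.5).
#' @param min_pixels Minimum number of usable pixels (default 50).
#' @return A list of class `crossover_calibration` with `beta`, `gamma` and
#'   the pixel counts used.
#' @export
calibrate_crossover <- function(donor_only, acceptor_only,
                                background_quantile = 0.5, min_pixels = 50L) {
  slope_origin <- function(direct, transfer, label) {
    x <- direct$pixels; y <- transfer$pixels
    stopifnot(identical(dim(x), dim(y)))
    floorv <- stats::quantile(x, background_quantile, names = FALSE)
    sel <- x >= floorv & x > 0
    if (sum(sel) < min_pixels || sum(x[sel]^2) == 0) {
      stop("crossover calibration failed: too few above-background pixels in ",
           label, " reference", call. = FALSE)
    }
    sum(x[sel] * y[sel]) / sum(x[sel]^2)
  }
  beta <- slope_origin(donor_only$dd, donor_only$da, "donor-only")
  gamma <- slope_origin(acceptor_only$aa, acceptor_only$da, "acceptor-only")
  structure(list(beta = beta, gamma = gamma), class = "crossover_calibration")
}

#' @export
print.crossover_calibration <- function(x, ...) {
  cat(sprintf("<crossover_calibration> beta = %.4g, gamma = %.4g\n",
              x$beta, x$gamma))
  invisible(x)
}

#' Per-pixel apparent FRET efficiency map
#'
#' Computes the crossover-corrected sensitized emission
#' `Fc = DA - beta * DD - gamma * AA` (clipped at zero) and the apparent
#' efficiency `E_app = Fc / (Fc + DD)` wherever `Fc + DD > 0`; pixels without
#' signal are `NA`, never zero, so "no signal" is distinct from "no FRET".
#' No G-factor correction is applied: for an intramolecular 1:1 sensor the
#' map is an efficiency index, comparable within an instrument. Lower
#' efficiency on a junction corresponds to higher mechanical tension on the
#' sensor (sign convention only; no force calibration is performed).
#'
#' @param dd,da,aa Co-registered [intensity_image()]s of the three channels.
#' @param cal A `crossover_calibration` (or list with `beta`, `gamma`).
#' @param method `"ratio_of_total"` (default) uses `Fc / (Fc + DD)`;
#'   `"ratio_to_donor"` uses the monotone alternative `Fc / DD`.
#' @return An [intensity_image()]-like object of class `efficiency_map` whose
#'   `pixels` hold the per-pixel efficiency (NA where undefined).
#' @export
fret_efficiency_map <- function(dd, da, aa, cal,
                                method = c("ratio_of_total", "ratio_to_donor")) {
  method <- match.arg(method)
  stopifnot(inherits(dd, "intensity_image"), inherits(da, "intensity_image"),
            inherits(aa, "intensity_image"))
  if (!identical(dim(dd$pixels), dim(da$pixels)) ||
      !identical(dim(dd$pixels), dim(aa$pixels))) {
    stop("channel images must share the same shape", call. = FALSE)
  }
  fc <- da$pixels - cal$beta * dd$pixels - cal$gamma * aa$pixels
  fc[fc < 0] <- 0
  denom <- if (method == "ratio_of_total") fc + dd$pixels else dd$pixels
  eff <- ifelse(denom > 0, fc / denom, NA_real_)
  structure(
    list(pixels = matrix(eff, nrow(fc), ncol(fc)), pixel_size = dd$pixel_size,
         channel = "fret_efficiency", method = method,
         beta = cal$beta, gamma = cal$gamma),
    class = c("efficiency_map")
  )
}

#' @export
print.efficiency_map <- function(x, ...) {
  v <- x$pixels[is.finite(x$pixels)]
  cat(sprintf("<efficiency_map> %d x %d px, defined %.1f%%, median E = %.3f\n",
              nrow(x$pixels), ncol(x$pixels),
              100 * length(v) / length(x$pixels),
              if (length(v)) stats::median(v) else NA_real_))
  invisible(x)
}
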