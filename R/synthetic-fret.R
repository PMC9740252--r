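# Ground-truthed three-filter FRET channel triplets with declared crossover.

#' Generate a synthetic FRET channel triplet with ground truth
#'
#' The generative model is the exact inverse of the sensitized-emission
#' correction: `DD = donor * (1 - E)`, `AA` = acceptor abundance, and
#' `DA = donor * E + beta * DD + gamma * AA`, plus optional additive Gaussian
#' noise.
#'
#' @param efficiency Matrix of true apparent FRET efficiency per pixel, each
#'   value in \[0, 1\], or a scalar (uniform map) combined with `size`.
#' @param beta Donor bleed-through coefficient (>= 0).
#' @param gamma Acceptor cross-excitation coefficient (>= 0).
#' @param donor Donor abundance map (matrix or scalar, default 1000).
#' @param acceptor Acceptor abundance map (matrix or scalar; defaults to the
#'   donor map, as for an intramolecular sensor).
#' @param size Image side when maps are given as scalars (default 64).
#' @param noise_sd Additive Gaussian noise sd applied to all three channels.
#' @param pixel_size µm/px.
#' @param seed RNG seed.
#' @return List with `dd`, `da`, `aa` ([intensity_image()]) and `truth`
#'   (list: `efficiency`, `beta`, `gamma`, `donor`, `acceptor`).
#' @export
make_fret_triplet <- function(efficiency, beta = 0.6, gamma = 0.1,
                              donor = 1000, acceptor = NULL, size = 64L,
                              noise_sd = 0, pixel_size = 0.1, seed = 1L) {
  if (beta < 0 || gamma < 0) stop("beta and gamma must be >= 0", call. = FALSE)
  as_map <- function(x) if (is.matrix(x)) x else matrix(x, size, size)
  eff <- as_map(efficiency)
  if (any(eff < 0 | eff > 1)) {
    stop("efficiency must be within [0, 1]", call. = FALSE)
  }
  don <- as_map(donor)
  acc <- if (is.null(acceptor)) don else as_map(acceptor)
  stopifnot(identical(dim(eff), dim(don)), identical(dim(eff), dim(acc)))
  local_seed(seed, {
    dd <- don * (1 - eff)
    aa <- acc
    da <- don * eff + beta * dd + gamma * aa
    if (noise_sd > 0) {
      addn <- function(m) pmax(m + matrix(stats::rnorm(length(m), 0, noise_sd),
                                          nrow(m), ncol(m)), 0)
      dd <- addn(dd); aa <- addn(aa); da <- addn(da)
    }
    list(
      dd = intensity_image(dd, pixel_size, "DD"),
      da = intensity_image(da, pixel_size, "DA"),
      aa = intensity_image(aa, pixel_size, "AA"),
      truth = list(efficiency = eff, beta = beta, gamma = gamma,
                   donor = don, acceptor = acc)
    )
  })
}
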