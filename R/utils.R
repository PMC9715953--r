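# Internal helpers shared across modules.

# Canonical polarization-state order used everywhere (stack axes, TIFF pages).
PSHG_STATES <- c("LCP", "RCP", "VLP", "HLP")

# Polarimetric parameter identifiers, in feature-table column order.
PSHG_PARAMS <- c("icp", "rratio", "dcp", "shgcd", "shgld")

# Per-parameter summary/texture statistics, in feature-table column order.
PSHG_STATS <- c("mean", "mad", "contrast", "correlation", "entropy", "asm", "idm")

#' Names of the 36 feature columns
#'
#' Column order is `pixel_density` followed by, for each polarimetric
#' parameter (`icp`, `rratio`, `dcp`, `shgcd`, `shgld`), the seven statistics
#' `mean`, `mad`, `contrast`, `correlation`, `entropy`, `asm`, `idm`.
#'
#' @return Character vector of length 36.
#' @export
feature_column_names <- function() {
  c("pixel_density",
    as.vector(t(outer(PSHG_PARAMS, PSHG_STATS, paste, sep = "_"))))
}

# Truncated-normal sampling by inverse CDF; vectorized over all arguments.
# `lo`/`hi` may collapse to a point, in which case that point is returned.
rtruncnorm_inv <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n)
  p <- pmin(pmax(plo + u * (phi - plo), 1e-12), 1 - 1e-12)
  x <- stats::qnorm(p, mean, sd)
  pmin(pmax(x, lo), hi)
}

# Smoothed unit-variance Gaussian random field; `scale` is the Gaussian
# smoothing sigma in pixels (spatial correlation length of the field).
# The smoothing kernel radius is capped so it never exceeds the image.
smooth_field <- function(height, width, scale) {
  z <- matrix(stats::rnorm(height * width), height, width)
  if (scale > 0) {
    radius <- 2 * ceiling(3 * scale) + 1
    max_r <- min(height, width)
    if (max_r %% 2 == 0) max_r <- max_r - 1
    z <- EBImage::gblur(z, sigma = scale, radius = min(radius, max_r),
                        boundary = "replicate")
    s <- stats::sd(as.vector(z))
    if (s > 0) z <- z / s
  }
  z
}

`%||%` <- function(a, b) if (is.null(a)) b else a
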