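#' Compute Stokes elements from a 16-state polarization stack
#'
#' For each incoming polarization state the analyzed-state intensities are
#' combined as `s0 = I_HLP + I_VLP`, `s1 = I_HLP - I_VLP`,
#' `s3 = I_RCP - I_LCP`. The combination rule is the standard Stokes
#' definition from analyzed intensities; a global intensity scale carries
#' through unchanged (the downstream parameters are ratios or are
#' standardized, so no extra normalization is applied). Repeated frames are
#' averaged before the combination.
#'
#' @param stack A `"polarization_stack"` array
#'   `[height, width, incoming, analyzed(, frame)]` with dimnames naming the
#'   four states LCP, RCP, VLP, HLP on both state axes.
#' @return A `"stokes_maps"` object: lists `s0`, `s1`, `s3`, each holding one
#'   matrix per incoming state.
#' @export
compute_stokes <- function(stack) {
  d <- dim(stack)
  if (length(d) == 4) {
    dim(stack) <- c(d, 1)
    d <- dim(stack)
  }
  stopifnot(length(d) == 5, d[3] == 4, d[4] == 4)
  dn <- dimnames(stack)
  inc_names <- dn[[3]] %||% PSHG_STATES
  ana_names <- dn[[4]] %||% PSHG_STATES
  missing <- setdiff(PSHG_STATES, inc_names)
  if (length(missing))
    stop("missing incoming polarization state(s): ",
         paste(missing, collapse = ", "))
  missing <- setdiff(PSHG_STATES, ana_names)
  if (length(missing))
    stop("missing analyzed polarization state(s): ",
         paste(missing, collapse = ", "))

  avg <- function(inc, ana) {
    m <- stack[, , match(inc, inc_names), match(ana, ana_names), ,
               drop = FALSE]
    rowMeans(array(m, dim = c(d[1] * d[2], d[5])))
  }
  s0 <- s1 <- s3 <- stats::setNames(vector("list", 4), PSHG_STATES)
  for (inc in PSHG_STATES) {
    hlp <- avg(inc, "HLP"); vlp <- avg(inc, "VLP")
    rcp <- avg(inc, "RCP"); lcp <- avg(inc, "LCP")
    s0[[inc]] <- matrix(hlp + vlp, d[1], d[2])
    s1[[inc]] <- matrix(hlp - vlp, d[1], d[2])
    s3[[inc]] <- matrix(rcp - lcp, d[1], d[2])
  }
  structure(list(s0 = s0, s1 = s1, s3 = s3, height = d[1], width = d[2]),
            class = "stokes_maps")
}

#' Fit the SNR calibration curve from repeated frames
#'
#' Computes the per-pixel mean `mu` and standard deviation `sigma` over
#' repeated frames of every raw image, defines `SNR = mu / sigma`, and fits
#' the power law `SNR = a * mu^b` by least squares on log-log axes over
#' pixels with `sigma > 0` and `mu > 0`. For shot-limited noise the expected
#' exponent is `b = 0.5`.
#'
#' Counts are clamped at the detector floor of zero, so pixels whose signal
#' is buried in noise have a censored, flattened `mu`/`sigma` relation. The
#' fit is therefore two-pass: an initial fit over all usable pixels, then a
#' refit restricted to pixels whose initially predicted SNR is at least
#' `refit_min_snr`, where censoring is negligible. The returned law is the
#' refit; using it below its domain (e.g. thresholding dim pixels at
#' SNR = 1) is a deliberate extrapolation of the noise model.
#'
#' @param stack A `"polarization_stack"` with at least 3 frames.
#' @param max_pixels Cap on the number of (pixel, image) samples entering the
#'   fit; a deterministic regular subsample is used above the cap.
#' @param refit_min_snr Predicted-SNR floor for the second pass (default 2);
#'   0 disables the refit.
#' @return A `"snr_calibration"`: `a`, `b`, `n_pixels`, `sigma_resid`
#'   (residual SD on the log scale) and the fitted `mu_range`.
#' @export
fit_snr_calibration <- function(stack, max_pixels = 2e5,
                                refit_min_snr = 2) {
  d <- dim(stack)
  if (length(d) != 5 || d[5] < 3)
    stop("SNR calibration requires a stack with >= 3 repeated frames")
  flat <- array(stack, dim = c(prod(d[1:4]), d[5]))
  mu <- rowMeans(flat)
  sigma <- sqrt(pmax(rowMeans(flat^2) - mu^2, 0) * d[5] / (d[5] - 1))
  keep <- sigma > 0 & mu > 0
  if (!any(keep))
    stop("all pixels constant across frames; no SNR fit possible")
  mu <- mu[keep]; sigma <- sigma[keep]
  if (length(mu) > max_pixels) {
    idx <- seq(1, length(mu), length.out = max_pixels)
    mu <- mu[idx]; sigma <- sigma[idx]
  }
  power_fit <- function(mu, sigma) {
    fit <- stats::lm(log(mu / sigma) ~ log(mu))
    co <- stats::coef(fit)
    list(a = exp(unname(co[1])), b = unname(co[2]),
         resid = stats::sd(stats::residuals(fit)))
  }
  f <- power_fit(mu, sigma)
  if (refit_min_snr > 0) {
    usable <- f$a * mu^f$b >= refit_min_snr
    if (sum(usable) >= 10) {
      mu <- mu[usable]; sigma <- sigma[usable]
      f <- power_fit(mu, sigma)
    }
  }
  structure(list(a = f$a, b = f$b, n_pixels = length(mu),
                 sigma_resid = f$resid, mu_range = range(mu)),
            class = "snr_calibration")
}

#' Predict SNR from mean intensity using a fitted calibration
#'
#' @param calibration A [fit_snr_calibration()] result.
#' @param mu Mean intensity values (counts); non-positive values get SNR 0.
#' @return Predicted `SNR = a * mu^b`, same shape as `mu`.
#' @export
predict_snr <- function(calibration, mu) {
  stopifnot(inherits(calibration, "snr_calibration"))
  out <- ifelse(mu > 0, calibration$a * mu^calibration$b, 0)
  if (is.matrix(mu)) out <- matrix(out, nrow(mu), ncol(mu))
  out
}

#' @exportS3Method generics::glance
glance.snr_calibration <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, n_pixels = x$n_pixels,
                 sigma_resid = x$sigma_resid,
                 mu_min = x$mu_range[1], mu_max = x$mu_range[2])
}

#' Threshold an intensity map on predicted SNR
#'
#' A pixel is valid iff its predicted SNR is at least `min_snr` (inclusive
#' boundary). The default threshold of 1 discards pixels whose signal is
#' comparable to noise. Intensities above the calibration's fitted domain
#' trigger a warning (extrapolation); predictions below the domain are the
#' calibration's normal use, since thresholding happens among dim pixels.
#'
#' @param mu Intensity map (typically the `I_CP` map).
#' @param calibration A [fit_snr_calibration()] result.
#' @param min_snr Minimum SNR; default 1.
#' @return Logical matrix, `TRUE` for valid pixels.
#' @export
snr_mask <- function(mu, calibration, min_snr = 1) {
  pos <- mu[mu > 0]
  if (length(pos) && max(pos) > 2 * calibration$mu_range[2])
    warning("intensity map extends above the SNR calibration domain; ",
            "mask uses extrapolated SNR predictions")
  predict_snr(calibration, mu) >= min_snr
}

#' Average circularly polarized SHG intensity
#'
#' `I_CP = (s0^RCP + s0^LCP) / 2` per pixel.
#'
#' @param stokes A [compute_stokes()] result.
#' @return Matrix of `I_CP` values.
#' @export
compute_icp <- function(stokes) {
  (stokes$s0$RCP + stokes$s0$LCP) / 2
}

#' R-ratio map (achiral susceptibility ratio)
#'
#' With `A = (s0^RCP + s0^LCP) / (s3^RCP - s3^LCP)`, computes
#' `R = 1 + 2A + 2 sqrt(A^2 - 1)`. Pixels with `|A| < 1` (negative radicand)
#' or `|A|` above `a_cap` (numerically meaningless near-zero denominator)
#' are `NA`.
#'
#' @param stokes A [compute_stokes()] result.
#' @param a_cap Upper bound on `|A|`; default `1e6`.
#' @return Matrix of R values with `NA` at invalid pixels.
#' @export
compute_rratio <- function(stokes, a_cap = 1e6) {
  num <- stokes$s0$RCP + stokes$s0$LCP
  den <- stokes$s3$RCP - stokes$s3$LCP
  A <- num / den
  A[!is.finite(A) | abs(A) < 1 | abs(A) > a_cap] <- NA
  1 + 2 * A + 2 * sqrt(A^2 - 1)
}

#' Degree of circular polarization map
#'
#' `DCP = (|s3^RCP| / s0^RCP + |s3^LCP| / s0^LCP) / 2`. Pixels with a
#' non-positive `s0` are `NA`; values above `1 + tol` are unphysical (noise)
#' and set `NA`; values in `(1, 1 + tol]` are clamped to 1.
#'
#' @param stokes A [compute_stokes()] result.
#' @param tol Tolerance above 1 before a pixel is declared invalid.
#' @return Matrix of DCP values in `[0, 1]` with `NA` at invalid pixels.
#' @export
compute_dcp <- function(stokes, tol = 0.05) {
  ok <- stokes$s0$RCP > 0 & stokes$s0$LCP > 0
  dcp <- (abs(stokes$s3$RCP) / stokes$s0$RCP +
            abs(stokes$s3$LCP) / stokes$s0$LCP) / 2
  dcp[!ok] <- NA
  dcp[dcp > 1 + tol] <- NA
  pmin(dcp, 1)
}

#' SHG circular and linear dichroism maps
#'
#' `SHG_CD = 2 (s0^RCP - s0^LCP) / (s0^RCP + s0^LCP)` and
#' `SHG_LD = 2 (s0^VLP - s0^HLP) / (s0^VLP + s0^HLP)`; both lie in
#' `[-2, 2]`. Pixels where either `s0` in the pair is non-positive are `NA`.
#'
#' @param stokes A [compute_stokes()] result.
#' @return List with matrices `shgcd` and `shgld`.
#' @export
compute_dichroisms <- function(stokes) {
  dich <- function(p, q) {
    ok <- p > 0 & q > 0
    out <- 2 * (p - q) / (p + q)
    out[!ok] <- NA
    out
  }
  list(shgcd = dich(stokes$s0$RCP, stokes$s0$LCP),
       shgld = dich(stokes$s0$VLP, stokes$s0$HLP))
}

#' Compute the five polarimetric parameter maps with a validity mask
#'
#' Combines [compute_icp()], [compute_rratio()], [compute_dcp()] and
#' [compute_dichroisms()] and attaches the pixel validity mask: when a
#' calibration is supplied, a pixel is valid iff the SNR predicted from its
#' `I_CP` is at least `min_snr`; otherwise all pixels with `I_CP > 0` are
#' valid. Invalid pixels are excluded from all downstream texture and
#' summary statistics.
#'
#' @param stokes A [compute_stokes()] result.
#' @param calibration Optional [fit_snr_calibration()] result.
#' @param min_snr SNR threshold (inclusive); default 1.
#' @param a_cap,dcp_tol Passed to [compute_rratio()] and [compute_dcp()].
#' @return A `"polar_maps"` object: matrices `icp`, `rratio`, `dcp`,
#'   `shgcd`, `shgld` and the logical `valid` mask.
#' @export
polarimetric_maps <- function(stokes, calibration = NULL, min_snr = 1,
                              a_cap = 1e6, dcp_tol = 0.05) {
  stopifnot(inherits(stokes, "stokes_maps"))
  icp <- compute_icp(stokes)
  valid <- if (is.null(calibration)) icp > 0 else
    snr_mask(icp, calibration, min_snr)
  dich <- compute_dichroisms(stokes)
  structure(list(icp = icp,
                 rratio = compute_rratio(stokes, a_cap),
                 dcp = compute_dcp(stokes, dcp_tol),
                 shgcd = dich$shgcd, shgld = dich$shgld,
                 valid = valid),
            class = "polar_maps")
}
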