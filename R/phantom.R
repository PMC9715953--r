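#' Region parameter set for the synthetic phantom
#'
#' Describes the distribution of polarimetric parameters and fiber content of
#' one tissue-like region (tumor or normal side) of the phantom.
#'
#' @param fiber_density Fraction of pixels carrying SHG signal (collagen
#'   "bright pixel" density), in `[0, 1]`.
#' @param icp_mean Mean circularly polarized SHG intensity `I_CP` of fiber
#'   pixels, in camera counts.
#' @param icp_spread Log-scale standard deviation of the lognormal `I_CP`
#'   distribution (dimensionless).
#' @param r_mean,r_spread Mean and SD of the Gaussian R-ratio distribution,
#'   truncated to the branch that the Stokes inversion can represent exactly
#'   (`R >= 3`; see [generate_phantom()]).
#' @param dcp_mean,dcp_spread Mean and SD of the target degree of circular
#'   polarization, truncated per pixel to the interval compatible with the
#'   sampled `I_CP`, `R` and SHG-CD (Stokes feasibility `|s3| <= s0`).
#' @param cd_spread,ld_spread Amplitude (SD) of the zero-mean SHG-CD and
#'   SHG-LD spatial fields; values are clipped to `[-1.9, 1.9]`.
#' @param disorder_scale Spatial correlation length (pixels) of the SHG-CD/LD
#'   fields. Short lengths emulate disordered fiber orientation (tumor-like
#'   texture); long lengths emulate organized collagen.
#'
#' @return A named list of class `"phantom_region"`.
#' @export
phantom_region <- function(fiber_density = 0.65,
                           icp_mean = 800, icp_spread = 0.3,
                           r_mean = 3.7, r_spread = 0.4,
                           dcp_mean = 0.3, dcp_spread = 0.08,
                           cd_spread = 0.55, ld_spread = 0.55,
                           disorder_scale = 14) {
  stopifnot(fiber_density >= 0, fiber_density <= 1,
            icp_mean > 0, icp_spread >= 0, r_spread >= 0,
            dcp_spread >= 0, cd_spread >= 0, ld_spread >= 0,
            disorder_scale >= 0)
  if (dcp_mean < 0 || dcp_mean > 1)
    stop("dcp_mean must lie in [0, 1]; got ", dcp_mean)
  if (cd_spread > 2 || ld_spread > 2)
    stop("cd_spread/ld_spread above 2 force dichroisms outside [-2, 2]")
  structure(as.list(environment()), class = "phantom_region")
}

#' Configuration of the synthetic P-SHG phantom
#'
#' The phantom is a mosaic of widefield fields of view with a tumor-like
#' region on the left and a normal-like region on the right, separated at
#' `boundary_col`. The two regions differ in SHG intensity, fiber (bright
#' pixel) density, R-ratio distribution and orientation disorder, which
#' drives SHG-CD/LD texture heterogeneity. Defaults place the boundary at
#' the midline of a single 1024x1024 field tiled into 128x128 sub-images.
#'
#' @param field_height,field_width Size of one field of view, pixels.
#' @param mosaic_rows,mosaic_cols Number of fields in the tiled mosaic; the
#'   full image is `mosaic_rows * field_height` by
#'   `mosaic_cols * field_width`.
#' @param tile_size Sub-image size in pixels; must divide both full
#'   dimensions.
#' @param boundary_col Pixel column of the tumor/normal divide (tumor spans
#'   columns `1..boundary_col`).
#' @param tumor,normal [phantom_region()] parameter sets.
#' @param gain Shot-noise gain: raw intensities receive noise of variance
#'   `mean / gain`, so the per-pixel SNR is approximately
#'   `sqrt(gain * mean)`.
#' @param noise `"shot"` or `"none"` (exact, noiseless stack).
#' @param background_level Mean count level of non-fiber (background) pixels.
#' @param n_frames Number of repeated frames to synthesize.
#' @param exclusions Optional list of ellipses, each
#'   `list(cx=, cy=, rx=, ry=)` in pixels, marked excluded (adipose/vessel
#'   stand-ins) and exercising the tile-rejection path.
#' @param seed Integer seed; the generator and the stack synthesis are fully
#'   deterministic given the seed.
#'
#' @return A list of class `"phantom_config"` with derived fields `height`
#'   and `width` (full mosaic size).
#' @export
phantom_config <- function(field_height = 1024, field_width = 1024,
                           mosaic_rows = 1, mosaic_cols = 1,
                           tile_size = 128,
                           boundary_col = NULL,
                           tumor = phantom_region(fiber_density = 0.35,
                                                  icp_mean = 300,
                                                  icp_spread = 0.35,
                                                  r_mean = 4.4, r_spread = 0.5,
                                                  dcp_mean = 0.35,
                                                  dcp_spread = 0.1,
                                                  disorder_scale = 3),
                           normal = phantom_region(),
                           gain = 0.05, noise = c("shot", "none"),
                           background_level = 2,
                           n_frames = 1,
                           exclusions = list(),
                           seed = 1L) {
  noise <- match.arg(noise)
  height <- mosaic_rows * field_height
  width <- mosaic_cols * field_width
  if (height %% tile_size != 0 || width %% tile_size != 0)
    stop("tile_size (", tile_size, ") must divide the mosaic dimensions ",
         height, "x", width)
  if (is.null(boundary_col)) boundary_col <- width %/% 2
  stopifnot(boundary_col >= 1, boundary_col < width,
            gain > 0, background_level >= 0, n_frames >= 1)
  cfg <- list(field_height = field_height, field_width = field_width,
              mosaic_rows = mosaic_rows, mosaic_cols = mosaic_cols,
              height = height, width = width,
              tile_size = tile_size, boundary_col = boundary_col,
              tumor = tumor, normal = normal,
              gain = gain, noise = noise,
              background_level = background_level,
              n_frames = as.integer(n_frames),
              exclusions = exclusions, seed = as.integer(seed))
  structure(cfg, class = "phantom_config")
}

# Pixel mask of the configured exclusion ellipses.
exclusion_mask <- function(config) {
  m <- matrix(FALSE, config$height, config$width)
  for (e in config$exclusions) {
    rows <- seq_len(config$height)
    cols <- seq_len(config$width)
    dy <- (rows - e$cy) / e$ry
    dx <- (cols - e$cx) / e$rx
    m <- m | (outer(dy^2, dx^2, `+`) <= 1)
  }
  m
}

#' Generate the phantom ground truth
#'
#' Samples per-pixel target polarimetric parameters (`I_CP`, R-ratio, DCP,
#' SHG-CD, SHG-LD) for the fiber pixels of each region, together with the
#' region/exclusion labels and fiber mask. The targets are jointly feasible
#' under the Stokes inversion used by [synthesize_stack()]:
#' * R is truncated to `R >= 3`, the branch on which the R-ratio formula
#'   recomputed from Stokes elements returns the target exactly;
#' * DCP is drawn from a truncated normal on the exact per-pixel interval
#'   compatible with `|s3| <= s0` given the sampled `I_CP`, R and SHG-CD;
#' * SHG-CD/LD are smoothed Gaussian fields (correlation length
#'   `disorder_scale`) clipped to `[-1.9, 1.9]`; the number of clipped pixels
#'   is recorded in the `n_clipped` field.
#'
#' @param config A [phantom_config()].
#' @return A list of class `"phantom_truth"`: `region` (integer matrix,
#'   1 = tumor, 2 = normal, 0 = excluded), `fiber` (logical matrix),
#'   matrices `icp`, `rratio`, `dcp`, `shgcd`, `shgld` (`NA` off-fiber),
#'   `exclusion` (logical), `boundary_col`, `n_clipped`, and the `config`.
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  h <- config$height; w <- config$width
  region <- matrix(2L, h, w)
  region[, seq_len(config$boundary_col)] <- 1L
  excl <- exclusion_mask(config)
  region[excl] <- 0L

  fiber <- matrix(FALSE, h, w)
  icp <- rr <- dcp <- cd <- ld <- matrix(NA_real_, h, w)
  n_clipped <- 0L

  for (lab in c(1L, 2L)) {
    rp <- if (lab == 1L) config$tumor else config$normal
    in_region <- region == lab
    n_px <- sum(in_region)
    if (n_px == 0) next
    fib <- in_region & (matrix(stats::runif(h * w), h, w) < rp$fiber_density)
    fiber <- fiber | fib

    # Orientation-disorder driven dichroism fields: smoothed over the whole
    # mosaic at this region's correlation length, then masked to the region.
    zcd <- smooth_field(h, w, rp$disorder_scale)
    zld <- smooth_field(h, w, rp$disorder_scale)
    cd_r <- rp$cd_spread * zcd[fib]
    ld_r <- rp$ld_spread * zld[fib]
    n_clipped <- n_clipped + sum(abs(cd_r) > 1.9) + sum(abs(ld_r) > 1.9)
    cd[fib] <- pmin(pmax(cd_r, -1.9), 1.9)
    ld[fib] <- pmin(pmax(ld_r, -1.9), 1.9)

    n_f <- sum(fib)
    icp[fib] <- stats::qlnorm(stats::runif(n_f),
                              meanlog = log(rp$icp_mean) - rp$icp_spread^2 / 2,
                              sdlog = rp$icp_spread)
    rr[fib] <- rtruncnorm_inv(n_f, rp$r_mean, rp$r_spread, 3.05, 25)

    # Feasible DCP interval given I_CP, R and SHG-CD (see synthesize_stack):
    # s3^RCP = u >= 0, s3^LCP = -v <= 0, u + v = 2*I/A, u <= s0^RCP,
    # v <= s0^LCP, with A = ((R-1)^2 + 4) / (4 (R - 1)) >= 1.
    i_f <- icp[fib]; r_f <- rr[fib]; cd_f <- cd[fib]
    a0 <- i_f * (1 + cd_f / 2)   # s0^RCP
    b0 <- i_f * (1 - cd_f / 2)   # s0^LCP
    A <- ((r_f - 1)^2 + 4) / (4 * (r_f - 1))
    D <- 2 * i_f / A
    u_min <- pmax(0, D - b0)
    u_max <- pmin(a0, D)
    d1 <- (u_min / a0 + (D - u_min) / b0) / 2
    d2 <- (u_max / a0 + (D - u_max) / b0) / 2
    lo <- pmin(d1, d2); hi <- pmax(d1, d2)
    dcp[fib] <- rtruncnorm_inv(n_f, rp$dcp_mean, rp$dcp_spread, lo, hi)
  }

  structure(list(region = region, fiber = fiber, exclusion = excl,
                 icp = icp, rratio = rr, dcp = dcp, shgcd = cd, shgld = ld,
                 boundary_col = config$boundary_col,
                 n_clipped = n_clipped, config = config),
            class = "phantom_truth")
}

# Per-incoming-state Stokes targets implied by the truth maps.
# Returns list over incoming states of list(s0, s1, s3) matrices (background
# pixels get s0 = background_level, s1 = s3 = 0).
truth_stokes <- function(truth, config) {
  h <- config$height; w <- config$width
  fib <- truth$fiber
  icp <- truth$icp; rr <- truth$rratio
  dcp <- truth$dcp; cd <- truth$shgcd; ld <- truth$shgld

  bg <- config$background_level
  s0 <- lapply(PSHG_STATES, function(s) matrix(bg, h, w))
  names(s0) <- PSHG_STATES
  s3 <- lapply(PSHG_STATES, function(s) matrix(0, h, w))
  names(s3) <- PSHG_STATES
  s1 <- lapply(PSHG_STATES, function(s) matrix(0, h, w))
  names(s1) <- PSHG_STATES

  a0 <- icp * (1 + cd / 2)  # s0^RCP
  b0 <- icp * (1 - cd / 2)  # s0^LCP
  A <- ((rr - 1)^2 + 4) / (4 * (rr - 1))
  D <- 2 * icp / A
  # Solve u/a0 + v/b0 = 2*DCP, u + v = D for u = s3^RCP, v = -s3^LCP.
  slope <- 1 / a0 - 1 / b0
  u <- ifelse(abs(slope) < 1e-12, D / 2, (2 * dcp - D / b0) / slope)
  u <- pmin(pmax(u, pmax(0, D - b0)), pmin(a0, D))
  v <- D - u
  bad <- fib & (u > a0 + 1e-9 | v > b0 + 1e-9)
  if (any(bad)) {
    i <- which(bad)[1]
    stop("Stokes inversion infeasible (|s3| > s0) at pixel ", i,
         ": I_CP=", icp[i], " R=", rr[i], " DCP=", dcp[i], " SHG-CD=", cd[i])
  }

  s0$RCP[fib] <- a0[fib]; s0$LCP[fib] <- b0[fib]
  s3$RCP[fib] <- u[fib];  s3$LCP[fib] <- -v[fib]
  s0$VLP[fib] <- (icp * (1 + ld / 2))[fib]
  s0$HLP[fib] <- (icp * (1 - ld / 2))[fib]
  list(s0 = s0, s1 = s1, s3 = s3)
}

#' Synthesize the 16-state polarization stack from phantom truth
#'
#' Inverts the polarimetric parameter definitions into per-incoming-state
#' Stokes elements (`s0^RCP = I_CP (1 + SHG_CD/2)`, `s0^LCP = I_CP
#' (1 - SHG_CD/2)`, `s3^RCP - s3^LCP = 2 I_CP / A` with
#' `A = ((R-1)^2 + 4) / (4 (R-1))`, DCP fixing the split with the convention
#' `s3^RCP >= 0 >= s3^LCP`, `s0^VLP/HLP = I_CP (1 +/- SHG_LD/2)`, all
#' `s1 = 0`) and maps them to the 16 analyzed intensities
#' `I = (s0 +/- s1)/2` and `(s0 +/- s3)/2`. Shot-like noise of variance
#' `mean / gain` is applied per frame; background pixels receive noise-only
#' values around `background_level`. All intensities are clamped
#' non-negative.
#'
#' @param truth A [generate_phantom()] result.
#' @param config The matching [phantom_config()]; `config$noise = "none"`
#'   gives an exact, noiseless stack.
#' @param n_frames Number of frames; defaults to `config$n_frames`.
#' @return A `"polarization_stack"`: 5-D array
#'   `[height, width, incoming, analyzed, frame]` with state dimnames in the
#'   order LCP, RCP, VLP, HLP.
#' @export
synthesize_stack <- function(truth, config = truth$config,
                             n_frames = config$n_frames) {
  stopifnot(inherits(truth, "phantom_truth"))
  set.seed(config$seed + 1L)
  st <- truth_stokes(truth, config)
  h <- config$height; w <- config$width
  arr <- array(0, dim = c(h, w, 4, 4, n_frames),
               dimnames = list(NULL, NULL, incoming = PSHG_STATES,
                               analyzed = PSHG_STATES, NULL))
  for (inc in PSHG_STATES) {
    mean_img <- list(
      LCP = (st$s0[[inc]] - st$s3[[inc]]) / 2,
      RCP = (st$s0[[inc]] + st$s3[[inc]]) / 2,
      VLP = (st$s0[[inc]] - st$s1[[inc]]) / 2,
      HLP = (st$s0[[inc]] + st$s1[[inc]]) / 2)
    for (ana in PSHG_STATES) {
      m <- mean_img[[ana]]
      for (f in seq_len(n_frames)) {
        if (config$noise == "shot") {
          img <- m + sqrt(pmax(m, 0) / config$gain) *
            matrix(stats::rnorm(h * w), h, w)
          arr[, , inc, ana, f] <- pmax(img, 0)
        } else {
          arr[, , inc, ana, f] <- pmax(m, 0)
        }
      }
    }
  }
  structure(arr, class = "polarization_stack")
}
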