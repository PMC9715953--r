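test_that("Stokes elements follow the analyzed-intensity combination rule", {
  # all four analyzed intensities equal -> pure unpolarized combination
  st <- compute_stokes(tiny_stack(list(), default = 1))
  for (inc in c("LCP", "RCP", "VLP", "HLP")) {
    expect_equal(st$s0[[inc]], matrix(2, 2, 2))
    expect_equal(st$s1[[inc]], matrix(0, 2, 2))
    expect_equal(st$s3[[inc]], matrix(0, 2, 2))
  }
  # directed circular component
  st <- compute_stokes(tiny_stack(list(
    LCP = list(RCP = 2, LCP = 0, HLP = 1, VLP = 1))))
  expect_equal(st$s0$LCP, matrix(2, 2, 2))
  expect_equal(st$s1$LCP, matrix(0, 2, 2))
  expect_equal(st$s3$LCP, matrix(2, 2, 2))
})

test_that("a stack with a missing state is rejected by name", {
  arr <- array(1, dim = c(2, 2, 4, 4, 1),
               dimnames = list(NULL, NULL,
                               incoming = c("LCP", "RCP", "VLP", "XXX"),
                               analyzed = c("LCP", "RCP", "VLP", "HLP"),
                               NULL))
  expect_error(compute_stokes(arr), "HLP")
})

test_that("frame averaging happens before the Stokes combination", {
  arr <- array(0, dim = c(1, 1, 4, 4, 2),
               dimnames = list(NULL, NULL,
                               incoming = c("LCP", "RCP", "VLP", "HLP"),
                               analyzed = c("LCP", "RCP", "VLP", "HLP"),
                               NULL))
  arr[1, 1, "LCP", "HLP", ] <- c(1, 3)  # mean 2
  arr[1, 1, "LCP", "VLP", ] <- c(4, 0)  # mean 2
  st <- compute_stokes(arr)
  expect_equal(st$s0$LCP[1, 1], 4)
  expect_equal(st$s1$LCP[1, 1], 0)
})

test_that("polarimetric parameter formulas match hand substitution", {
  # I_CP
  expect_equal(compute_icp(stokes_from(s0 = list(RCP = 1, LCP = 1)))[1, 1], 1)
  expect_equal(compute_icp(stokes_from(s0 = list(RCP = 3, LCP = 1)))[1, 1], 2)
  # R-ratio: A = 1 -> R = 3 (radicand zero)
  st <- stokes_from(s0 = list(RCP = 1, LCP = 1),
                    s3 = list(RCP = 1, LCP = -1))
  expect_equal(compute_rratio(st)[1, 1], 3)
  # A = -1 -> R = -1
  st <- stokes_from(s0 = list(RCP = 1, LCP = 1),
                    s3 = list(RCP = -1, LCP = 1))
  expect_equal(compute_rratio(st)[1, 1], -1)
  # |A| < 1 -> invalid pixel
  st <- stokes_from(s0 = list(RCP = 0.5, LCP = 0.4),
                    s3 = list(RCP = 1, LCP = -1))
  expect_true(is.na(compute_rratio(st)[1, 1]))
  # DCP
  st <- stokes_from(s0 = list(RCP = 1, LCP = 0.5),
                    s3 = list(RCP = 0.5, LCP = -0.25))
  expect_equal(compute_dcp(st)[1, 1], 0.5)
  st <- stokes_from(s0 = list(RCP = 1, LCP = 1),
                    s3 = list(RCP = 1, LCP = -1))
  expect_equal(compute_dcp(st)[1, 1], 1)
  st <- stokes_from(s0 = list(RCP = 1, LCP = 1))
  expect_equal(compute_dcp(st)[1, 1], 0)
  # dichroisms
  d <- compute_dichroisms(stokes_from(s0 = list(RCP = 3, LCP = 1,
                                                VLP = 2, HLP = 2)))
  expect_equal(d$shgcd[1, 1], 1)
  expect_equal(d$shgld[1, 1], 0)
  d_sw <- compute_dichroisms(stokes_from(s0 = list(RCP = 1, LCP = 3,
                                                   VLP = 2, HLP = 2)))
  expect_equal(d_sw$shgcd[1, 1], -1)
})

test_that("maps agree with independent per-pixel scalar recomputation", {
  cfg <- small_config(seed = 13)
  st <- compute_stokes(synthesize_stack(generate_phantom(cfg), cfg))
  maps <- polarimetric_maps(st)
  set.seed(42)
  idx <- sample(length(maps$icp), 50)
  for (i in idx) {
    s0r <- st$s0$RCP[i]; s0l <- st$s0$LCP[i]
    s0v <- st$s0$VLP[i]; s0h <- st$s0$HLP[i]
    s3r <- st$s3$RCP[i]; s3l <- st$s3$LCP[i]
    expect_identical(maps$icp[i], (s0r + s0l) / 2)
    A <- (s0r + s0l) / (s3r - s3l)
    r_ref <- if (!is.finite(A) || abs(A) < 1 || abs(A) > 1e6) NA_real_
             else 1 + 2 * A + 2 * sqrt(A^2 - 1)
    expect_equal(maps$rratio[i], r_ref)
    dcp_ref <- if (s0r > 0 && s0l > 0)
      (abs(s3r) / s0r + abs(s3l) / s0l) / 2 else NA_real_
    if (!is.na(dcp_ref) && dcp_ref > 1.05) dcp_ref <- NA_real_
    expect_equal(maps$dcp[i], min(dcp_ref, 1))
    cd_ref <- if (s0r > 0 && s0l > 0) 2 * (s0r - s0l) / (s0r + s0l)
              else NA_real_
    expect_equal(maps$shgcd[i], cd_ref)
  }
})

test_that("shot-noise frames calibrate to a square-root SNR law", {
  set.seed(101)
  mu <- matrix(runif(40 * 40, 20, 2000), 40, 40)
  frames <- array(0, dim = c(40, 40, 4, 4, 12),
                  dimnames = list(NULL, NULL, incoming = PSHG <- c("LCP",
                    "RCP", "VLP", "HLP"), analyzed = PSHG, NULL))
  for (i in 1:4) for (j in 1:4) for (f in 1:12)
    frames[, , i, j, f] <- mu + sqrt(mu) * matrix(rnorm(1600), 40, 40)
  cal <- fit_snr_calibration(frames)
  expect_equal(cal$b, 0.5, tolerance = 0.05)
  expect_equal(cal$a, 1, tolerance = 0.1)
  # quadrupling the signal (with shot noise at the new level) doubles the
  # predicted SNR at the matched intensity quantile
  frames4 <- frames
  for (i in 1:4) for (j in 1:4) for (f in 1:12)
    frames4[, , i, j, f] <- 4 * mu + sqrt(4 * mu) *
      matrix(rnorm(1600), 40, 40)
  cal4 <- fit_snr_calibration(frames4)
  q <- stats::median(mu)
  expect_equal(predict_snr(cal4, 4 * q) / predict_snr(cal, q), 2,
               tolerance = 0.05)
})

test_that("constant pixels are excluded from the SNR fit; all-constant errors", {
  set.seed(7)
  mu <- matrix(runif(100, 50, 500), 10, 10)
  frames <- array(0, dim = c(10, 10, 4, 4, 6),
                  dimnames = list(NULL, NULL, incoming = S <- c("LCP",
                    "RCP", "VLP", "HLP"), analyzed = S, NULL))
  for (i in 1:4) for (j in 1:4) for (f in 1:6)
    frames[, , i, j, f] <- mu + sqrt(mu) * matrix(rnorm(100), 10, 10)
  frames[1, 1, , , ] <- 100  # sigma = 0 at one pixel
  cal <- fit_snr_calibration(frames)
  expect_s3_class(cal, "snr_calibration")
  expect_error(fit_snr_calibration(frames * 0 + 5), "constant")
  expect_error(fit_snr_calibration(frames[, , , , 1:2, drop = FALSE]),
               "frames")
})

test_that("SNR mask thresholds inclusively and never gains pixels when raised", {
  cal <- structure(list(a = 1, b = 0.5, n_pixels = 100, sigma_resid = 0,
                        mu_range = c(0.5, 100)),
                   class = "snr_calibration")
  m <- matrix(c(0, 0.25, 1, 4, 25, 100), 2, 3)
  mask <- snr_mask(m, cal, min_snr = 1)
  expect_identical(as.vector(mask),
                   c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))  # SNR(1) = 1 kept
  expect_false(any(snr_mask(matrix(0, 4, 4), cal)))
  m2 <- matrix(runif(100, 0, 80), 10, 10)
  lo <- snr_mask(m2, cal, min_snr = 1)
  hi <- snr_mask(m2, cal, min_snr = 3)
  expect_true(all(lo[hi]))  # raising the threshold only removes pixels
})

test_that("fitted mask agrees with empirical mu/sigma thresholding away from the boundary", {
  cfg <- small_config(seed = 21, n_frames = 8)
  truth <- generate_phantom(cfg)
  stack <- synthesize_stack(truth, cfg)
  cal <- fit_snr_calibration(stack)
  # brute-force per-pixel mu/sigma of one raw image over its repeats
  raw <- stack[, , "RCP", "RCP", ]
  mu <- apply(raw, c(1, 2), mean)
  sg <- apply(raw, c(1, 2), sd)
  emp_snr <- ifelse(sg > 0, mu / sg, Inf)
  mask <- suppressWarnings(snr_mask(mu, cal, min_snr = 1))
  clear <- emp_snr < 0.5 | emp_snr > 2  # pixels far from the threshold
  expect_gt(mean(mask[clear] == (emp_snr[clear] >= 1)), 0.99)
})
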