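# Shared fixtures: small phantoms and hand-built Stokes objects.

# Small, fast phantom: 256x256 field, 32-pixel tiles, midline boundary.
small_config <- function(seed = 1L, noise = "shot", ...) {
  phantom_config(field_height = 256, field_width = 256, tile_size = 32,
                 tumor = phantom_region(fiber_density = 0.35,
                                        icp_mean = 300, icp_spread = 0.35,
                                        r_mean = 4.4, r_spread = 0.5,
                                        dcp_mean = 0.35, dcp_spread = 0.1,
                                        disorder_scale = 2),
                 normal = phantom_region(disorder_scale = 8),
                 noise = noise, seed = seed, ...)
}

# Build a "stokes_maps" object from scalar (or matrix) element values.
stokes_from <- function(s0 = list(), s1 = list(), s3 = list()) {
  as_mat <- function(v) if (is.matrix(v)) v else matrix(v, 1, 1)
  fill <- function(lst, default = 0) {
    out <- lapply(c(LCP = "LCP", RCP = "RCP", VLP = "VLP", HLP = "HLP"),
                  function(s) as_mat(if (!is.null(lst[[s]])) lst[[s]]
                                     else default))
    out
  }
  structure(list(s0 = fill(s0), s1 = fill(s1), s3 = fill(s3),
                 height = 1, width = 1),
            class = "stokes_maps")
}

# Tiny stack with given analyzed intensities for one incoming state and
# flat value elsewhere.
tiny_stack <- function(values_by_state, h = 2, w = 2, default = 1) {
  arr <- array(default, dim = c(h, w, 4, 4, 1),
               dimnames = list(NULL, NULL,
                               incoming = c("LCP", "RCP", "VLP", "HLP"),
                               analyzed = c("LCP", "RCP", "VLP", "HLP"),
                               NULL))
  for (inc in names(values_by_state))
    for (ana in names(values_by_state[[inc]]))
      arr[, , inc, ana, 1] <- values_by_state[[inc]][[ana]]
  structure(arr, class = "polarization_stack")
}

# Brute-force GLCM by explicit pixel loops (independent oracle).
glcm_oracle <- function(grey, n_levels, d = 1, angles = c(0, 45, 90, 135)) {
  offs <- list(`0` = c(0, d), `45` = c(-d, d), `90` = c(-d, 0),
               `135` = c(-d, -d))
  counts <- matrix(0, n_levels, n_levels)
  nr <- nrow(grey); nc <- ncol(grey)
  for (ang in as.character(angles)) {
    dr <- offs[[ang]][1]; dc <- offs[[ang]][2]
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      i2 <- i + dr; j2 <- j + dc
      if (i2 < 1 || i2 > nr || j2 < 1 || j2 > nc) next
      a <- grey[i, j]; b <- grey[i2, j2]
      if (is.na(a) || is.na(b)) next
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
  }
  counts
}

# Brute-force Haralick features by explicit double loops over (i, j).
haralick_oracle <- function(P) {
  n <- nrow(P)
  lev <- seq_len(n) - 1
  marg <- rowSums(P)
  mu <- sum(lev * marg)
  sig2 <- sum((lev - mu)^2 * marg)
  contrast <- 0; corr <- 0; ent <- 0; asm <- 0; idm <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    p <- P[i, j]
    contrast <- contrast + (lev[i] - lev[j])^2 * p
    corr <- corr + p * (lev[i] - mu) * (lev[j] - mu)
    if (p > 0) ent <- ent - p * log2(p)
    asm <- asm + p^2
    idm <- idm + p / (1 + (lev[i] - lev[j])^2)
  }
  list(contrast = contrast,
       correlation = if (sig2 > 0) corr / sig2 else NA_real_,
       entropy = ent, asm = asm, idm = idm)
}

# Brute-force silhouette via explicit a(i)/b(i) computation.
silhouette_oracle <- function(x, labels) {
  n <- nrow(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    d_own <- c(); d_other <- c()
    for (j in seq_len(n)) {
      if (j == i) next
      dij <- sqrt(sum((x[i, ] - x[j, ])^2))
      if (labels[j] == labels[i]) d_own <- c(d_own, dij)
      else d_other <- c(d_other, dij)
    }
    if (length(d_own) == 0) { s[i] <- 0; next }
    a <- mean(d_own); b <- mean(d_other)
    s[i] <- (b - a) / max(a, b)
  }
  s
}
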