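#' Tile an image into a grid of square sub-images
#'
#' Subdivides a `height` x `width` mosaic into disjoint `tile_size` x
#' `tile_size` sub-images (a 2048 x 2048 field with 128-pixel tiles yields
#' 256 sub-images). Partial tiles are not allowed.
#'
#' @param height,width Image dimensions in pixels.
#' @param tile_size Sub-image edge length in pixels; must divide both
#'   dimensions.
#' @return A tibble of class `"subimage_grid"` with one row per tile:
#'   `tile_row`, `tile_col` (grid indices) and pixel bounds `row0`, `row1`,
#'   `col0`, `col1`. Attributes `n_rows`, `n_cols`, `tile_size`.
#' @export
tile_grid <- function(height, width, tile_size) {
  if (height %% tile_size != 0 || width %% tile_size != 0)
    stop("tile_size (", tile_size, ") must divide image dimensions ",
         height, "x", width, "; partial tiles are not supported")
  n_rows <- height %/% tile_size
  n_cols <- width %/% tile_size
  g <- tidyr::expand_grid(tile_row = seq_len(n_rows),
                          tile_col = seq_len(n_cols))
  g <- dplyr::mutate(g,
                     row0 = (.data$tile_row - 1L) * tile_size + 1L,
                     row1 = .data$tile_row * tile_size,
                     col0 = (.data$tile_col - 1L) * tile_size + 1L,
                     col1 = .data$tile_col * tile_size)
  structure(g, n_rows = n_rows, n_cols = n_cols, tile_size = tile_size,
            class = c("subimage_grid", class(g)))
}

#' Quantize a tile of continuous values into grey levels
#'
#' Valid pixels are binned into `n_levels` equal-width bins over `range`
#' (values outside the range are clipped to the end bins); invalid pixels
#' become `NA`, the background code, and never occupy a grey level. A
#' degenerate range (`max == min`) puts all valid pixels in level 1.
#'
#' @param values Numeric matrix of parameter values.
#' @param valid Logical matrix; `FALSE`/`NA` pixels are background.
#' @param n_levels Number of grey levels `N_g` (>= 2).
#' @param range Length-2 numeric; finite quantization bounds.
#' @return Integer matrix with levels in `1..n_levels`, `NA` background.
#' @export
quantize <- function(values, valid, n_levels = 64, range = NULL) {
  if (is.null(range)) range <- base::range(values[valid], na.rm = TRUE)
  stopifnot(n_levels >= 2, all(is.finite(range)))
  lo <- range[1]; hi <- range[2]
  g <- matrix(NA_integer_, nrow(values), ncol(values))
  ok <- valid & is.finite(values)
  if (hi > lo) {
    lev <- floor((values[ok] - lo) / (hi - lo) * n_levels) + 1L
    g[ok] <- pmin(pmax(lev, 1L), as.integer(n_levels))
  } else {
    g[ok] <- 1L
  }
  g
}

# Symmetric pair counts for one displacement (dr, dc); pairs touching a
# background (NA) pixel are skipped.
glcm_counts_offset <- function(grey, dr, dc, n_levels) {
  nr <- nrow(grey); nc <- ncol(grey)
  r0 <- max(1, 1 - dr); r1 <- min(nr, nr - dr)
  c0 <- max(1, 1 - dc); c1 <- min(nc, nc - dc)
  if (r0 > r1 || c0 > c1) return(matrix(0L, n_levels, n_levels))
  a <- grey[r0:r1, c0:c1, drop = FALSE]
  b <- grey[(r0 + dr):(r1 + dr), (c0 + dc):(c1 + dc), drop = FALSE]
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) return(matrix(0L, n_levels, n_levels))
  counts <- matrix(tabulate((a[keep] - 1L) * n_levels + b[keep],
                            nbins = n_levels * n_levels),
                   n_levels, n_levels, byrow = TRUE)
  counts + t(counts)  # count both orders: symmetric GLCM
}

#' Grey-level co-occurrence matrix of a quantized tile
#'
#' Builds one symmetric GLCM per angle at displacement `d` (0 deg =
#' horizontal, 90 deg = vertical, 45/135 deg the diagonals), counting each
#' pair in both orders and skipping any pair with a background (`NA`)
#' member. The per-angle matrices are averaged and normalized into a
#' direction-independent probability matrix.
#'
#' @param grey Integer matrix from [quantize()] (`NA` = background).
#' @param n_levels Number of grey levels.
#' @param d Displacement in pixels; default 1 (nearest neighbour).
#' @param angles Subset of `c(0, 45, 90, 135)` degrees.
#' @return A `"glcm"` object: normalized probability matrix `P` (`NULL` when
#'   no valid pair exists), `counts` (summed over angles), `n_levels`,
#'   `n_pairs` and the `empty` flag.
#' @export
compute_glcm <- function(grey, n_levels = max(grey, na.rm = TRUE),
                         d = 1, angles = c(0, 45, 90, 135)) {
  offsets <- list(`0` = c(0, d), `45` = c(-d, d),
                  `90` = c(-d, 0), `135` = c(-d, -d))
  bad <- setdiff(as.character(angles), names(offsets))
  if (length(bad)) stop("unsupported GLCM angle(s): ",
                        paste(bad, collapse = ", "))
  counts <- matrix(0, n_levels, n_levels)
  for (ang in as.character(angles)) {
    off <- offsets[[ang]]
    counts <- counts + glcm_counts_offset(grey, off[1], off[2], n_levels)
  }
  n_pairs <- sum(counts)
  P <- if (n_pairs > 0) counts / n_pairs else NULL
  structure(list(P = P, counts = counts, n_levels = n_levels,
                 n_pairs = n_pairs, empty = n_pairs == 0),
            class = "glcm")
}

#' Haralick texture features of a GLCM
#'
#' Computes, from the normalized symmetric GLCM `P(i, j)`:
#' * contrast `sum (i - j)^2 P(i, j)`;
#' * correlation `sum P(i, j) (i - mu)(j - mu) / sigma^2`, with `mu`,
#'   `sigma` the grey-level marginal mean and SD; the sign convention gives
#'   +1 for a perfectly positively correlated image and -1 for a perfectly
#'   negatively correlated one. Undefined (`NA`) for a constant tile
#'   (`sigma = 0`);
#' * entropy `-sum P log2 P` over non-zero entries;
#' * angular second moment `ASM = sum P^2` (1 for a uniform image);
#' * inverse difference moment `IDM = sum P / (1 + (i - j)^2)` (1 for a
#'   uniform image).
#'
#' @param glcm A [compute_glcm()] result.
#' @return One-row tibble with columns `contrast`, `correlation`, `entropy`,
#'   `asm`, `idm`; all `NA` for an empty GLCM.
#' @export
haralick_features <- function(glcm) {
  stopifnot(inherits(glcm, "glcm"))
  if (glcm$empty)
    return(tibble::tibble(contrast = NA_real_, correlation = NA_real_,
                          entropy = NA_real_, asm = NA_real_,
                          idm = NA_real_))
  P <- glcm$P
  n <- glcm$n_levels
  lev <- seq_len(n) - 1  # grey levels 0..N_g-1
  I <- matrix(lev, n, n)
  J <- t(I)
  p_marg <- rowSums(P)  # symmetric GLCM: row and column marginals agree
  mu <- sum(lev * p_marg)
  sig2 <- sum((lev - mu)^2 * p_marg)
  contrast <- sum((I - J)^2 * P)
  correlation <- if (sig2 > 0) sum(P * (I - mu) * (J - mu)) / sig2
                 else NA_real_
  nz <- P > 0
  entropy <- -sum(P[nz] * log2(P[nz]))
  tibble::tibble(contrast = contrast, correlation = correlation,
                 entropy = entropy, asm = sum(P^2),
                 idm = sum(P / (1 + (I - J)^2)))
}

#' Per-tile summary statistics
#'
#' Mean and mean absolute deviation (about the mean) of the valid, finite
#' pixels of a tile, plus the pixel density (fraction of valid pixels).
#'
#' @param values Numeric matrix (one tile of a parameter map).
#' @param valid Logical matrix of the same shape.
#' @return One-row tibble `mean`, `mad`, `pixel_density`; `mean`/`mad` are
#'   `NA` when no valid finite pixel exists.
#' @export
tile_summary <- function(values, valid) {
  dens <- mean(valid, na.rm = TRUE)
  v <- values[valid & is.finite(values)]
  if (length(v) == 0)
    return(tibble::tibble(mean = NA_real_, mad = NA_real_,
                          pixel_density = dens))
  m <- mean(v)
  tibble::tibble(mean = m, mad = mean(abs(v - m)), pixel_density = dens)
}

#' Assemble the 36-column per-sub-image feature table
#'
#' Tiles the five polarimetric parameter maps, drops sub-images that overlap
#' the exclusion mask (majority of pixels excluded) or whose pixel density
#' falls below `min_density` (insufficient SHG signal), and computes for each
#' retained tile the pixel density plus, per parameter, the mean, MAD and
#' the five GLCM Haralick features. Texture uses `n_levels` grey levels over
#' a per-parameter global range taken from robust quantiles of all valid
#' pixels of the mosaic, so texture is comparable across tiles; the
#' SNR-valid mask (plus per-map `NA`s) defines the background excluded from
#' pair counting.
#'
#' @param maps A [polarimetric_maps()] result.
#' @param tile_size Sub-image edge length (pixels); default 128.
#' @param exclusion Optional logical matrix marking excluded
#'   (adipose/vessel) pixels.
#' @param min_density Minimum pixel density for a tile to be retained;
#'   default 0.1.
#' @param n_levels Number of GLCM grey levels `N_g`; default 64.
#' @param range_probs Quantile probabilities defining each parameter's
#'   global quantization range; default `c(0.01, 0.99)`.
#' @return A tibble (`"feature_table"`) with `tile_row`, `tile_col` and the
#'   36 feature columns of [feature_column_names()]. Attributes: `grid`
#'   (the full [tile_grid()] with per-tile `excluded` and `low_density`
#'   flags), `ranges`, `n_levels`, `tile_size`, `n_rows`, `n_cols`.
#' @export
build_feature_table <- function(maps, tile_size = 128, exclusion = NULL,
                                min_density = 0.1, n_levels = 64,
                                range_probs = c(0.01, 0.99)) {
  stopifnot(inherits(maps, "polar_maps"))
  h <- nrow(maps$valid); w <- ncol(maps$valid)
  if (!is.null(exclusion) &&
      (nrow(exclusion) != h || ncol(exclusion) != w))
    stop("exclusion mask geometry (", nrow(exclusion), "x", ncol(exclusion),
         ") does not match the maps (", h, "x", w, ")")
  grid <- tile_grid(h, w, tile_size)

  ranges <- lapply(PSHG_PARAMS, function(p) {
    v <- maps[[p]][maps$valid & is.finite(maps[[p]])]
    if (length(v) == 0) return(c(0, 1))
    r <- stats::quantile(v, range_probs, names = FALSE)
    if (r[2] <= r[1]) r <- range(v)
    if (r[2] <= r[1]) r <- c(r[1], r[1] + 1)
    r
  })
  names(ranges) <- PSHG_PARAMS

  rows <- vector("list", nrow(grid))
  excluded <- low_density <- logical(nrow(grid))
  for (k in seq_len(nrow(grid))) {
    g <- grid[k, ]
    ri <- g$row0:g$row1; ci <- g$col0:g$col1
    if (!is.null(exclusion) && mean(exclusion[ri, ci]) > 0.5) {
      excluded[k] <- TRUE
      next
    }
    valid_t <- maps$valid[ri, ci]
    dens <- mean(valid_t)
    if (dens < min_density) {
      low_density[k] <- TRUE
      next
    }
    feats <- list(tibble::tibble(tile_row = g$tile_row,
                                 tile_col = g$tile_col,
                                 pixel_density = dens))
    for (p in PSHG_PARAMS) {
      vals <- maps[[p]][ri, ci]
      ok <- valid_t & is.finite(vals)
      s <- tile_summary(vals, ok)
      grey <- quantize(vals, ok, n_levels, ranges[[p]])
      tx <- haralick_features(compute_glcm(grey, n_levels))
      f <- dplyr::bind_cols(s[, c("mean", "mad")], tx)
      names(f) <- paste(p, names(f), sep = "_")
      feats <- c(feats, list(f))
    }
    rows[[k]] <- dplyr::bind_cols(feats)
  }
  out <- dplyr::bind_rows(rows)
  grid$excluded <- excluded
  grid$low_density <- low_density
  structure(out, grid = grid, ranges = ranges, n_levels = n_levels,
            tile_size = tile_size,
            n_rows = attr(grid, "n_rows"), n_cols = attr(grid, "n_cols"),
            class = c("feature_table", class(out)))
}
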