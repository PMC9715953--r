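#' Build a pixel-level region label matrix from a boundary column
#'
#' @param height,width Image dimensions in pixels.
#' @param boundary_col Pixel column of the tumor/normal divide; columns
#'   `1..boundary_col` are tumor.
#' @return Integer matrix, 1 = tumor (left), 2 = normal (right).
#' @export
region_from_boundary <- function(height, width, boundary_col) {
  stopifnot(boundary_col >= 1, boundary_col < width)
  r <- matrix(2L, height, width)
  r[, seq_len(boundary_col)] <- 1L
  r
}

#' Rasterize a pixel-level ground truth onto the sub-image grid
#'
#' Each tile receives the majority pixel label within its bounds (tumor,
#' normal or excluded); an exact tie is labelled excluded rather than
#' fabricating a class on the boundary.
#'
#' @param region Integer matrix per pixel: 1 = tumor, 2 = normal,
#'   0 = excluded.
#' @param grid A [tile_grid()] whose geometry matches `region`.
#' @return Tibble `tile_row`, `tile_col`, `region` (factor tumor / normal /
#'   excluded).
#' @export
rasterize_ground_truth <- function(region, grid) {
  stopifnot(inherits(grid, "subimage_grid"))
  ts <- attr(grid, "tile_size")
  if (nrow(region) != attr(grid, "n_rows") * ts ||
      ncol(region) != attr(grid, "n_cols") * ts)
    stop("ground-truth raster geometry does not match the sub-image grid")
  lab <- character(nrow(grid))
  for (k in seq_len(nrow(grid))) {
    g <- grid[k, ]
    px <- region[g$row0:g$row1, g$col0:g$col1]
    counts <- c(excluded = sum(px == 0L), tumor = sum(px == 1L),
                normal = sum(px == 2L))
    top <- counts == max(counts)
    lab[k] <- if (sum(top) > 1) "excluded" else names(counts)[top]
  }
  tibble::tibble(tile_row = grid$tile_row, tile_col = grid$tile_col,
                 region = factor(lab,
                                 levels = c("tumor", "normal", "excluded")))
}

#' Silhouette-weighted cluster occupancies of a region
#'
#' For region `r` and cluster `a`, the occupancy is
#' `Q_{a,r} = sum_{i in a, r} |C_i - 1.5| / sum_{j in r} |C_j - 1.5|`.
#' Effective cluster membership follows the continuous association
#' (`C < 1.5` means cluster 1, `C > 1.5` cluster 2), so sub-images whose
#' negative silhouette pushed them across the boundary count toward the
#' opposite cluster; `C = 1.5` carries zero weight. `Q_{1,r} + Q_{2,r} = 1`
#' whenever the region carries any weight; a region with zero total weight
#' yields `NA` occupancies.
#'
#' @param c_assoc Continuous association values `C` in `[1, 2]`.
#' @param region Factor/character per sub-image, `"tumor"` or `"normal"`
#'   (others ignored).
#' @return Tibble with one row per region: `region`, `q1`, `q2`.
#' @export
cluster_occupancy <- function(c_assoc, region) {
  stopifnot(length(c_assoc) == length(region))
  w <- abs(c_assoc - 1.5)
  eff <- ifelse(c_assoc < 1.5, 1L, 2L)  # C = 1.5 has zero weight anyway
  purrr::map_dfr(c("tumor", "normal"), function(r) {
    in_r <- region == r
    tot <- sum(w[in_r])
    if (!any(in_r) || tot == 0)
      return(tibble::tibble(region = r, q1 = NA_real_, q2 = NA_real_))
    tibble::tibble(region = r,
                   q1 = sum(w[in_r & eff == 1L]) / tot,
                   q2 = sum(w[in_r & eff == 2L]) / tot)
  })
}

#' Inter/intra-cluster occupancy difference (IIOD)
#'
#' `IIOD = |Q_{1,L} - Q_{2,L}| |Q_{1,R} - Q_{2,R}| |Q_{1,L} - Q_{1,R}|
#' |Q_{2,L} - Q_{2,R}|`, in `[0, 1]`. The maximum of 1 is attained when each
#' cluster occupies only one side of the boundary; the minimum of 0 when
#' occupancies are 50/50 or a single cluster covers both sides.
#'
#' @param q1l,q2l Occupancies of clusters 1 and 2 on the left (tumor) side.
#' @param q1r,q2r Occupancies on the right (normal) side.
#' @return The IIOD value; `NA` if any occupancy is `NA`.
#' @export
iiod <- function(q1l, q2l, q1r, q2r) {
  if (any(is.na(c(q1l, q2l, q1r, q2r)))) return(NA_real_)
  abs(q1l - q2l) * abs(q1r - q2r) * abs(q1l - q1r) * abs(q2l - q2r)
}

#' Project a new feature table onto a stored principal component
#'
#' Transfers a reference region's PC loading vector to a new region:
#' standardizes the new table (by default with its own column means/SDs;
#' alternatively with the reference statistics) and forms the linear
#' combination of its 36 features given by the stored loadings. The
#' resulting score column can be fed directly to [kmeans_binary()].
#'
#' @param pca Reference [run_pca()] model.
#' @param model Reference `"standardizer"` (defines the feature columns).
#' @param new_table Feature table of the new region with the same feature
#'   columns.
#' @param pc Component index to transfer; default 2.
#' @param standardize `"local"` (new region's own statistics, default) or
#'   `"reference"` (reuse the stored center/scale).
#' @return Numeric vector of projected scores, one per row of `new_table`.
#' @export
transfer_pc_projection <- function(pca, model, new_table, pc = 2,
                                   standardize = c("local", "reference")) {
  standardize <- match.arg(standardize)
  stopifnot(inherits(pca, "pshg_pca"), inherits(model, "standardizer"))
  if (pc > ncol(pca$loadings)) stop("PCA has no component ", pc)
  missing <- setdiff(model$features, names(new_table))
  if (length(missing))
    stop("new table lacks feature column(s): ",
         paste(missing, collapse = ", "))
  x <- if (standardize == "reference") apply_standardizer(model, new_table)
       else scale(as.matrix(new_table[, model$features]))
  drop(x %*% pca$loadings[, pc])
}

#' Score cluster maps against the ground truth with occupancies and IIOD
#'
#' Joins each subset's continuous cluster map to the rasterized ground
#' truth, computes the four occupancies (clusters 1/2 on the tumor and
#' normal sides) and the IIOD, and flags the best subset (maximal IIOD;
#' ties resolved deterministically to the first listed subset).
#'
#' @param results A list of [cluster_subset()] tibbles (or one tibble
#'   covering several subsets).
#' @param truth A [rasterize_ground_truth()] tibble.
#' @return A tibble (`"margin_report"`): `subset`, `q1_tumor`, `q2_tumor`,
#'   `q1_normal`, `q2_normal`, `iiod`, `best`.
#' @export
build_margin_report <- function(results, truth) {
  if (is.data.frame(results)) results <- list(results)
  rows <- purrr::map(results, function(res) {
    joined <- dplyr::inner_join(res, truth, by = c("tile_row", "tile_col"))
    joined <- dplyr::filter(joined, .data$region != "excluded")
    q <- cluster_occupancy(joined$c_assoc, as.character(joined$region))
    qt <- q[q$region == "tumor", ]; qn <- q[q$region == "normal", ]
    tibble::tibble(subset = res$subset[1],
                   q1_tumor = qt$q1, q2_tumor = qt$q2,
                   q1_normal = qn$q1, q2_normal = qn$q2,
                   iiod = iiod(qt$q1, qt$q2, qn$q1, qn$q2))
  })
  out <- dplyr::bind_rows(rows)
  out$best <- FALSE
  if (any(is.finite(out$iiod)))
    out$best[which.max(out$iiod)] <- TRUE
  class(out) <- c("margin_report", class(out))
  out
}

#' Estimate the boundary column from a vertical profile
#'
#' Finds where the per-column mean of the continuous cluster map crosses
#' the no-association level 1.5, interpolating linearly between adjacent
#' column centers. When several crossings exist the one with the steepest
#' local slope is taken. The returned position is in tile-column units
#' measured from the left edge (a value of `k` means the boundary sits at
#' the right edge of tile column `k`); multiply by the tile size for
#' pixels.
#'
#' @param profile Numeric per-column profile (from [vertical_profile()],
#'   typically of the median-filtered map).
#' @return Boundary position in tile-column units, or `NA` when the
#'   profile never crosses 1.5.
#' @export
estimate_boundary <- function(profile) {
  ok <- which(!is.na(profile))
  if (length(ok) < 2) return(NA_real_)
  p <- profile[ok]
  d <- diff(sign(p - 1.5))
  cross <- which(d != 0 & !is.na(d))
  if (length(cross) == 0) return(NA_real_)
  slopes <- abs(p[cross + 1] - p[cross])
  i <- cross[which.max(slopes)]
  frac <- (1.5 - p[i]) / (p[i + 1] - p[i])
  # column centers sit at (index - 0.5); interpolate between them
  (ok[i] - 0.5) + frac * (ok[i + 1] - ok[i])
}
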