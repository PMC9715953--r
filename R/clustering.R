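#' Binary K-Means with canonical labels
#'
#' Runs k = 2 K-Means (squared-Euclidean objective, 50 seeded restarts) and
#' canonicalizes the arbitrary cluster indices so that cluster 1 is the
#' cluster with the higher mean pixel density — the normal-like side in
#' tissue, making the continuous map, occupancies and IIOD comparable
#' across subsets and runs.
#'
#' @param x Numeric matrix (rows = sub-images).
#' @param pixel_density Per-row pixel density used for canonicalization.
#' @param seed Integer seed; identical seeds give identical labels.
#' @param nstart Number of random restarts; default 50.
#' @return Integer vector of labels in `{1, 2}`.
#' @export
kmeans_binary <- function(x, pixel_density, seed = 1L, nstart = 50) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("K-Means with k = 2 requires at least 2 rows")
  if (!all(is.finite(x))) stop("K-Means input contains non-finite values")
  stopifnot(length(pixel_density) == nrow(x))
  set.seed(seed)
  km <- stats::kmeans(x, centers = 2, nstart = nstart, iter.max = 100)
  labels <- km$cluster
  if (mean(pixel_density[labels == 2]) > mean(pixel_density[labels == 1]))
    labels <- 3L - labels
  as.integer(labels)
}

#' Per-point silhouette scores
#'
#' Euclidean-distance silhouette: for each point, `a` is its mean distance
#' to the other members of its own cluster and `b` the mean distance to the
#' opposite cluster; the score is `(b - a) / max(a, b)`, in `[-1, 1]`. A
#' point that is the sole member of its cluster scores 0.
#'
#' @param x Numeric matrix (rows = points).
#' @param labels Integer labels in `{1, 2}`; both clusters must be
#'   non-empty.
#' @return Numeric vector of silhouette scores.
#' @export
silhouette_scores <- function(x, labels) {
  x <- as.matrix(x)
  stopifnot(length(labels) == nrow(x))
  if (length(unique(labels)) < 2)
    stop("silhouette requires both clusters to be non-empty")
  dmat <- as.matrix(stats::dist(x))
  n <- nrow(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    own[i] <- FALSE
    if (!any(own)) { s[i] <- 0; next }  # singleton cluster
    a <- mean(dmat[i, own])
    b <- mean(dmat[i, labels != labels[i]])
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  s
}

#' Continuous cluster association
#'
#' Fuses the binary label `B` and silhouette score `S` into a single
#' continuous association `C`: `C = B + (1 - S)/2` for `B = 1` and
#' `C = B - (1 - S)/2` for `B = 2`. `C` ranges from 1 (perfectly associated
#' with cluster 1) to 2 (perfectly associated with cluster 2); the
#' inter-cluster boundary lies at 1.5, and points with negative silhouette
#' scores move across it to the opposite cluster.
#'
#' @param B Integer labels in `{1, 2}`.
#' @param S Silhouette scores in `[-1, 1]`.
#' @return Numeric vector `C` in `[1, 2]`.
#' @export
continuous_association <- function(B, S) {
  if (!all(B %in% c(1L, 2L))) stop("B must contain only labels 1 and 2")
  if (any(!is.finite(S)) || any(S < -1 - 1e-12) || any(S > 1 + 1e-12))
    stop("silhouette scores must lie in [-1, 1]")
  S <- pmin(pmax(S, -1), 1)
  ifelse(B == 1L, 1 + (1 - S) / 2, 2 - (1 - S) / 2)
}

#' Place per-tile values on the sub-image grid
#'
#' @param values Numeric vector, one value per retained tile.
#' @param tile_row,tile_col Grid indices of the retained tiles.
#' @param n_rows,n_cols Grid dimensions.
#' @return Numeric matrix with `NA` at missing (rejected) cells.
#' @export
grid_map <- function(values, tile_row, tile_col, n_rows, n_cols) {
  m <- matrix(NA_real_, n_rows, n_cols)
  m[cbind(tile_row, tile_col)] <- values
  m
}

#' NA-preserving 3x3 median filter
#'
#' Each present cell is replaced by the median of itself and its up to 8
#' nearest neighbours, computed over the present (non-`NA`) values only;
#' border cells use their shrunken neighbourhood and missing cells
#' (rejected sub-images) stay missing. The filter never creates values
#' outside the range of its inputs.
#'
#' @param grid Numeric matrix with `NA` marking missing cells.
#' @return Filtered matrix of the same shape.
#' @export
median_filter_map <- function(grid) {
  nr <- nrow(grid); nc <- ncol(grid)
  out <- grid
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (is.na(grid[i, j])) next
      nb <- grid[max(1, i - 1):min(nr, i + 1),
                 max(1, j - 1):min(nc, j + 1)]
      out[i, j] <- stats::median(nb[!is.na(nb)])
    }
  }
  out
}

#' Vertical (per-column) profile of a cluster map
#'
#' Averages the present values of each grid column, tracing how cluster
#' association varies horizontally across the tissue (tumor to normal).
#'
#' @param grid Numeric matrix with `NA` missing cells.
#' @return Numeric vector, one mean per column; all-missing columns are
#'   `NA`.
#' @export
vertical_profile <- function(grid) {
  p <- colMeans(grid, na.rm = TRUE)
  p[is.nan(p)] <- NA_real_
  p
}

#' Harmonic mean
#'
#' `H = N / sum(1 / x_i)`; defined for strictly positive inputs and never
#' larger than the arithmetic mean, which makes it sensitive to the weakest
#' cluster's silhouette score.
#'
#' @param x Strictly positive numeric vector.
#' @return The harmonic mean.
#' @export
harmonic_mean <- function(x) {
  if (length(x) == 0 || any(!is.finite(x)) || any(x <= 0))
    stop("harmonic mean requires strictly positive finite values")
  length(x) / sum(1 / x)
}

#' Cluster one data subset and build its continuous map
#'
#' Selects the subset columns, standardizes them (PC score subsets are used
#' as-is, consistent with the PCA standardization), runs [kmeans_binary()]
#' and [silhouette_scores()], and fuses them with
#' [continuous_association()].
#'
#' @param table Row-aligned feature table (from [standardize_features()]).
#' @param pca A [run_pca()] result on the same rows.
#' @param subset Subset identifier (see [select_subset()]).
#' @param seed Integer seed for K-Means.
#' @return A tibble of class `"cluster_result"`: `tile_row`, `tile_col`,
#'   `subset`, `label`, `silhouette`, `c_assoc`.
#' @export
cluster_subset <- function(table, pca = NULL, subset = "ALL", seed = 1L) {
  x <- select_subset(table, pca, subset)
  if (!grepl("^PC[0-9]+$", subset)) x <- scale(x)
  B <- kmeans_binary(x, table$pixel_density, seed = seed)
  S <- silhouette_scores(x, B)
  out <- tibble::tibble(tile_row = table$tile_row,
                        tile_col = table$tile_col,
                        subset = subset, label = B, silhouette = S,
                        c_assoc = continuous_association(B, S))
  class(out) <- c("cluster_result", class(out))
  out
}

#' Compare clustering quality across data subsets
#'
#' Runs binary K-Means and silhouette scoring for each subset and reports
#' the per-cluster mean silhouette scores together with their arithmetic
#' and harmonic means. The harmonic mean weights the weaker cluster more
#' heavily, so a subset that dumps almost everything into one cluster can
#' score a high arithmetic mean yet a depressed harmonic mean. The
#' subset(s) with the maximal harmonic mean are flagged.
#'
#' @param table Row-aligned feature table.
#' @param pca A [run_pca()] result on the same rows.
#' @param subsets Character vector of subset identifiers.
#' @param seed Integer seed (shared by all subsets).
#' @return Tibble with one row per subset: `subset`, `sil_cluster1`,
#'   `sil_cluster2`, `arithmetic_mean`, `harmonic_mean` (`NA` when a
#'   cluster's mean silhouette is non-positive), `best`.
#' @export
compare_subsets <- function(table, pca = NULL,
                            subsets = c("INT", "INT+TXT", "POL", "ALL",
                                        "PC1", "PC2", "PC3", "PC4"),
                            seed = 1L) {
  rows <- purrr::map(subsets, function(ss) {
    res <- cluster_subset(table, pca, ss, seed = seed)
    m1 <- mean(res$silhouette[res$label == 1L])
    m2 <- mean(res$silhouette[res$label == 2L])
    hm <- if (m1 > 0 && m2 > 0) harmonic_mean(c(m1, m2)) else NA_real_
    tibble::tibble(subset = ss, sil_cluster1 = m1, sil_cluster2 = m2,
                   arithmetic_mean = (m1 + m2) / 2, harmonic_mean = hm)
  })
  out <- dplyr::bind_rows(rows)
  best <- which(out$harmonic_mean == max(out$harmonic_mean, na.rm = TRUE))
  out$best <- seq_len(nrow(out)) %in% best
  out
}
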