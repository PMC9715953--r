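#' Standardize the feature table
#'
#' Centers each feature column to mean 0 and scales it to SD 1 (z-scores),
#' so that only true variation between sub-images, not differences of scale
#' or units, contributes to the PCA variance. Rows containing missing
#' feature values (e.g. the undefined correlation of a constant tile) are
#' dropped with a message.
#'
#' @param table A [build_feature_table()] tibble (or any tibble whose
#'   feature columns are everything except `tile_row`/`tile_col`).
#' @param features Character vector of feature columns; defaults to all
#'   columns except `tile_row` and `tile_col`.
#' @return A list: `x` (standardized numeric matrix), `model` (a
#'   `"standardizer"` with per-feature `center` and `scale`), and `table`
#'   (the input restricted to the rows actually used, so downstream stages
#'   stay row-aligned with `x`).
#' @export
standardize_features <- function(table, features = NULL) {
  if (is.null(features))
    features <- setdiff(names(table), c("tile_row", "tile_col"))
  x <- as.matrix(table[, features])
  keep <- stats::complete.cases(x)
  if (nrow(x) - sum(keep) > 0)
    message("dropping ", nrow(x) - sum(keep),
            " row(s) with missing feature values")
  x <- x[keep, , drop = FALSE]
  if (nrow(x) < 2) stop("standardization requires at least 2 complete rows")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  zero <- scl == 0
  if (any(zero))
    stop("zero-variance feature column(s): ",
         paste(features[zero], collapse = ", "))
  xs <- scale(x, center = ctr, scale = scl)
  attr(xs, "scaled:center") <- NULL
  attr(xs, "scaled:scale") <- NULL
  model <- structure(list(center = ctr, scale = scl, features = features),
                     class = "standardizer")
  list(x = xs, model = model, table = table[keep, , drop = FALSE])
}

#' Apply a fitted standardizer to a new table
#'
#' @param model A `"standardizer"` from [standardize_features()].
#' @param table A tibble containing the model's feature columns.
#' @return Standardized numeric matrix.
#' @export
apply_standardizer <- function(model, table) {
  stopifnot(inherits(model, "standardizer"))
  missing <- setdiff(model$features, names(table))
  if (length(missing))
    stop("table lacks feature column(s): ", paste(missing, collapse = ", "))
  x <- as.matrix(table[, model$features])
  xs <- scale(x, center = model$center, scale = model$scale)
  attr(xs, "scaled:center") <- NULL
  attr(xs, "scaled:scale") <- NULL
  xs
}

#' Principal component analysis of standardized features
#'
#' Eigendecomposition of the covariance matrix of the standardized data (on
#' z-scores this is the correlation matrix of the original features, so the
#' eigenvalues sum to the number of features). The sign of each component is
#' fixed deterministically: the loading of largest magnitude is made
#' positive, so maps and transferred projections are reproducible across
#' runs.
#'
#' @param x Standardized numeric matrix (rows = sub-images).
#' @return A `"pshg_pca"` object: `values` (eigenvalues, decreasing),
#'   `loadings` (features x PCs, orthonormal columns), `scores` (rows x
#'   PCs), `var_explained`, `cum_var`, `n_obs`.
#' @export
run_pca <- function(x) {
  if (!all(is.finite(x))) stop("PCA input contains non-finite values")
  if (nrow(x) <= ncol(x))
    warning("fewer observations (", nrow(x), ") than features + 1 (",
            ncol(x) + 1, "); trailing eigenvalues are degenerate")
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  k <- length(pc$sdev)
  loadings <- pc$rotation
  scores <- pc$x
  for (j in seq_len(k)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  values <- pc$sdev^2
  structure(list(values = values, loadings = loadings, scores = scores,
                 var_explained = values / sum(values),
                 cum_var = cumsum(values) / sum(values),
                 n_obs = nrow(x)),
            class = "pshg_pca")
}

#' Kaiser criterion: retain components with eigenvalue at least 1
#'
#' On standardized data an eigenvalue below 1 marks a component carrying
#' less variance than a single original feature. The boundary is inclusive
#' (an eigenvalue of exactly 1 is retained).
#'
#' @param pca A [run_pca()] result.
#' @return Integer vector of retained PC indices (possibly empty, with a
#'   warning).
#' @export
kaiser_retain <- function(pca) {
  stopifnot(inherits(pca, "pshg_pca"))
  keep <- which(pca$values >= 1)
  if (length(keep) == 0)
    warning("no eigenvalue reaches 1; no component retained")
  keep
}

#' @exportS3Method generics::tidy
tidy.pshg_pca <- function(x, matrix = c("loadings", "eigenvalues", "scores"),
                          ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    eigenvalues = tibble::tibble(
      pc = seq_along(x$values), eigenvalue = x$values,
      var_explained = x$var_explained, cum_var = x$cum_var),
    loadings = tibble::as_tibble(x$loadings, rownames = "feature") |>
      tidyr::pivot_longer(-"feature", names_to = "pc",
                          values_to = "loading"),
    scores = tibble::as_tibble(x$scores, rownames = NULL) |>
      dplyr::mutate(row = dplyr::row_number(), .before = 1))
}

#' @exportS3Method generics::glance
glance.pshg_pca <- function(x, ...) {
  keep <- suppressWarnings(kaiser_retain(x))
  tibble::tibble(n_features = ncol(x$loadings), n_obs = x$n_obs,
                 n_retained = length(keep),
                 cum_var_retained = if (length(keep)) x$cum_var[max(keep)]
                                    else 0)
}

#' Resolve a clustering data subset
#'
#' The eight subsets mirror the combinations used to optimize the
#' clustering: `INT` (SHG intensity mean and MAD plus pixel density),
#' `INT+TXT` (`INT` plus the intensity texture features), `POL` (mean and
#' MAD of all five polarimetric parameters plus pixel density), `ALL` (the
#' full 36-feature set), and `PC1`..`PC4` (a single principal-component
#' score column).
#'
#' @param table The (row-aligned) feature table returned by
#'   [standardize_features()].
#' @param pca A [run_pca()] result on the same rows; required for `PCk`
#'   subsets.
#' @param subset Subset identifier.
#' @return Numeric matrix with named columns, one row per sub-image.
#' @export
select_subset <- function(table, pca = NULL,
                          subset = c("INT", "INT+TXT", "POL", "ALL",
                                     "PC1", "PC2", "PC3", "PC4")) {
  subset <- match.arg(subset)
  if (grepl("^PC[0-9]+$", subset)) {
    if (is.null(pca)) stop("subset ", subset, " requires a PCA model")
    k <- as.integer(sub("PC", "", subset))
    if (k > ncol(pca$scores)) stop("PCA has no component ", k)
    if (nrow(pca$scores) != nrow(table))
      stop("PCA scores and table have different numbers of rows")
    return(matrix(pca$scores[, k], ncol = 1,
                  dimnames = list(NULL, subset)))
  }
  cols <- switch(subset,
    "INT" = c("pixel_density", "icp_mean", "icp_mad"),
    "INT+TXT" = c("pixel_density", "icp_mean", "icp_mad", "icp_contrast",
                  "icp_correlation", "icp_entropy", "icp_asm", "icp_idm"),
    "POL" = c("pixel_density",
              as.vector(t(outer(PSHG_PARAMS, c("mean", "mad"),
                                paste, sep = "_")))),
    "ALL" = feature_column_names())
  missing <- setdiff(cols, names(table))
  if (length(missing))
    stop("feature table lacks column(s): ", paste(missing, collapse = ", "))
  as.matrix(table[, cols])
}
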