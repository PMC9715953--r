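#' Pipeline configuration
#'
#' Bundles the phantom settings and the stage parameters behind a single
#' object. A single `seed` drives every stochastic stage through fixed
#' offsets (phantom generation uses `seed`, stack synthesis `seed + 1`,
#' calibration frames `seed + 2`, K-Means `seed + 3`), so stages rerun in
#' isolation reproduce the full run.
#'
#' @param phantom A [phantom_config()] describing the input phantom.
#' @param min_snr SNR threshold for pixel validity; default 1.
#' @param tile_size Sub-image size in pixels; defaults to the phantom's.
#' @param n_levels GLCM grey levels; default 64.
#' @param min_density Minimum pixel density per retained tile; default 0.1.
#' @param subsets Data subsets to cluster; default the eight standard ones.
#' @param seed Master seed; defaults to the phantom's seed.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(phantom = phantom_config(),
                            min_snr = 1, tile_size = phantom$tile_size,
                            n_levels = 64, min_density = 0.1,
                            subsets = c("INT", "INT+TXT", "POL", "ALL",
                                        "PC1", "PC2", "PC3", "PC4"),
                            seed = phantom$seed) {
  structure(list(phantom = phantom, min_snr = min_snr,
                 tile_size = tile_size, n_levels = n_levels,
                 min_density = min_density, subsets = subsets,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; the `phantom`
#' block mirrors [phantom_config()], with optional `tumor` and `normal`
#' blocks mirroring [phantom_region()].
#'
#' @param path YAML file path.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  ph <- y$phantom %||% list()
  for (side in c("tumor", "normal"))
    if (!is.null(ph[[side]]))
      ph[[side]] <- do.call(phantom_region, ph[[side]])
  phantom <- do.call(phantom_config, ph)
  args <- y[setdiff(names(y), "phantom")]
  do.call(pipeline_config, c(list(phantom = phantom), args))
}

# Crop phantom truth maps to a window (used for the calibration stack).
crop_truth <- function(truth, rows, cols) {
  t2 <- truth
  for (f in c("region", "fiber", "exclusion", "icp", "rratio", "dcp",
              "shgcd", "shgld"))
    t2[[f]] <- truth[[f]][rows, cols, drop = FALSE]
  cfg <- truth$config
  cfg$height <- length(rows); cfg$width <- length(cols)
  cfg$field_height <- cfg$height; cfg$field_width <- cfg$width
  cfg$mosaic_rows <- cfg$mosaic_cols <- 1L
  cfg$boundary_col <- max(1L, min(cfg$width - 1L,
                                  truth$boundary_col - min(cols) + 1L))
  t2$config <- cfg
  t2
}

#' Analyze a phantom end to end
#'
#' Runs the full in-memory chain on a phantom: truth generation, stack
#' synthesis, SNR calibration on a repeated-frame stack of a window
#' straddling the boundary, Stokes elements, the five parameter maps with
#' the SNR mask, the 36-feature table, standardization + PCA, clustering of
#' the requested subsets, and the margin report with IIOD against the
#' phantom's known boundary.
#'
#' @param config A [pipeline_config()].
#' @param calibrate Fit and apply the SNR calibration (requires synthesizing
#'   an extra repeated-frame window); default `TRUE` for shot-noise
#'   phantoms.
#' @param cal_frames,cal_size Frames and window edge length for the
#'   calibration stack.
#' @return A list of class `"pshg_analysis"`: `truth`, `calibration`,
#'   `maps`, `features` (feature table), `pca`, `std_model`, `clusters`
#'   (named list of [cluster_subset()] tibbles), `comparison`
#'   ([compare_subsets()] tibble), `margin` ([build_margin_report()]
#'   tibble), `boundary` (per-subset tibble of estimated boundary positions
#'   in tile columns), `truth_tiles`.
#' @export
analyze_phantom <- function(config = pipeline_config(),
                            calibrate = config$phantom$noise == "shot",
                            cal_frames = 8, cal_size = 256) {
  stopifnot(inherits(config, "pipeline_config"))
  ph <- config$phantom
  truth <- generate_phantom(ph)
  stack <- synthesize_stack(truth, ph)
  cal <- NULL
  if (calibrate) {
    sz <- min(cal_size, ph$height, ph$width)
    rows <- seq_len(sz)
    c0 <- max(1L, min(ph$width - sz + 1L, ph$boundary_col - sz %/% 2))
    cal_truth <- crop_truth(truth, rows, c0:(c0 + sz - 1L))
    cal_truth$config$seed <- ph$seed + 1L  # synthesize uses seed + 2
    cal_stack <- synthesize_stack(cal_truth, cal_truth$config,
                                  n_frames = cal_frames)
    cal <- fit_snr_calibration(cal_stack)
  }
  stokes <- compute_stokes(stack)
  maps <- suppressWarnings(
    polarimetric_maps(stokes, calibration = cal, min_snr = config$min_snr))
  features <- build_feature_table(maps, tile_size = config$tile_size,
                                  exclusion = truth$exclusion,
                                  min_density = config$min_density,
                                  n_levels = config$n_levels)
  std <- standardize_features(features)
  pca <- run_pca(std$x)
  clusters <- stats::setNames(
    purrr::map(config$subsets,
               ~cluster_subset(std$table, pca, .x, seed = config$seed + 3L)),
    config$subsets)
  comparison <- compare_subsets(std$table, pca, config$subsets,
                                seed = config$seed + 3L)
  grid <- tile_grid(ph$height, ph$width, config$tile_size)
  truth_tiles <- rasterize_ground_truth(truth$region, grid)
  margin <- build_margin_report(clusters, truth_tiles)
  n_rows <- attr(features, "n_rows"); n_cols <- attr(features, "n_cols")
  boundary <- purrr::map_dfr(clusters, function(res) {
    cmap <- grid_map(res$c_assoc, res$tile_row, res$tile_col,
                     n_rows, n_cols)
    prof <- vertical_profile(median_filter_map(cmap))
    tibble::tibble(subset = res$subset[1],
                   boundary_tiles = estimate_boundary(prof),
                   boundary_px = estimate_boundary(prof) *
                     config$tile_size)
  })
  structure(list(truth = truth, calibration = cal, maps = maps,
                 features = features, pca = pca, std_model = std$model,
                 table = std$table, clusters = clusters,
                 comparison = comparison, margin = margin,
                 boundary = boundary, truth_tiles = truth_tiles,
                 config = config),
            class = "pshg_analysis")
}

#' Run the pipeline and write its artifacts
#'
#' Calls [analyze_phantom()] and writes every stage's outputs under
#' `out_dir`: the five parameter maps and validity mask as 32-bit float
#' TIFFs, region/exclusion masks as 8-bit label TIFFs, the feature table
#' and per-subset cluster grids as CSV, the PCA model as JSON, the subset
#' comparison, margin report and boundary estimates as CSV, and a manifest
#' (JSON) listing every file with its stage. Identical config and seed give
#' byte-identical CSV/JSON outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param ... Passed to [analyze_phantom()].
#' @return The `"pshg_analysis"` result, invisibly, with the manifest in
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         out_dir = tempfile("pshg_run_"), ...) {
  res <- analyze_phantom(config, ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  emit <- function(stage, file) {
    manifest[[length(manifest) + 1]] <<- list(stage = stage, file = file)
  }
  map_tf <- list(icp = c(65535, 0), rratio = c(64, 0), dcp = c(1, 0),
                 shgcd = c(4, -2), shgld = c(4, -2))
  for (p in PSHG_PARAMS) {
    f <- file.path(out_dir, paste0("map_", p, ".tif"))
    write_map_tiff(res$maps[[p]], f,
                   scale = map_tf[[p]][1], offset = map_tf[[p]][2])
    emit("polarimetry", f)
  }
  f <- file.path(out_dir, "valid_mask.tif")
  write_label_tiff(res$maps$valid * 1L, f); emit("polarimetry", f)
  f <- file.path(out_dir, "region_mask.tif")
  write_label_tiff(res$truth$region, f); emit("phantom", f)
  f <- file.path(out_dir, "exclusion_mask.tif")
  write_label_tiff(res$truth$exclusion * 1L, f); emit("phantom", f)

  f <- file.path(out_dir, "features.csv")
  utils::write.csv(res$features, f, row.names = FALSE); emit("texture", f)
  f <- file.path(out_dir, "pca.json")
  jsonlite::write_json(list(eigenvalues = res$pca$values,
                            var_explained = res$pca$var_explained,
                            loadings = as.data.frame(res$pca$loadings),
                            features = rownames(res$pca$loadings)),
                       f, digits = NA, auto_unbox = TRUE)
  emit("decomposition", f)
  for (ss in names(res$clusters)) {
    f <- file.path(out_dir,
                   paste0("cluster_", gsub("[^A-Za-z0-9]", "_", ss), ".csv"))
    utils::write.csv(res$clusters[[ss]], f, row.names = FALSE)
    emit("clustering", f)
  }
  f <- file.path(out_dir, "subset_comparison.csv")
  utils::write.csv(res$comparison, f, row.names = FALSE)
  emit("clustering", f)
  f <- file.path(out_dir, "margin_report.csv")
  utils::write.csv(res$margin, f, row.names = FALSE); emit("margin", f)
  f <- file.path(out_dir, "boundary_estimates.csv")
  utils::write.csv(res$boundary, f, row.names = FALSE); emit("margin", f)

  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE)
  res$manifest <- manifest
  res$out_dir <- out_dir
  invisible(res)
}
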