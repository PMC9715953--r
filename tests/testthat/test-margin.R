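test_that("ground-truth rasterization uses majority labels with ties excluded", {
  grid <- tile_grid(8, 8, 4)
  region <- region_from_boundary(8, 8, 4)       # clean split at a tile edge
  gt <- rasterize_ground_truth(region, grid)
  expect_equal(as.character(gt$region),
               c("tumor", "normal", "tumor", "normal"))
  # 60/40 straddle -> majority label
  region <- region_from_boundary(8, 8, 5)
  gt <- rasterize_ground_truth(region, grid)
  expect_equal(as.character(gt$region[gt$tile_col == 2]),
               c("normal", "normal"))
  # exact tie -> excluded
  region <- matrix(c(1L, 2L), 8, 8)  # alternating rows: 8 vs 8 per tile
  gt <- rasterize_ground_truth(region, grid)
  expect_true(all(gt$region == "excluded"))
  # fully excluded tile
  region <- region_from_boundary(8, 8, 4)
  region[1:4, 1:4] <- 0L
  gt <- rasterize_ground_truth(region, grid)
  expect_equal(as.character(gt$region[1]), "excluded")
  expect_error(rasterize_ground_truth(matrix(1L, 4, 4), grid), "geometry")
})

test_that("cluster occupancies are silhouette-weighted and sum to one", {
  # perfect case: all C = 1 in a region
  q <- cluster_occupancy(c(1, 1, 1), rep("tumor", 3))
  expect_equal(q$q1[q$region == "tumor"], 1)
  expect_equal(q$q2[q$region == "tumor"], 0)
  # hand evaluation: C = {1.0, 1.25, 1.75} -> Q1 = 0.75, Q2 = 0.25
  q <- cluster_occupancy(c(1, 1.25, 1.75), rep("normal", 3))
  expect_equal(q$q1[q$region == "normal"], 0.75)
  expect_equal(q$q2[q$region == "normal"], 0.25)
  # Q1 + Q2 = 1 for any region with weight; C = 1.5 contributes nothing
  set.seed(50)
  C <- c(runif(20, 1, 2), 1.5)
  reg <- sample(c("tumor", "normal"), 21, replace = TRUE)
  q <- cluster_occupancy(C, reg)
  expect_equal(q$q1 + q$q2, c(1, 1))
  # scaling all weights |C - 1.5| by a common factor leaves Q unchanged
  C2 <- 1.5 + 0.3 * (C - 1.5)
  expect_equal(cluster_occupancy(C2, reg)[, c("q1", "q2")],
               q[, c("q1", "q2")])
  # a region with zero weight yields NA occupancies
  q <- cluster_occupancy(c(1.5, 1.5), c("tumor", "tumor"))
  expect_true(all(is.na(q[q$region == "tumor", c("q1", "q2")])))
})

test_that("IIOD reaches its printed extremes and hand-computed value", {
  expect_equal(iiod(0, 1, 1, 0), 1)          # perfect separation
  expect_equal(iiod(1, 0, 1, 0), 0)          # one cluster everywhere
  expect_equal(iiod(0.5, 0.5, 0.5, 0.5), 0)  # 50% occupancy
  expect_equal(iiod(0.8, 0.2, 0.3, 0.7), 0.06)
  expect_true(is.na(iiod(NA, 1, 1, 0)))
  # invariant to swapping cluster indices together with sides
  set.seed(60)
  for (i in 1:20) {
    q1l <- runif(1); q1r <- runif(1)
    v1 <- iiod(q1l, 1 - q1l, q1r, 1 - q1r)
    v2 <- iiod(1 - q1r, q1r, 1 - q1l, q1l)
    expect_equal(v1, v2)
    expect_gte(v1, 0); expect_lte(v1, 1)
  }
})

test_that("margin report scores subsets and flags the best deterministically", {
  truth <- tibble::tibble(tile_row = rep(1:2, each = 4),
                          tile_col = rep(1:4, 2),
                          region = factor(rep(c("tumor", "tumor", "normal",
                                                "normal"), 2),
                                          levels = c("tumor", "normal",
                                                     "excluded")))
  perfect <- tibble::tibble(tile_row = truth$tile_row,
                            tile_col = truth$tile_col,
                            subset = "A",
                            label = rep(c(2L, 2L, 1L, 1L), 2),
                            silhouette = 1,
                            c_assoc = rep(c(2, 2, 1, 1), 2))
  poor <- dplyr::mutate(perfect, subset = "B",
                        c_assoc = rep(c(1.6, 1.4, 1.6, 1.4), 2),
                        label = rep(c(2L, 1L, 2L, 1L), 2))
  rep_out <- build_margin_report(list(perfect, poor), truth)
  expect_equal(rep_out$iiod[rep_out$subset == "A"], 1)
  expect_true(rep_out$best[rep_out$subset == "A"])
  expect_false(rep_out$best[rep_out$subset == "B"])
  # all subsets identical -> tie broken toward the first listed
  rep_tie <- build_margin_report(list(perfect,
                                      dplyr::mutate(perfect, subset = "A2")),
                                 truth)
  expect_equal(sum(rep_tie$best), 1)
  expect_true(rep_tie$best[1])
})

test_that("PC transfer reproduces reference scores and ignores loading sign", {
  cfg <- small_config(seed = 41)
  maps <- polarimetric_maps(
    compute_stokes(synthesize_stack(generate_phantom(cfg), cfg)))
  ft <- build_feature_table(maps, tile_size = 32, n_levels = 16)
  std <- standardize_features(ft)
  pca <- run_pca(std$x)
  # self-consistency with reference standardization statistics
  proj <- transfer_pc_projection(pca, std$model, std$table, pc = 2,
                                 standardize = "reference")
  expect_equal(unname(proj), unname(pca$scores[, 2]), tolerance = 1e-10)
  # a second phantom, same settings but another seed
  cfg2 <- small_config(seed = 42)
  maps2 <- polarimetric_maps(
    compute_stokes(synthesize_stack(generate_phantom(cfg2), cfg2)))
  ft2 <- build_feature_table(maps2, tile_size = 32, n_levels = 16)
  std2 <- standardize_features(ft2)
  proj2 <- transfer_pc_projection(pca, std$model, std2$table, pc = 1)
  B <- kmeans_binary(matrix(proj2, ncol = 1), std2$table$pixel_density,
                     seed = 7)
  # negating the loading vector leaves canonical labels unchanged
  pca_neg <- pca
  pca_neg$loadings <- -pca_neg$loadings
  proj_neg <- transfer_pc_projection(pca_neg, std$model, std2$table, pc = 1)
  B_neg <- kmeans_binary(matrix(proj_neg, ncol = 1),
                         std2$table$pixel_density, seed = 7)
  expect_identical(B, B_neg)
  # transferred clustering separates the two sides of the new phantom
  gt2 <- rasterize_ground_truth(generate_phantom(cfg2)$region,
                                tile_grid(cfg2$height, cfg2$width, 32))
  joined <- dplyr::inner_join(
    tibble::tibble(tile_row = std2$table$tile_row,
                   tile_col = std2$table$tile_col, label = B),
    gt2, by = c("tile_row", "tile_col"))
  tab <- table(joined$label, joined$region)
  frac_tumor_2 <- tab["2", "tumor"] / sum(tab[, "tumor"])
  frac_normal_1 <- tab["1", "normal"] / sum(tab[, "normal"])
  expect_gt(frac_tumor_2, 0.5)
  expect_gt(frac_normal_1, 0.5)
  expect_error(transfer_pc_projection(pca, std$model, ft2[, 1:5], pc = 1),
               "lacks")
})

test_that("boundary estimation finds the steepest 1.5 crossing", {
  prof <- c(1.9, 1.85, 1.8, 1.3, 1.2, 1.1)
  # crossing between columns 3 and 4 (centers 2.5 and 3.5)
  est <- estimate_boundary(prof)
  expect_gt(est, 2.5); expect_lt(est, 3.5)
  expect_equal(est, 2.5 + (1.5 - 1.8) / (1.3 - 1.8))
  expect_true(is.na(estimate_boundary(c(1.9, 1.8, 1.7))))
  expect_true(is.na(estimate_boundary(c(NA, NA))))
  # NA columns are skipped, interpolation spans them
  est <- estimate_boundary(c(1.9, NA, 1.1))
  expect_gt(est, 0.5); expect_lt(est, 2.5)
})
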