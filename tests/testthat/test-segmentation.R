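test_that("VOI cylinders match analytic volume and union idempotently", {
  h <- 1.625
  vol <- cp_volume(array(0, c(60, 60, 12)), h)
  seed1 <- data.frame(cx = 30, cy = 30, z_start = 1, z_end = 10,
                      radius_um = 10, region = "all")
  # no seeds -> empty mask
  empty <- build_voi_mask(seed1[0, ], vol)
  expect_false(any(empty$mask))
  voi <- build_voi_mask(seed1, vol)
  n_expected <- pi * (10 / h)^2 * 10
  expect_lt(abs(sum(voi$mask) - n_expected) / n_expected, 0.10)
  # two identical seeds: same mask (idempotent union)
  voi2 <- build_voi_mask(rbind(seed1, seed1), vol)
  expect_identical(voi2$mask, voi$mask)
  # seed outside the grid is skipped with a warning
  far <- data.frame(cx = 500, cy = 500, z_start = 1, z_end = 2,
                    radius_um = 5, region = "all")
  expect_warning(voi3 <- build_voi_mask(far, vol), "outside")
  expect_false(any(voi3$mask))
})

test_that("bimodal threshold lands in the valley of a two-Gaussian
           mixture", {
  set.seed(11)
  h <- 1.625
  n <- 1e5
  vals <- c(rnorm(n / 2, 100, 10), rnorm(n / 2, 200, 10))
  d <- c(50, 50, 40)
  vol <- cp_volume(array(vals, d), h)
  voi <- build_voi_mask(data.frame(cx = 25, cy = 25, z_start = 1,
                                   z_end = 40, radius_um = 200,
                                   region = "all"), vol)
  thr <- find_bimodal_threshold(vol, voi)
  expect_true(thr$bimodal)
  # analytic minimum of the mixture density is at 150
  expect_gte(thr$threshold, 140)
  expect_lte(thr$threshold, 160)
  expect_lt(thr$peaks_gray[["background"]], thr$threshold)
  expect_gt(thr$peaks_gray[["plaque"]], thr$threshold)
})

test_that("a unimodal histogram engages the flagged Otsu fallback", {
  set.seed(12)
  vol <- cp_volume(array(rnorm(64^3, 120, 8), c(64, 64, 64)), 1.625)
  voi <- build_voi_mask(data.frame(cx = 32, cy = 32, z_start = 1,
                                   z_end = 64, radius_um = 200,
                                   region = "all"), vol)
  thr <- find_bimodal_threshold(vol, voi)
  expect_false(thr$bimodal)
  expect_match(thr$method, "otsu")
})

test_that("two delta-like peaks give the midpoint of the empty valley", {
  vox <- array(50, c(20, 20, 20))
  vox[, , 11:20] <- 150
  vol <- cp_volume(vox, 1.625)
  voi <- build_voi_mask(data.frame(cx = 10, cy = 10, z_start = 1,
                                   z_end = 20, radius_um = 100,
                                   region = "all"), vol)
  thr <- find_bimodal_threshold(vol, voi)
  expect_true(thr$bimodal)
  expect_lt(abs(thr$threshold - 100), 1)
})

test_that("degenerate VOIs are rejected", {
  vol <- cp_volume(array(7, c(10, 10, 10)), 1.625)
  voi <- build_voi_mask(data.frame(cx = 5, cy = 5, z_start = 1, z_end = 10,
                                   radius_um = 50, region = "all"), vol)
  expect_error(find_bimodal_threshold(vol, voi), "constant")
  empty <- build_voi_mask(vol = vol, seeds = data.frame(
    cx = numeric(), cy = numeric(), z_start = numeric(),
    z_end = numeric(), radius_um = numeric(), region = character()))
  expect_error(find_bimodal_threshold(vol, empty), "empty")
})

test_that("the 150 um^3 rule removes a 30-voxel and keeps a 100-voxel
           component at 1.625 um voxels", {
  h <- 1.625
  vox <- array(0, c(24, 24, 24))
  vox[2:4, 2:3, 2:6] <- 1     # 3 x 2 x 5  = 30 voxels = 128.7 um^3
  vox[10:14, 10:14, 10:13] <- 1  # 5 x 5 x 4 = 100 voxels = 429.2 um^3
  vol <- cp_volume(vox, h)
  voi <- build_voi_mask(data.frame(cx = 12, cy = 12, z_start = 1,
                                   z_end = 24, radius_um = 100,
                                   region = "all"), vol)
  expect_equal(30 * h^3, 128.7, tolerance = 1e-3)
  expect_equal(100 * h^3, 429.2, tolerance = 1e-3)
  lab <- extract_plaques(vol, voi, threshold = 0.5)  # default 150 um^3
  expect_identical(length(label_ids(lab)), 1L)
  expect_identical(sum(lab$labels > 0), 100L)
  # with the filter off, both survive, ordered by descending volume
  lab2 <- extract_plaques(vol, voi, threshold = 0.5, min_volume_um3 = 0)
  expect_identical(length(label_ids(lab2)), 2L)
  expect_identical(sum(lab2$labels == 1L), 100L)
  expect_identical(sum(lab2$labels == 2L), 30L)
})

test_that("raising threshold or the volume filter never increases labels or
           label volumes", {
  set.seed(21)
  vox <- array(rnorm(20^3, 100, 30), c(20, 20, 20))
  vol <- cp_volume(vox, 1.625)
  voi <- build_voi_mask(data.frame(cx = 10, cy = 10, z_start = 1,
                                   z_end = 20, radius_um = 100,
                                   region = "all"), vol)
  count_and_max <- function(thr, mv) {
    lab <- extract_plaques(vol, voi, thr, min_volume_um3 = mv)
    ids <- label_ids(lab)
    list(n = length(ids),
         vmax = if (length(ids)) max(tabulate(lab$labels[lab$labels > 0]))
         else 0L)
  }
  prev <- count_and_max(100, 0)
  for (thr in c(120, 140, 160)) {
    cur <- count_and_max(thr, 0)
    expect_lte(cur$vmax, prev$vmax)
    prev <- cur
  }
  n_loose <- count_and_max(130, 0)$n
  n_tight <- count_and_max(130, 40)$n
  expect_lte(n_tight, n_loose)
})

test_that("every extracted voxel lies inside the VOI mask", {
  ph <- generate_phantom(small_phantom_spec(n_plaque = 10L, seed = 3L))
  voi <- build_voi_mask(seed_rois_from_truth(ph$truth), ph$volume)
  thr <- find_bimodal_threshold(ph$volume, voi)
  lab <- extract_plaques(ph$volume, voi, thr$threshold)
  expect_true(all(voi$mask[lab$labels > 0]))
})

test_that("component labeling matches an exhaustive flood-fill oracle", {
  for (s in 1:3) {
    set.seed(s)
    d <- c(14L, 12L, 10L)
    mask <- array(runif(prod(d)) < 0.3, d)
    for (conn in c(6L, 26L)) {
      fast <- cereplaq:::label_components_cpp(mask, d, conn)
      slow <- brute_components(mask, conn)
      expect_identical(partition_sets(fast), partition_sets(slow))
    }
  }
})

test_that("segmentation recovers phantom plaques with high per-object
           Dice", {
  ph <- generate_phantom(small_phantom_spec(n_plaque = 20L, n_purkinje = 5L,
                                            n_vessel = 2L, seed = 7L))
  voi <- build_voi_mask(seed_rois_from_truth(ph$truth), ph$volume)
  thr <- find_bimodal_threshold(ph$volume, voi)
  lab <- extract_plaques(ph$volume, voi, thr$threshold)
  tl <- ph$truth$plaque_labels$labels
  sl <- lab$labels
  h <- 1.625
  rec <- ph$truth$records[ph$truth$records$class == "plaque", ]
  above <- rec$id[rec$n_voxels * h^3 > 150]
  dice <- vapply(above, function(id) {
    tm <- tl == id
    ids <- sl[tm]; ids <- ids[ids > 0]
    if (!length(ids)) return(0)
    best <- as.integer(names(which.max(table(ids))))
    sm <- sl == best
    2 * sum(tm & sm) / (sum(tm) + sum(sm))
  }, numeric(1))
  expect_gte(mean(dice >= 0.8), 0.95)
})
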