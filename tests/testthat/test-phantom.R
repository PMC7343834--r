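test_that("identical spec and seed give voxel-identical phantoms", {
  spec <- small_phantom_spec(n_plaque = 8L, n_purkinje = 3L, n_vessel = 1L,
                             seed = 13L)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$truth$plaque_labels$labels, b$truth$plaque_labels$labels)
  expect_identical(a$truth$records, b$truth$records)
})

test_that("zero objects and zero noise give the bare layered background", {
  spec <- small_phantom_spec(n_plaque = 0L, noise = 0, seed = 1L)
  ph <- generate_phantom(spec)
  means <- spec$layer_model$means
  expect_setequal(unique(as.vector(ph$volume$voxels)), unname(means))
  expect_identical(sum(ph$truth$plaque_labels$labels), 0L)
  expect_identical(sum(ph$truth$purkinje_labels$labels), 0L)
  expect_identical(sum(ph$truth$vessel_labels$labels), 0L)
  expect_identical(nrow(ph$truth$records), 0L)
  # layer ordering along the dorso-ventral axis: white below granular below
  # molecular
  lm <- ph$truth$layer_map
  expect_true(all(diff(lm[, 1, 1]) >= 0))
})

test_that("spec validation rejects impossible configurations", {
  expect_error(small_phantom_spec(grid = c(64L, 64L, 64L)), "too small")
  expect_error(
    phantom_spec(layer_model = list(
      means = c(white = 85, granular = 90, molecular = 100),
      thickness_um = c(white = 100, granular = 65))),
    "granular")
  expect_error(small_phantom_spec(noise = -1), "noise")
})

test_that("true plaque volumes follow the configured log-normal law", {
  # median recovery at a moderate dispersion: the sampling error of a
  # 50-draw median is ~1.25 sdlog / sqrt(50) on the log scale, so a 25%
  # band is a ~3-sigma statement at sdlog 0.4
  meds <- numeric(20)
  for (s in 1:20) {
    ph <- generate_phantom(small_phantom_spec(
      grid = c(192L, 160L, 96L), n_plaque = 50L, noise = 0, seed = s,
      sdlog = 0.4))
    v <- ph$truth$records$volume_um3
    expect_length(v, 50L)
    meds[s] <- median(v)
  }
  # each sample median within 25% of the configured 1000 um^3 median
  expect_true(all(abs(meds - 1000) / 1000 < 0.25))
  # the median of medians within 10%
  expect_lt(abs(median(meds) - 1000) / 1000, 0.10)
  # at the study dispersion (sdlog 1.25), pooled log-volume moments over 20
  # seeds stay within 3 standard errors of the generating parameters
  all_logv <- numeric(0)
  for (s in 1:20) {
    ph <- generate_phantom(small_phantom_spec(
      grid = c(192L, 160L, 96L), n_plaque = 50L, noise = 0, seed = 100 + s))
    all_logv <- c(all_logv, log(ph$truth$records$volume_um3))
  }
  n <- length(all_logv)
  expect_lt(abs(mean(all_logv) - log(1000)), 3 * 1.25 / sqrt(n))
  expect_lt(abs(sd(all_logv) - 1.25), 3 * 1.25 / sqrt(2 * n))
})

test_that("plaques are confined to the molecular layer and axes honour the
           regional spread", {
  spec <- small_phantom_spec(n_plaque = 25L, seed = 5L)
  ph <- generate_phantom(spec)
  lm <- ph$truth$layer_map
  lab <- ph$truth$plaque_labels$labels
  expect_true(all(lm[lab > 0] == 3L))
  rec <- ph$truth$records
  expect_true(all(abs(sqrt(rec$ax^2 + rec$ay^2 + rec$az^2) - 1) < 1e-9))
  for (r in seq_len(nrow(rec))) {
    reg <- if (rec$region[r] == "hemisphere")
      spec$regions[[1]] else spec$regions[[2]]
    dev <- acos(min(1, abs(sum(c(rec$ax[r], rec$ay[r], rec$az[r]) *
                                 reg$preferred_axis)))) * 180 / pi
    expect_lte(dev, max(reg$spread_deg) + 1e-6)
  }
})

test_that("purkinje centroids sit on the granular-molecular interface", {
  spec <- small_phantom_spec(n_plaque = 0L, n_purkinje = 8L, seed = 2L)
  ph <- generate_phantom(spec)
  rec <- ph$truth$records
  h <- spec$voxel_size_um
  gb <- sum(spec$layer_model$thickness_um) / h
  for (r in seq_len(nrow(rec))) {
    disp <- (spec$fold_amplitude_um / h) *
      sin(2 * pi * rec$cy_um[r] / spec$fold_period_um)
    expected_cx <- (gb + disp - 0.5) * h
    expect_lt(abs(rec$cx_um[r] - expected_cx), rec$a_um[r])
  }
})

test_that("object placement reports the failing class when space runs out", {
  # far more somata than the interface can hold
  spec <- small_phantom_spec(grid = c(160L, 64L, 48L), n_plaque = 0L,
                             n_purkinje = 200L, seed = 1L)
  expect_error(generate_phantom(spec), "purkinje")
})

test_that("MIP projects the slab maximum with the floor slice rule", {
  h <- 1.625
  vox <- array(2, c(8, 9, 30))
  vol <- cp_volume(vox, h)
  # constant volume projects to a constant image
  expect_true(all(render_mip(vol, "coronal", thickness_um = 25) == 2))
  # a single bright voxel appears at its in-plane coordinates only
  vox[3, 7, 5] <- 10
  vol <- cp_volume(vox, h)
  img <- render_mip(vol, "coronal", thickness_um = 25)
  expect_equal(dim(img), c(8, 9))
  expect_equal(img[3, 7], 10)
  expect_equal(sum(img == 10), 1)
  # 25 um at 1.625 um voxels covers floor(25/1.625) = 15 slices: a bright
  # voxel on slice 16 is outside a slab starting at the origin
  vox2 <- array(0, c(4, 4, 30))
  vox2[2, 2, 16] <- 5
  img2 <- render_mip(cp_volume(vox2, h), "coronal", thickness_um = 25)
  expect_equal(max(img2), 0)
  img3 <- render_mip(cp_volume(vox2, h), "coronal", thickness_um = 25,
                     start_um = 1.7)  # slab shifted by one slice: 2..16
  expect_equal(max(img3), 5)
  # slab outside the volume errors
  expect_error(render_mip(vol, "coronal", thickness_um = 25,
                          start_um = 40 * h), "bounds")
  expect_error(render_mip(vol, "coronal", thickness_um = 0.5), "voxel")
})

test_that("MIP dominates every constituent slice element-wise", {
  set.seed(4)
  vol <- cp_volume(array(rnorm(16 * 12 * 20), c(16, 12, 20)), 1.625)
  img <- render_mip(vol, "sagittal", thickness_um = 10, start_um = 3)
  first <- floor(3 / 1.625) + 1
  for (j in first:(first + floor(10 / 1.625) - 1))
    expect_true(all(img >= vol$voxels[, j, ] - 1e-12))
})
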