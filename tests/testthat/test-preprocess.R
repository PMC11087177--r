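test_that("slab extraction contains every mask slice and is centred", {
  d <- c(10, 10, 60)
  ct <- rg_volume(array(rnorm(prod(d)), d), c(2, 2, 2))
  m <- array(0L, d)
  m[4:6, 4:6, 10:30] <- 1L
  cfg <- preprocess_config(slab_slices = 48, target_shape = c(16, 16, 48))
  r <- extract_slab(ct, rg_mask(m, c(2, 2, 2)), cfg)
  expect_equal(diff(r$slab) + 1L, 48L)
  expect_true(r$slab[1] <= 10 && r$slab[2] >= 30)
  expect_equal(dim(r$ct$data)[3], 48L)
  # mask spanning exactly the slab width is returned verbatim
  m2 <- array(0L, d)
  m2[4, 4, 7:54] <- 1L
  r2 <- extract_slab(ct, rg_mask(m2, c(2, 2, 2)), cfg)
  expect_equal(r2$slab, c(7L, 54L))
})

test_that("slab extraction rejects impossible requests", {
  cfg <- preprocess_config(slab_slices = 48, target_shape = c(16, 16, 48))
  d <- c(8, 8, 40)
  ct <- rg_volume(array(0, d))
  m <- array(0L, d)
  m[4, 4, 20] <- 1L
  expect_error(extract_slab(ct, rg_mask(m), cfg), "40 axial slices")
  d2 <- c(8, 8, 60)
  ct2 <- rg_volume(array(0, d2))
  m2 <- array(0L, d2)
  m2[4, 4, 5:58] <- 1L
  expect_error(extract_slab(ct2, rg_mask(m2), cfg), "cannot be contained")
})

test_that("body mask recovers the analytic body within a one-voxel
           shell", {
  p <- still_phantom()
  case <- generate_case(p, seed = 1)
  cfg <- preprocess_config(slab_slices = vol_dims(case$ct1)[3],
                           target_shape = c(16, 16,
                                            vol_dims(case$ct1)[3]))
  bm <- body_mask(case$ct1, cfg)
  analytic <- array(as.integer(case$ct1$data > -500), vol_dims(case$ct1))
  dis <- bm$data != analytic
  d <- vol_dims(case$ct1)
  surf <- rgmcmp:::surface_voxels(analytic) |
    rgmcmp:::surface_voxels(1L - analytic)
  shell <- array(rgmcmp:::cpp_edt_sq(as.integer(surf), as.integer(d),
                                     c(1, 1, 1)), d) <= 3 + 1e-9
  expect_true(all(!dis | shell))
})

test_that("body mask handles degenerate thresholds", {
  cfg <- preprocess_config()
  air <- rg_volume(array(-1000, c(8, 8, 4)))
  expect_error(body_mask(air, cfg), "threshold")
  lo <- preprocess_config(body_threshold_hu = -2000)
  expect_true(all(body_mask(air, lo)$data == 1L))
})

test_that("union crop covers both bodies", {
  p <- still_phantom()
  case <- generate_case(p, seed = 2)
  cfg <- preprocess_config(slab_slices = vol_dims(case$ct1)[3],
                           target_shape = c(16, 16,
                                            vol_dims(case$ct1)[3]))
  # identical volumes: the box equals the single-body bounding box
  r <- crop_to_union(case$ct1, case$ct1, masks = list(case$ctv1),
                     cfg = cfg)
  bm <- body_mask(case$ct1, cfg)$data
  expect_equal(r$box$xr, range(which(apply(bm, 1, any))))
  expect_equal(r$box$yr, range(which(apply(bm, 2, any))))
  # a laterally shifted copy widens the box to contain both bodies
  shifted <- propagate(case$ct1, rigid_transform(translation_mm =
                                                   c(-14, 0, 0)))
  r2 <- crop_to_union(case$ct1, shifted, cfg = cfg)
  expect_lte(r2$box$xr[1], r$box$xr[1])
  expect_gt(diff(r2$box$xr), diff(r$box$xr))
  # axial extent untouched
  expect_equal(dim(r$ct2$data)[3], vol_dims(case$ct1)[3])
})

test_that("resampling preserves shape contracts and mask volume", {
  cfg <- preprocess_config(slab_slices = 24,
                           target_shape = c(20, 20, 24))
  d <- c(40, 40, 48)
  cube <- array(0L, d)
  cube[11:30, 11:30, 11:30] <- 1L
  vol <- rg_volume(array(rnorm(prod(d)), d), c(1, 1, 1))
  r <- resample_to_grid(vol, rg_mask(cube, c(1, 1, 1)), cfg)
  expect_equal(dim(r$vol$data), c(20L, 20L, 24L))
  expect_true(all(r$mask$data %in% c(0L, 1L)))
  expect_gte(min(r$vol$data), min(vol$data))
  expect_lte(max(r$vol$data), max(vol$data))
  # physical mask volume preserved within 10% under 2x downsampling
  vox_in <- prod(c(1, 1, 1))
  vox_out <- prod(r$mask$spacing)
  expect_lt(abs(sum(r$mask$data) * vox_out - sum(cube) * vox_in) /
              (sum(cube) * vox_in), 0.1)
  # identity resampling is a no-op up to floating point
  cfg_id <- preprocess_config(slab_slices = 48,
                              target_shape = c(40, 40, 48))
  r_id <- resample_to_grid(vol, rg_mask(cube, c(1, 1, 1)), cfg_id)
  expect_equal(r_id$vol$data, vol$data, tolerance = 1e-9)
  expect_identical(r_id$mask$data, cube)
})

test_that("HU normalization matches its closed forms and is idempotent", {
  cfg <- preprocess_config()
  v <- rg_volume(array(c(-1500, -1000, 250, 1500, 2000), c(5, 1, 1)))
  n <- normalize_hu(v, cfg)
  expect_equal(as.numeric(n$data), c(0, 0, 0.5, 1, 1))
  expect_equal(normalize_hu(n, cfg)$data, n$data)
})

test_that("the preprocessing chain keeps masks binary throughout", {
  case <- generate_case(tiny_phantom(), seed = 3)
  cfg <- preprocess_config(slab_slices = 16, target_shape = c(24, 24, 16))
  slab <- extract_slab(case$ct2, case$ctv2, cfg)
  expect_true(all(slab$mask$data %in% c(0L, 1L)))
  cr <- crop_to_union(slab$ct, slab$ct, masks = list(slab$mask),
                      cfg = cfg)
  expect_true(all(cr$masks[[1]]$data %in% c(0L, 1L)))
  rs <- resample_to_grid(cr$ct2, cr$masks[[1]], cfg)
  expect_true(all(rs$mask$data %in% c(0L, 1L)))
})
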