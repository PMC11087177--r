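reg_cfg_fast <- registration_config(max_iterations = 150)

test_that("propagate honours interpolation contracts", {
  case <- generate_case(still_phantom(), seed = 1)
  ident <- rigid_transform()
  expect_equal(propagate(case$ct1, ident)$data, case$ct1$data,
               tolerance = 1e-10)
  out <- propagate(case$ctv1, ident)
  expect_identical(out$data, case$ctv1$data)
  expect_true(all(out$data %in% c(0L, 1L)))
})

test_that("integer-voxel translation of a mask equals the index-shift
           oracle", {
  case <- generate_case(still_phantom(), seed = 2)
  m <- case$ctv1
  sp <- m$spacing
  t <- rigid_transform(translation_mm = c(2 * sp[1], -sp[2], 0))
  got <- propagate(m, t)$data
  # oracle: out(i) = in(i + shift), zero outside
  d <- vol_dims(m)
  want <- array(0L, d)
  want[1:(d[1] - 2), 2:d[2], ] <- m$data[3:d[1], 1:(d[2] - 1), ]
  expect_identical(got, want)
})

test_that("rigid registration recovers the identity", {
  case <- generate_case(still_phantom(), seed = 3)
  t <- register_rigid(case$ct2, case$ct2, reg_cfg_fast)
  expect_lt(max(abs(t$translation_mm)), 0.1 * min(case$ct2$spacing))
  expect_lt(max(abs(t$rotation_deg)), 0.1)
})

test_that("rigid registration recovers a known 4 mm translation", {
  # default grid and spacing: the recovery contract is stated at the
  # working resolution, not the miniature test grid
  p <- still_phantom(grid_shape = c(64, 64, 48),
                     spacing_mm = c(2.5, 2.5, 2.5),
                     target_radii_mm = c(18, 14, 18), ctv_margin_mm = 10,
                     rigid_offset_mm = c(4, 0, 0))
  case <- generate_case(p, seed = 4)
  t <- register_rigid(case$ct2, case$ct1, reg_cfg_fast)
  expect_lt(max(abs(t$translation_mm - c(4, 0, 0))), 0.5)
})

test_that("rigid registration recovers a known 5 degree rotation", {
  p <- still_phantom(grid_shape = c(64, 64, 48),
                     spacing_mm = c(2.5, 2.5, 2.5),
                     target_radii_mm = c(18, 14, 18), ctv_margin_mm = 10,
                     rigid_rotation_deg = c(0, 0, 5))
  case <- generate_case(p, seed = 5)
  t <- register_rigid(case$ct2, case$ct1, reg_cfg_fast)
  expect_lt(abs(t$rotation_deg[3] - 5), 1)
  expect_lt(max(abs(t$rotation_deg[1:2])), 1)
})

test_that("degenerate constant images are reported as non-convergent", {
  flat <- rg_volume(array(0, c(16, 16, 8)), c(2, 2, 2))
  expect_error(register_rigid(flat, flat), "constant")
  expect_error(register_bspline(flat, flat), "constant")
})

test_that("B-spline registration of identical images stays near zero
           displacement", {
  case <- generate_case(still_phantom(), seed = 6)
  t <- register_bspline(case$ct2, case$ct2, reg_cfg_fast)
  mag <- sqrt(t$dvf[, , , 1]^2 + t$dvf[, , , 2]^2 + t$dvf[, , , 3]^2)
  expect_lt(mean(mag), 0.5)
})

test_that("transform metadata echoes the pyramid and control-grid
           configuration", {
  case <- generate_case(still_phantom(), seed = 6)
  t <- register_bspline(case$ct2, case$ct2, reg_cfg_fast)
  expect_equal(t$meta$pyramid_levels, 4)
  expect_equal(t$meta$grid_spacing_voxels, 16)
  expect_true(all(is.finite(t$dvf)))
})

test_that("deformable propagation beats rigid propagation on a warped
           phantom", {
  case <- generate_case(phantom_params(target_scale2 = 1,
                                       target_fade2 = 1), seed = 7)
  tr <- register_rigid(case$ct2, case$ct1, reg_cfg_fast)
  td <- register_bspline(case$ct2, case$ct1, reg_cfg_fast,
                         init_rigid = tr)
  dsc_rb <- dsc(propagate(case$ctv1, tr, grid_of(case$ct2)), case$ctv2)
  dsc_dir <- dsc(propagate(case$ctv1, td, grid_of(case$ct2)), case$ctv2)
  expect_gt(dsc_dir, dsc_rb)
})

test_that("registration leaves the fixed image untouched and reruns are
           bit-identical", {
  case <- generate_case(still_phantom(rigid_offset_mm = c(3, 0, 0)),
                        seed = 8)
  fixed_before <- case$ct2$data
  t1 <- register_rigid(case$ct2, case$ct1, reg_cfg_fast)
  t2 <- register_rigid(case$ct2, case$ct1, reg_cfg_fast)
  expect_identical(case$ct2$data, fixed_before)
  expect_identical(t1, t2)
})
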