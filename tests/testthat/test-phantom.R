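test_that("analytic ALPS of the phantom follows the assigned diagonals", {
  iso <- diag(rep(1e-3, 3))
  spec_iso <- small_phantom_spec(tensors = list(projection_fiber = iso,
                                               association_fiber = iso))
  ph <- build_alps_phantom(spec_iso)
  expect_equal(unname(ph$truth$alps_analytic), c(1, 1))

  spec <- small_phantom_spec(tensors = list(
    projection_fiber = diag(c(1.2e-3, 0.8e-3, 1.7e-3)),
    association_fiber = diag(c(1.1e-3, 1.7e-3, 0.7e-3))))
  ph2 <- build_alps_phantom(spec)
  expect_equal(unname(ph2$truth$alps_analytic),
               rep((1.2 + 1.1) / (0.8 + 0.7), 2), tolerance = 1e-12)
})

test_that("noiseless phantom signals equal the per-voxel tensor prediction", {
  spec <- small_phantom_spec()
  ph <- build_alps_phantom(spec)
  lab <- ph$truth$region_labels
  for (vox in list(c(2, 2, 2), c(24, 24, 8), ph$truth$roi_centers[1, c("i", "j", "k")])) {
    vox <- as.integer(vox)
    nm <- ph$truth$level_names[lab[vox[1], vox[2], vox[3]]]
    expect_equal(ph$dwi$data[vox[1], vox[2], vox[3], ],
                 tensor_signal(spec$tensors[[nm]], spec$scheme, spec$S0),
                 tolerance = 1e-12)
  }
})

test_that("truth ROI centers lie inside their labelled fiber regions", {
  ph <- build_alps_phantom(small_phantom_spec())
  tr <- ph$truth$roi_centers
  lab_at <- ph$truth$level_names[
    ph$truth$region_labels[cbind(tr$i, tr$j, tr$k)]]
  want <- paste0(ifelse(tr$fiber_class == "projection",
                        "projection_fiber_", "association_fiber_"),
                 ifelse(tr$hemisphere == "left", "L", "R"))
  expect_identical(lab_at, want)
})

test_that("phantom build is bit-identical under a fixed seed", {
  spec <- small_phantom_spec(noise_sigma = 10, seed = 99)
  a <- build_alps_phantom(spec)
  b <- build_alps_phantom(spec)
  expect_identical(a$dwi$data, b$dwi$data)
})

test_that("mirroring the fiber tensors swaps the hemispheric indices", {
  tL_p <- diag(c(1.2e-3, 0.7e-3, 1.7e-3)); tR_p <- diag(c(1.0e-3, 0.6e-3, 1.5e-3))
  tL_a <- diag(c(1.1e-3, 1.6e-3, 0.8e-3)); tR_a <- diag(c(0.9e-3, 1.5e-3, 0.7e-3))
  spec <- small_phantom_spec(tensors = list(
    projection_fiber_L = tL_p, projection_fiber_R = tR_p,
    association_fiber_L = tL_a, association_fiber_R = tR_a))
  mirrored <- small_phantom_spec(tensors = list(
    projection_fiber_L = tR_p, projection_fiber_R = tL_p,
    association_fiber_L = tR_a, association_fiber_R = tL_a))
  r1 <- pipeline_alps(spec)$result
  r2 <- pipeline_alps(mirrored)$result
  expect_equal(r1$left, r2$right, tolerance = 1e-12)
  expect_equal(r1$right, r2$left, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(r1$left, r1$right)))
})

test_that("Rician noise has the expected magnitude statistics", {
  sch <- make_scheme(6, 1000, 1)
  dwi <- structure(list(data = array(0, dim = c(40, 40, 10, 7)),
                        affine = diag(4), voxdim = c(1, 1, 1), scheme = sch),
                   class = "alps_dwi")
  expect_identical(add_rician_noise(dwi, 0), dwi)
  expect_error(add_rician_noise(dwi, -1), ">= 0")
  # zero signal + Rician noise is Rayleigh with mean sigma * sqrt(pi/2)
  noisy <- add_rician_noise(dwi, sigma = 5, seed = 1)
  expect_equal(mean(noisy$data), 5 * sqrt(pi / 2), tolerance = 0.01)
  noisy2 <- add_rician_noise(dwi, sigma = 5, seed = 1)
  expect_identical(noisy$data, noisy2$data)
})

test_that("lesion masks are nested, binary and volumetrically faithful", {
  les <- list(hematoma = list(center = c(24, 24, 8), semiaxes = c(4, 5, 3)),
              edema = list(center = c(24, 24, 8), semiaxes = c(8, 9, 5)))
  spec <- small_phantom_spec(lesion = les)
  m <- simulate_lesion_masks(spec)
  expect_true(all(m$hematoma %in% c(0, 1)))
  expect_true(all(m$total_lesion[m$hematoma == 1] == 1))

  # zero-semiaxis hematoma: empty mask, edema equals the whole lesion
  spec0 <- small_phantom_spec(lesion = list(
    hematoma = list(center = c(24, 24, 8), semiaxes = c(0, 0, 0)),
    edema = les$edema))
  m0 <- simulate_lesion_masks(spec0)
  expect_equal(sum(m0$hematoma), 0)
  expect_equal(sum(m0$total_lesion), sum(m$total_lesion))

  expect_error(simulate_lesion_masks(small_phantom_spec(lesion = list(
    hematoma = list(center = c(10, 10, 8), semiaxes = c(3, 3, 2)),
    edema = list(center = c(38, 38, 8), semiaxes = c(3, 3, 2))))),
    "not contained")

  # voxel count vs continuous ellipsoid volume at 1 mm isotropic
  spec1 <- phantom_spec(grid = c(60, 60, 60), voxdim = c(1, 1, 1),
                        lesion = list(
                          hematoma = list(center = c(30, 30, 30),
                                          semiaxes = c(8, 10, 12)),
                          edema = list(center = c(30, 30, 30),
                                       semiaxes = c(14, 16, 18))))
  m1 <- simulate_lesion_masks(spec1)
  vol_analytic <- 4 / 3 * pi * 8 * 10 * 12
  expect_lt(abs(sum(m1$hematoma) - vol_analytic) / vol_analytic, 0.05)
})

test_that("unknown region tensors are rejected", {
  expect_error(small_phantom_spec(tensors = list(cortex = diag(rep(1e-3, 3)))),
               "unknown region label")
  bad <- diag(c(1e-3, -1e-3, 1e-3))
  expect_error(small_phantom_spec(tensors = list(edema = bad)),
               "positive definite")
})
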