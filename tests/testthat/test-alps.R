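make_fit <- function(t6_by_voxel, grid) {
  structure(
    list(tensors = array(t(t6_by_voxel), c(grid, 6)),
         s0 = array(1000, grid), mask = array(TRUE, grid),
         voxel_size = c(2, 2, 2)),
    class = "dti_fit"
  )
}

test_that("ROI means are plain arithmetic over the ROI voxels", {
  grid <- c(4, 4, 2)
  t6 <- matrix(c(1.2e-3, 0.8e-3, 0.9e-3, 0, 0, 0), 6, prod(grid))
  fit <- make_fit(t6, grid)
  m <- roi_mean_diffusivities(fit, roi_spec("projection", c(0, 0, 0)))
  expect_equal(m$dxx, 1.2e-3)
  expect_equal(m$n_voxels, 4)
  # distinct values average: Dxx {1,2,3,4}e-3 -> 2.5e-3
  fit2 <- make_fit(t6, grid)
  fit2$tensors[1:2, 1:2, 1, 1] <- c(1, 2, 3, 4) * 1e-3
  m2 <- roi_mean_diffusivities(fit2, roi_spec("projection", c(0, 0, 0)))
  expect_equal(m2$dxx, 2.5e-3)
})

test_that("out-of-grid and unmasked ROIs are rejected", {
  grid <- c(4, 4, 2)
  fit <- make_fit(matrix(1e-3, 6, prod(grid)), grid)
  expect_error(roi_mean_diffusivities(fit, roi_spec("projection", c(3, 0, 0))),
               "outside")
  fit$mask[1, 1, 1] <- FALSE
  expect_error(roi_mean_diffusivities(fit, roi_spec("projection", c(0, 0, 0))),
               "mask")
})

test_that("the 2x2x1 footprint is enforced unless overridden", {
  expect_error(roi_spec("projection", c(0, 0, 0), c(3, 3, 1)), "2 x 2 x 1")
  expect_silent(roi_spec("projection", c(0, 0, 0), c(3, 3, 1),
                         allow_resize = TRUE))
  expect_silent(roi_spec("tumor", c(0, 0, 0), c(5, 5, 3)))
})

test_that("the ALPS index follows its defining ratio", {
  # all four equal -> exactly 1
  expect_equal(compute_alps_index(list(dxx = 1e-3, dyy = 1e-3),
                                  list(dxx = 1e-3, dzz = 1e-3))$index, 1)
  # worked ratio: (1.2 + 1.0)/2 over (0.8 + 0.7)/2
  m <- compute_alps_index(list(dxx = 1.2e-3, dyy = 0.8e-3),
                          list(dxx = 1.0e-3, dzz = 0.7e-3))
  expect_equal(m$index, 1.1e-3 / 0.75e-3, tolerance = 1e-12)
  expect_equal(round(m$index, 4), 1.4667)
  expect_error(compute_alps_index(list(dxx = 1e-3, dyy = -1e-3),
                                  list(dxx = 1e-3, dzz = 0.5e-3)),
               "non-positive denominator")
  expect_error(compute_alps_index(list(dxx = 1e-3, dyy = NA),
                                  list(dxx = 1e-3, dzz = 1e-3)),
               "finite")
})

test_that("the index is scale invariant and swaps to its reciprocal", {
  withr::local_seed(8)
  for (i in 1:20) {
    v <- runif(4, 0.3e-3, 2e-3)
    base <- compute_alps_index(list(dxx = v[1], dyy = v[3]),
                               list(dxx = v[2], dzz = v[4]))$index
    c_ <- runif(1, 0.1, 10)
    scaled <- compute_alps_index(list(dxx = c_ * v[1], dyy = c_ * v[3]),
                                 list(dxx = c_ * v[2], dzz = c_ * v[4]))$index
    expect_equal(scaled, base, tolerance = 1e-12)
    swapped <- compute_alps_index(list(dxx = v[3], dyy = v[1]),
                                  list(dxx = v[4], dzz = v[2]))$index
    expect_equal(swapped, 1 / base, tolerance = 1e-12)
  }
})

test_that("tumor ADC rasterization: uniform fields, sub-voxel areas, truth recovery", {
  adc <- scalar_map(array(1.6e-3, c(10, 10, 3)), c(2, 2, 2), "ADC")
  # uniform field: any area returns the constant
  expect_equal(tumor_roi_adc(adc, c(10, 10, 3), area_mm2 = 5.3), 1.6e-3)
  expect_equal(tumor_roi_adc(adc, c(10, 10, 3), area_mm2 = 60), 1.6e-3)
  # 5.3 mm^2 circle (r = 1.30 mm) at a voxel center covers only that voxel
  varied <- adc
  varied$data[, , 2] <- seq_len(100) * 1e-5
  ctr <- c(4 * 2 + 1, 6 * 2 + 1, 3)      # center of 0-based voxel (4, 6, 1)
  expect_equal(tumor_roi_adc(varied, ctr, area_mm2 = 5.3),
               varied$data[5, 7, 2])
  expect_error(tumor_roi_adc(adc, c(25, 10, 3)), "outside")
  # full pipeline: phantom tumor compartment recovered within 1% noiseless
  gt <- default_gradient_table()
  truth <- build_phantom_tensors(default_phantom_spec())
  vol <- simulate_signal(truth, gt)
  amap <- trace_adc_map(vol, gt)
  got <- tumor_roi_adc(amap, c(32, 32, 5), area_mm2 = 5.3)  # inside tumor box
  expect_equal(got, 1.6e-3, tolerance = 1e-2)
})

test_that("suggest_roi lands inside the designed fiber boxes and gates on FA", {
  gt <- default_gradient_table()
  truth <- build_phantom_tensors(default_phantom_spec())
  fit <- fit_dti(simulate_signal(truth, gt), gt)
  fa <- fa_map(fit)
  sug <- suggest_roi(fa, fit, slice_index = 2)
  in_box <- function(roi, box) {
    all(roi$start_voxel[1:2] >= box$start[1:2]) &&
      all(roi$start_voxel[1:2] + roi$size_voxels[1:2] <=
            box$start[1:2] + box$size[1:2])
  }
  expect_true(in_box(sug$projection, truth$spec$regions$projection_area))
  expect_true(in_box(sug$association, truth$spec$regions$association_area))
  # all-zero FA: no candidate window
  flat_fa <- scalar_map(array(0, dim(fa$data)), fa$voxel_size, "FA")
  expect_error(suggest_roi(flat_fa, fit, 2), "no candidate window")
})

test_that("ROI sidecars round-trip and drive the full phantom pipeline", {
  rois <- read_roi_sidecar(
    system.file("extdata", "rois_phantom.json", package = "alpsdti")
  )
  expect_length(rois, 2)
  expect_equal(rois[[1]]$kind, "projection")
  f <- withr::local_tempfile(fileext = ".json")
  write_roi_sidecar(rois, f)
  again <- read_roi_sidecar(f)
  expect_equal(again[[1]]$start_voxel, rois[[1]]$start_voxel)
  # the sidecar ROIs reproduce the designed index on a noiseless phantom
  gt <- default_gradient_table()
  truth <- build_phantom_tensors(default_phantom_spec())
  fit <- fit_dti(simulate_signal(truth, gt), gt)
  m <- alps_from_fit(fit, rois$projection_left, rois$association_left)
  expect_equal(m$index, truth$designed_alps, tolerance = 1e-6)
})
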