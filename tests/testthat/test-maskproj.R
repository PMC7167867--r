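test_that("large-vessel detection keeps wide vessels and drops capillaries", {
  empty <- binary_vessel_map(matrix(FALSE, 80, 80), 10, plexus = "SCP")
  expect_false(any(detect_large_vessels(empty)$mask))
  # one 10-px-wide vessel and separate 2-px capillaries
  v <- matrix(FALSE, 120, 120)
  v[56:65, 10:110] <- TRUE                 # wide vessel
  v[20:21, 10:110] <- TRUE                 # capillary band
  v[100, 10:110] <- TRUE                   # 1-px capillary
  map <- binary_vessel_map(v, 10, plexus = "SCP")
  ex0 <- detect_large_vessels(map, min_calibre_px = 5, dilation_px = 0)
  wide <- matrix(FALSE, 120, 120)
  wide[56:65, 10:110] <- TRUE
  expect_gte(sum(ex0$mask & wide) / sum(wide), 0.95)
  expect_identical(sum(ex0$mask & v & !wide), 0L)
  # dilation only grows the mask
  ex2 <- detect_large_vessels(map, min_calibre_px = 5, dilation_px = 2)
  expect_true(all(ex0$mask <= ex2$mask))
  expect_error(detect_large_vessels(map, min_calibre_px = 0), ">= 1")
})

test_that("exclusion is an OR on the excluded grid and metric-time only", {
  set.seed(8)
  v <- matrix(runif(400) < 0.4, 20, 20)
  pre <- matrix(runif(400) < 0.2, 20, 20)
  map <- binary_vessel_map(v, 10, excluded = pre)
  mask <- matrix(runif(400) < 0.3, 20, 20)
  out <- apply_exclusion(map, mask)
  expect_identical(out$excluded, pre | mask)
  expect_identical(out$vessel, v)
  ident <- apply_exclusion(map, matrix(FALSE, 20, 20))
  expect_identical(ident$excluded, pre)
  expect_error(apply_exclusion(map, matrix(TRUE, 5, 5)), "shape")
})

test_that("full-field exclusion gives an empty metric denominator", {
  roi <- build_roi_set(20, c(240, 240))
  map <- binary_vessel_map(matrix(TRUE, 240, 240), 20)
  excl <- apply_exclusion(map, matrix(TRUE, 240, 240))
  expect_error(perfusion_density(excl, roi, "tight_central"), "empty denominator")
})

test_that("excluding painted shadows reduces the PD error of a deep slab", {
  ppm <- 512 / 12
  p <- synth_params(seed = 23, target_vld = 12, calibre_mean_mm = 0.035,
                    calibre_sd_mm = 0.004, large_vessel_count = 4,
                    noise_sigma = 0)
  net <- generate_vessel_tree(p)
  ras <- rasterize_network(net, ppm, plexus = "DCP")
  lv <- generate_large_vessels(p)
  lvr <- rasterize_network(lv, ppm)
  img <- ras$image$pixels
  img[lvr$truth$vessel] <- round(img[lvr$truth$vessel] * p$shadow_factor)
  dcp <- en_face_image(img, ppm, "DCP")
  map <- binarize_slab(dcp)
  roi <- build_roi_set(ppm, dim(img))
  truth_pd <- truth_pd_by_region(ras$truth, roi)
  masked <- apply_exclusion(map, lvr$truth$vessel)
  err_raw <- err_masked <- 0
  for (rg in roi_regions()) {
    err_raw <- err_raw + abs(perfusion_density(map, roi, rg) - truth_pd[[rg]])
    err_masked <- err_masked + abs(perfusion_density(masked, roi, rg) - truth_pd[[rg]])
  }
  expect_lt(err_masked, err_raw)
  # exclusion masks stay a minority of the field on plausible inputs
  expect_lt(mean(lvr$truth$vessel), 0.5)
})
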