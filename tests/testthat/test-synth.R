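test_that("generator handles empty and invalid parameter sets", {
  p0 <- synth_params(n_roots = 0)
  net <- generate_vessel_tree(p0)
  expect_length(net$segments, 0)
  expect_equal(network_length_mm(net), 0)
  expect_error(synth_params(target_vld = NA), "finite")
  expect_error(synth_params(noise_sigma = -1), ">= 0")
  expect_error(synth_params(vessel_level = 40, background_level = 50), "exceed")
})

test_that("tree growth is reproducible and hits its length target", {
  p <- synth_params(seed = 41, target_vld = 8, noise_sigma = 0)
  n1 <- generate_vessel_tree(p)
  n2 <- generate_vessel_tree(p)
  expect_identical(n1$segments, n2$segments)
  expect_identical(n1$calibre_mm, n2$calibre_mm)
  # all vertices inside the field
  expect_true(all(vapply(n1$segments, function(s) min(s) >= 0 && max(s) <= 12,
                         logical(1))))
  # realized density near target in the central 3-mm disc, by exact clipping
  p10 <- synth_params(seed = 42, target_vld = 20, noise_sigma = 0)
  net <- generate_vessel_tree(p10)
  len <- oracle_length_in_disc(net, c(6, 6), 1.5)
  vld <- len / (pi * 1.5^2)
  expect_lt(abs(vld - 20) / 20, 0.10)
})

test_that("rasterization strokes polylines at their calibre", {
  net0 <- vessel_network(list(), numeric(0), 12)
  ras0 <- rasterize_network(net0, 20)
  expect_false(any(ras0$truth$vessel))
  expect_identical(unique(as.vector(ras0$image$pixels)), 50L)
  # one straight 1-mm vessel of calibre 3 px at 100 px/mm
  net <- vessel_network(list(rbind(c(5.505, 6.005), c(6.505, 6.005))), 3 / 100, 12)
  ras <- rasterize_network(net, 100)
  expect_lt(abs(sum(ras$truth$vessel) - 300) / 300, 0.10)
  # noise-free images are exactly two-level
  p <- synth_params(seed = 2, target_vld = 5, noise_sigma = 0)
  ras2 <- rasterize_network(generate_vessel_tree(p), 512 / 12)
  expect_identical(sort(unique(as.vector(ras2$image$pixels))), c(50L, 200L))
  expect_error(rasterize_network(net, 100, image_shape = c(500, 500)),
               "inconsistent")
})

test_that("speckle is seeded, clipped, identity at zero, and mean-preserving", {
  img <- as_img(matrix(c(100L, 150L), 64, 64), ppm = 10)
  expect_identical(add_speckle(img, 0), img)
  a <- add_speckle(img, 10, seed = 3)
  b <- add_speckle(img, 10, seed = 3)
  expect_identical(a$pixels, b$pixels)
  expect_true(min(a$pixels) >= 0 && max(a$pixels) <= 255)
  # mean preserved within 3 standard errors (no clipping at these levels)
  se <- 10 / 64
  expect_lt(abs(mean(a$pixels) - mean(img$pixels)), 3 * se)
})

test_that("calibre scales perfusion but not vessel length density", {
  ppm <- 512 / 12
  p1 <- synth_params(seed = 55, target_vld = 10, calibre_mean_mm = 0.012,
                     calibre_sd_mm = 0, noise_sigma = 0)
  p2 <- synth_params(seed = 55, target_vld = 10, calibre_mean_mm = 0.024,
                     calibre_sd_mm = 0, noise_sigma = 0)
  n1 <- generate_vessel_tree(p1)
  n2 <- generate_vessel_tree(p2)
  expect_identical(n1$segments, n2$segments)  # geometry unchanged by calibre
  r1 <- rasterize_network(n1, ppm)
  r2 <- rasterize_network(n2, ppm)
  roi <- build_roi_set(ppm, dim(r1$truth$vessel))
  pd1 <- truth_pd_by_region(r1$truth, roi)
  pd2 <- truth_pd_by_region(r2$truth, roi)
  expect_true(all(pd2 > pd1))
  v1 <- sapply(roi_regions(), function(rg)
    vessel_length_density(skeletonize(r1$truth), roi, rg))
  v2 <- sapply(roi_regions(), function(rg)
    vessel_length_density(skeletonize(r2$truth), roi, rg))
  expect_true(all(abs(v2 / v1 - 1) < 0.05))
})

test_that("metrics-mode cohorts respect effects, overrides and degenerate groups", {
  # zero-effect cohorts: group means equal in expectation, nominal rejection
  B <- 200
  rej <- 0
  diffs <- numeric(B)
  for (b in 1:B) {
    sp <- cohort_spec(n_controls = 10, n_cases = 10, vld_effect = 0,
                      pd_effect = 0, seed = 7000 + b)
    tr <- generate_cohort(sp, render = "metrics")$truth
    x <- tr$vld[tr$plexus == "CC" & tr$region == "superior" & tr$group == "control"]
    y <- tr$vld[tr$plexus == "CC" & tr$region == "superior" & tr$group == "case"]
    res <- group_difference(x, y)
    diffs[b] <- res$mean_difference
    rej <- rej + (res$p_value < 0.05)
  }
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(B))  # unbiased at zero effect
  expect_lt(abs(rej / B - 0.05), 0.045)                 # near-nominal size
  # per-region overrides lower only the named region, cases only
  sp <- cohort_spec(n_controls = 200, n_cases = 200, vld_effect = 0,
                    pd_effect = 0, region_effects = c(superior = 3), seed = 9)
  tr <- generate_cohort(sp, render = "metrics")$truth
  cc <- tr[tr$plexus == "CC", ]
  d_sup <- mean(cc$vld[cc$region == "superior" & cc$group == "control"]) -
    mean(cc$vld[cc$region == "superior" & cc$group == "case"])
  d_inf <- mean(cc$vld[cc$region == "inferior" & cc$group == "control"]) -
    mean(cc$vld[cc$region == "inferior" & cc$group == "case"])
  expect_gt(d_sup, 2)
  expect_lt(abs(d_inf), 1)
  # zero cases: generation succeeds, downstream comparison errors
  sp0 <- cohort_spec(n_controls = 4, n_cases = 0, seed = 3)
  tr0 <- generate_cohort(sp0, render = "metrics")$truth
  expect_false("case" %in% tr0$group)
  wide <- cohort_table(tr0)
  expect_error(compare_groups(wide, "CC_superior_vld"), "label")
})

test_that("networks round-trip through the JSON polyline format", {
  p <- synth_params(seed = 6, target_vld = 2, noise_sigma = 0)
  net <- generate_vessel_tree(p)
  path <- tempfile(fileext = ".json")
  write_network_json(net, path)
  back <- read_network_json(path)
  expect_equal(back$segments, lapply(net$segments, unname))
  expect_equal(back$calibre_mm, net$calibre_mm)
})
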