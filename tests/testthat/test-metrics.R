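# a small ROI helper: one 240x240 field at 20 px/mm
roi_small <- build_roi_set(20, c(240, 240))

test_that("perfusion density obeys its counting contract", {
  white <- binary_vessel_map(matrix(TRUE, 240, 240), 20)
  black <- binary_vessel_map(matrix(FALSE, 240, 240), 20)
  expect_equal(perfusion_density(white, roi_small, "tight_central"), 100)
  expect_equal(perfusion_density(black, roi_small, "superior"), 0)
  # excluded pixels leave the denominator: half-masked all-white stays 100
  excl <- matrix(FALSE, 240, 240)
  excl[, 1:120] <- TRUE
  half <- binary_vessel_map(matrix(TRUE, 240, 240), 20, excluded = excl)
  expect_equal(perfusion_density(half, roi_small, "tight_central"), 100)
  all_excl <- binary_vessel_map(matrix(TRUE, 240, 240), 20,
                                excluded = matrix(TRUE, 240, 240))
  expect_error(perfusion_density(all_excl, roi_small, "tight_central"),
               "empty denominator")
})

test_that("perfusion density is monotone under adding vessel pixels", {
  set.seed(31)
  v <- matrix(runif(240^2) < 0.2, 240, 240)
  m1 <- binary_vessel_map(v, 20)
  v2 <- v | matrix(runif(240^2) < 0.1, 240, 240)
  m2 <- binary_vessel_map(v2, 20)
  for (rg in roi_regions()) {
    expect_gte(perfusion_density(m2, roi_small, rg),
               perfusion_density(m1, roi_small, rg))
  }
})

test_that("skeletonization preserves isolated pixels, bars and topology", {
  dot <- matrix(FALSE, 9, 9)
  dot[5, 5] <- TRUE
  expect_identical(skeletonize(binary_vessel_map(dot, 1))$skeleton, dot)
  bar <- matrix(FALSE, 60, 60)
  bar[30:32, 5:54] <- TRUE
  skel <- skeletonize(binary_vessel_map(bar, 1))$skeleton
  expect_true(abs(sum(skel) - 50) <= 2)
  expect_true(all(skel <= bar))
  # connected components preserved on random blobs
  for (s in 1:20) {
    set.seed(500 + s)
    m <- matrix(runif(40^2) < runif(1, 0.3, 0.55), 40, 40)
    sk <- skeletonize(binary_vessel_map(m, 1))$skeleton
    expect_identical(max(octaquant:::cpp_label(sk, 8L)),
                     max(octaquant:::cpp_label(m, 8L)))
  }
})

test_that("skeleton length weights axial and diagonal steps correctly", {
  h <- matrix(FALSE, 210, 210)
  h[100, 50:150] <- TRUE                       # 101 px horizontal run
  skel_h <- skeletonize(binary_vessel_map(h, 100))
  expect_equal(skeleton_length_mm(skel_h), 1.00)
  d <- matrix(FALSE, 210, 210)
  d[cbind(50:150, 50:150)] <- TRUE             # 101 px diagonal run
  skel_d <- skeletonize(binary_vessel_map(d, 100))
  expect_equal(skeleton_length_mm(skel_d), 100 * sqrt(2) / 100, tolerance = 1e-10)
})

test_that("vessel length density divides by included area", {
  ppm <- 20
  v <- matrix(FALSE, 240, 240)
  # 1 mm horizontal centerline through the tight central ring
  v[120, 111:131] <- TRUE
  skel <- skeletonize(binary_vessel_map(v, ppm))
  len <- skeleton_length_mm(skel, roi_small, "tight_central")
  area <- roi_region_areas(roi_small)[["tight_central"]]
  expect_equal(vessel_length_density(skel, roi_small, "tight_central"),
               len / area)
  empty <- skeletonize(binary_vessel_map(matrix(FALSE, 240, 240), ppm))
  expect_equal(vessel_length_density(empty, roi_small, "tight_central"), 0)
})

test_that("metrics under exclusion equal metrics on the restricted sub-image", {
  set.seed(77)
  v <- matrix(runif(240^2) < 0.25, 240, 240)
  excl <- matrix(FALSE, 240, 240)
  excl[60:120, 60:120] <- TRUE
  map <- binary_vessel_map(v, 20, excluded = excl)
  # restricted route: delete masked pixels outright and use no exclusion
  v2 <- v & !excl
  map2 <- binary_vessel_map(v2, 20)
  skel <- skeletonize(map)
  skel2 <- skeletonize(map2)
  for (rg in c("tight_central", "medium_central")) {
    pd1 <- perfusion_density(map, roi_small, rg)
    inc <- roi_small$labels == match(rg, roi_small$regions) & !excl
    expect_equal(pd1, 100 * sum(v2 & inc) / sum(inc))
  }
})

test_that("region_metrics returns the full six-region table", {
  set.seed(5)
  map <- binary_vessel_map(matrix(runif(240^2) < 0.3, 240, 240), 20, plexus = "DCP")
  out <- region_metrics(map, roi_small, eye_id = "e1", group = "control")
  expect_identical(nrow(out), 6L)
  expect_identical(out$region, roi_regions())
  expect_true(all(out$pd >= 0 & out$pd <= 100))
  expect_true(all(out$vld >= 0))
  expect_true(all(out$included_area_mm2 <= roi_analytic_areas() + 0.1))
})
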