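test_that("Huang threshold separates a two-level image and rejects constants", {
  img <- as_img(matrix(c(50, 200), 32, 32))
  t <- huang_threshold(img)
  bin <- threshold_binarize(img, t)
  expect_identical(bin$vessel, img$pixels == 200)
  expect_error(huang_threshold(as_img(matrix(7, 8, 8))), "constant")
})

test_that("Huang threshold matches the per-pixel fuzziness oracle", {
  for (s in 1:5) {
    m <- random_fixture(16, seed = 100 + s)
    expect_identical(huang_threshold(as_img(m)), oracle_huang(m))
  }
})

test_that("raising the Huang threshold never adds vessel pixels", {
  img <- as_img(random_fixture(24, seed = 9))
  t <- huang_threshold(img)
  low <- threshold_binarize(img, t)
  for (dt in c(1, 10, 50)) {
    high <- threshold_binarize(img, t + dt)
    expect_true(all(low$vessel | !high$vessel))
  }
})

test_that("local-median thresholding behaves on flat and point inputs", {
  flat <- as_img(matrix(90, 20, 20))
  expect_false(any(local_median_binarize(flat, 5, offset = 1)$vessel))
  point <- matrix(50, 21, 21)
  point[11, 11] <- 220
  bin <- local_median_binarize(as_img(point), 5)
  expect_identical(which(bin$vessel), which(point == 220))
  expect_error(local_median_binarize(flat, 4), "odd")
})

test_that("local-median thresholding equals the windowed-sort oracle", {
  for (s in 1:5) {
    m <- random_fixture(16, seed = 200 + s)
    got <- local_median_binarize(as_img(m), 5, offset = 3)
    expect_identical(got$vessel, m > oracle_local_median(m, 5) + 3)
  }
})

test_that("Phansalkar follows its threshold formula on degenerate inputs", {
  expect_false(any(phansalkar_binarize(as_img(matrix(0, 16, 16)))$vessel))
  # constant normalized 1.0: local s = 0, threshold = 1 + 2e^-10 - 0.25 < 1,
  # but 1.0 does not strictly exceed... evaluate the formula as implemented
  ones <- phansalkar_binarize(as_img(matrix(255, 16, 16)))
  thr <- 1 * (1 + 2 * exp(-10) - 0.25)
  expect_identical(unique(as.vector(ones$vessel)), 1 > thr)
  expect_error(phansalkar_binarize(as_img(matrix(1, 8, 8)), r = 0), "non-zero")
})

test_that("Phansalkar equals the naive per-window oracle", {
  for (s in 1:5) {
    m <- random_fixture(16, seed = 300 + s)
    got <- phansalkar_binarize(as_img(m), radius_px = 4)
    expect_identical(got$vessel, oracle_phansalkar(m, 4))
  }
})

test_that("Phansalkar is invariant to affine rescaling of the 8-bit range", {
  m <- random_fixture(24, seed = 17, lo = 60, hi = 160, sd = 15)
  m2 <- round((m - min(m)) / diff(range(m)) * 255)
  a <- phansalkar_binarize(as_img(m), radius_px = 6)
  b <- phansalkar_binarize(as_img(m2), radius_px = 6)
  # up to quantization of the rescaled image
  expect_lt(mean(a$vessel != b$vessel), 0.02)
})

test_that("combining binaries is a conjunction", {
  a <- binary_vessel_map(matrix(c(TRUE, FALSE), 10, 10), 10)
  expect_identical(combine_binaries(a, a)$vessel, a$vessel)
  nota <- binary_vessel_map(!a$vessel, 10)
  expect_false(any(combine_binaries(a, nota)$vessel))
  set.seed(4)
  x <- binary_vessel_map(matrix(runif(100) < 0.5, 10, 10), 10)
  y <- binary_vessel_map(matrix(runif(100) < 0.5, 10, 10), 10)
  expect_identical(combine_binaries(x, y)$vessel, x$vessel & y$vessel)
  expect_true(all(combine_binaries(x, y)$vessel <= x$vessel))
  bad <- binary_vessel_map(matrix(TRUE, 5, 5), 10)
  expect_error(combine_binaries(x, bad), "shape")
})

test_that("particle filtering removes only small components", {
  m <- matrix(FALSE, 20, 20)
  m[2:3, 2:3] <- TRUE          # 4 px
  m[10:14, 10] <- TRUE         # 5 px
  map <- binary_vessel_map(m, 10)
  expect_identical(filter_particles(map, 0)$vessel, m)
  expect_false(any(filter_particles(map, 6)$vessel))
  kept <- filter_particles(map, 5)$vessel
  expect_identical(sum(kept), 5L)
  for (s in 1:5) {
    set.seed(400 + s)
    rnd <- binary_vessel_map(matrix(runif(400) < 0.35, 20, 20), 10)
    expect_identical(filter_particles(rnd, 4)$vessel,
                     oracle_filter_particles(rnd$vessel, 4))
  }
})
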