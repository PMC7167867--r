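#' Huang fuzzy-entropy global threshold
#'
#' Finds the gray level minimizing Huang & Wang's measure of fuzziness. For a
#' candidate threshold `t` the image is split into the classes `g <= t` and
#' `g > t` with mean levels `mu0`, `mu1`; each pixel of gray `g` gets the
#' membership `u = 1 / (1 + |g - mu_class| / C)` with `C` the dynamic range,
#' and the fuzziness is the summed Shannon entropy
#' `-u log u - (1 - u) log(1 - u)`. All candidate levels between the image
#' minimum and maximum (exclusive) are searched; ties break toward the lower
#' level. Pixels strictly above the returned level are vessel.
#'
#' @param image an [en_face_image] or intensity matrix in \[0, 255\].
#' @return the threshold level (integer).
#' @export
huang_threshold <- function(image) {
  px <- as_intensity(image)
  h <- tabulate(as.vector(px) + 1L, nbins = 256L)  # counts for levels 0..255
  levels <- 0:255
  gmin <- min(px)
  gmax <- max(px)
  if (gmin == gmax) stop("constant image: Huang threshold undefined")
  C <- gmax - gmin

  csum <- cumsum(h)
  cwsum <- cumsum(h * levels)
  n <- csum[256L]

  entropy <- function(u) {
    # Shannon entropy of a fuzzy membership; 0 log 0 := 0
    e <- numeric(length(u))
    ok <- u > 0 & u < 1
    e[ok] <- -u[ok] * log(u[ok]) - (1 - u[ok]) * log(1 - u[ok])
    e
  }

  cand <- gmin:(gmax - 1L)
  fuzz <- vapply(cand, function(t) {
    i <- t + 1L
    n0 <- csum[i]
    n1 <- n - n0
    mu0 <- cwsum[i] / n0
    mu1 <- (cwsum[256L] - cwsum[i]) / n1
    mu <- ifelse(levels <= t, mu0, mu1)
    u <- 1 / (1 + abs(levels - mu) / C)
    sum(h * entropy(u))
  }, numeric(1))
  cand[which.min(fuzz)]
}

#' Binarize a slab at a global threshold
#'
#' @param image an [en_face_image].
#' @param threshold gray level; pixels strictly above it become vessel.
#' @return a [binary_vessel_map].
#' @export
threshold_binarize <- function(image, threshold) {
  px <- as_intensity(image)
  binary_vessel_map(px > threshold, px_per_mm = image$px_per_mm, plexus = image$plexus)
}

#' Local-median thresholding
#'
#' A pixel is vessel iff its intensity strictly exceeds the median of its
#' square window plus `offset`. Borders use reflective padding.
#'
#' @param image an [en_face_image].
#' @param window_px odd window side length (>= 3).
#' @param offset intensity added to the local median before comparison.
#' @return a [binary_vessel_map].
#' @export
local_median_binarize <- function(image, window_px = 31L, offset = 0) {
  if (window_px < 3 || window_px %% 2 == 0) {
    stop("`window_px` must be an odd integer >= 3")
  }
  px <- as_intensity(image)
  med <- cpp_local_median(px, as.integer(window_px))
  binary_vessel_map(px > med + offset, px_per_mm = image$px_per_mm,
                    plexus = image$plexus)
}

#' Phansalkar local thresholding
#'
#' Designed for low-contrast flow images: intensities are normalized to
#' \[0, 1\] and a pixel is flow iff its value strictly exceeds
#' `m * (1 + p * exp(-q * m) + k * ((s / r) - 1))`, where `m` and `s` are the
#' mean and standard deviation over a disc-shaped window of radius
#' `radius_px` (reflective padding). Defaults follow the common
#' implementation of the method.
#'
#' @param image an [en_face_image].
#' @param radius_px disc window radius in pixels (>= 1).
#' @param k,r,p,q method parameters; `r` is the dynamic range of the
#'   normalized standard deviation and must be non-zero.
#' @return a [binary_vessel_map].
#' @export
phansalkar_binarize <- function(image, radius_px = 15L, k = 0.25, r = 0.5,
                                p = 2, q = 10) {
  if (radius_px < 1) stop("`radius_px` must be >= 1")
  if (r == 0) stop("`r` must be non-zero")
  px <- as_intensity(image)
  norm <- px / 255
  ms <- cpp_local_mean_sd(norm, as.integer(radius_px))
  thr <- ms$mean * (1 + p * exp(-q * ms$mean) + k * ((ms$sd / r) - 1))
  binary_vessel_map(norm > thr, px_per_mm = image$px_per_mm, plexus = image$plexus)
}

#' Combine two binarizations of the same slab
#'
#' Dual-binarized retinal slabs keep only pixels classified as vessel by
#' both methods (logical AND), which suppresses the distinct false positives
#' of the global and local thresholds. Exclusion grids are merged by OR.
#'
#' @param a,b [binary_vessel_map]s sharing a grid.
#' @return a [binary_vessel_map].
#' @export
combine_binaries <- function(a, b) {
  if (!identical(dim(a$vessel), dim(b$vessel))) stop("shape mismatch")
  binary_vessel_map(a$vessel & b$vessel, px_per_mm = a$px_per_mm,
                    excluded = a$excluded | b$excluded, plexus = a$plexus)
}

#' Remove small particles
#'
#' Drops 8-connected components whose pixel area is below `min_area_px`,
#' mirroring an analyze-particles pass with a minimum size.
#'
#' @param map a [binary_vessel_map].
#' @param min_area_px minimum component area in pixels (>= 0) to keep.
#' @return a [binary_vessel_map].
#' @export
filter_particles <- function(map, min_area_px = 10L) {
  if (min_area_px < 0) stop("`min_area_px` must be >= 0")
  if (min_area_px == 0) return(map)
  lab <- cpp_label(map$vessel, 8L)
  nlab <- max(lab)
  if (nlab == 0L) return(map)
  sizes <- tabulate(lab[lab > 0L], nbins = nlab)
  keep <- sizes >= min_area_px
  vessel <- map$vessel
  vessel[lab > 0L] <- keep[lab[lab > 0L]]
  binary_vessel_map(vessel, px_per_mm = map$px_per_mm,
                    excluded = map$excluded, plexus = map$plexus)
}

#' Slab binarization as used per plexus
#'
#' SCP and DCP slabs are duplicated and binarized with the Huang
#' fuzzy-entropy global threshold and local-median thresholding, then
#' combined (AND). CC slabs are binarized with the Phansalkar method and
#' cleaned with a small-particle filter.
#'
#' @param image an [en_face_image] with its `plexus` field set.
#' @param params a [pipeline_params] list of method parameters.
#' @return a [binary_vessel_map].
#' @export
binarize_slab <- function(image, params = pipeline_params()) {
  if (image$plexus == "CC") {
    map <- phansalkar_binarize(image, radius_px = params$phansalkar_radius_px,
                               k = params$phansalkar_k, r = params$phansalkar_r,
                               p = params$phansalkar_p, q = params$phansalkar_q)
    return(filter_particles(map, params$min_particle_px))
  }
  g <- threshold_binarize(image, huang_threshold(image))
  l <- local_median_binarize(image, window_px = params$median_window_px,
                             offset = params$median_offset)
  combine_binaries(g, l)
}
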