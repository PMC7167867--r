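#' Perfusion density of a region
#'
#' Percentage of the analyzed (non-excluded) region area occupied by vessel
#' pixels: `100 * #(vessel & !excluded) / #(!excluded)` within the region.
#' Excluded pixels leave both the numerator and the denominator, so masking
#' shrinks the analyzed area rather than diluting the density.
#'
#' @param map a [binary_vessel_map].
#' @param roi a `roi_set` sharing the map's grid.
#' @param region region name (see [roi_regions()]).
#' @return perfusion density in percent.
#' @export
perfusion_density <- function(map, roi, region) {
  inc <- region_mask(roi, region) & !map$excluded
  denom <- sum(inc)
  if (denom == 0) stop(sprintf("empty denominator: region '%s' has no included pixels", region))
  100 * sum(map$vessel & inc) / denom
}

#' Skeletonize a binary vessel map
#'
#' Topology-preserving (Zhang-Suen) thinning to 1-px-wide, 8-connected
#' centerlines. Exclusion is not applied here; it acts when lengths are
#' measured.
#'
#' @param map a [binary_vessel_map].
#' @return an object of class `skeleton_map` (`skeleton` logical matrix,
#'   `px_per_mm`).
#' @export
skeletonize <- function(map) {
  structure(
    list(skeleton = cpp_thin(map$vessel), px_per_mm = map$px_per_mm,
         plexus = map$plexus),
    class = "skeleton_map"
  )
}

#' Physical centerline length within a region
#'
#' Length is estimated as the sum over 8-connected skeleton adjacencies of
#' one pixel pitch for axial steps and `sqrt(2)` pitches for diagonal steps
#' (each unordered neighbour pair counted once), restricted to included
#' (in-region, non-excluded) pixels, then converted to millimetres.
#'
#' @param skel a `skeleton_map`.
#' @param roi optional `roi_set`; with `region`, restricts to that region.
#' @param region optional region name.
#' @param excluded optional logical matrix of pixels to ignore.
#' @return length in mm.
#' @export
skeleton_length_mm <- function(skel, roi = NULL, region = NULL, excluded = NULL) {
  inc <- matrix(TRUE, nrow(skel$skeleton), ncol(skel$skeleton))
  if (!is.null(roi) && !is.null(region)) inc <- region_mask(roi, region)
  if (!is.null(excluded)) inc <- inc & !excluded
  e <- cpp_skeleton_edges(skel$skeleton, inc)
  (e[1] + sqrt(2) * e[2]) / skel$px_per_mm
}

#' Vessel length density of a region
#'
#' Skeleton length per analyzed area, in mm per mm^2. The area counts only
#' included (non-excluded) region pixels.
#'
#' @inheritParams skeleton_length_mm
#' @param roi a `roi_set`.
#' @param region region name.
#' @return VLD in mm^-1 (mm per mm^2).
#' @export
vessel_length_density <- function(skel, roi, region, excluded = NULL) {
  inc <- region_mask(roi, region)
  if (!is.null(excluded)) inc <- inc & !excluded
  area <- sum(inc) / skel$px_per_mm^2
  if (area == 0) stop(sprintf("zero included area in region '%s'", region))
  skeleton_length_mm(skel, roi, region, excluded) / area
}

#' Per-region metrics of one slab
#'
#' Computes perfusion density and vessel length density for all six regions
#' of the widefield grid, honouring the map's exclusion grid.
#'
#' @param map a [binary_vessel_map].
#' @param roi a `roi_set`.
#' @param eye_id,group identifiers copied into the output.
#' @return a tibble with columns `eye_id`, `group`, `plexus`, `region`,
#'   `pd`, `vld`, `included_area_mm2`.
#' @export
region_metrics <- function(map, roi, eye_id = NA_character_, group = NA_character_) {
  skel <- skeletonize(map)
  rows <- lapply(roi$regions, function(rg) {
    inc <- region_mask(roi, rg) & !map$excluded
    area <- sum(inc) / map$px_per_mm^2
    tibble::tibble(
      eye_id = eye_id, group = group, plexus = map$plexus, region = rg,
      pd = perfusion_density(map, roi, rg),
      vld = vessel_length_density(skel, roi, rg, excluded = map$excluded),
      included_area_mm2 = area
    )
  })
  do.call(rbind, rows)
}
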