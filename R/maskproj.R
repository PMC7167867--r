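#' Detect large superficial vessels
#'
#' Extracts the footprint of major vessels from a binarized SCP map so it
#' can be excluded from the deeper slabs, where such vessels cast shadow and
#' projection artifacts. Structures at least `min_calibre_px` wide are kept
#' by a morphological opening with a disc of radius
#' `floor(min_calibre_px / 2)`; a geodesic reconstruction capped at
#' `recon_iter` dilation steps (default: the opening radius) restores the
#' rim the opening eroded without regrowing attached capillaries; the result
#' is finally dilated by `dilation_px` for a safety margin.
#'
#' @param scp a [binary_vessel_map] of the superficial plexus.
#' @param min_calibre_px minimum vessel width (pixels, >= 1) counted as "major".
#' @param dilation_px safety dilation of the final mask (pixels).
#' @param recon_iter geodesic reconstruction steps; `NULL` for the opening radius.
#' @return an object of class `exclusion_mask` with fields `mask` (logical
#'   matrix), `min_calibre_px` and `dilation_px`.
#' @export
detect_large_vessels <- function(scp, min_calibre_px = 6L, dilation_px = 2L,
                                 recon_iter = NULL) {
  if (min_calibre_px < 1) stop("`min_calibre_px` must be >= 1")
  radius <- max(1L, as.integer(floor(min_calibre_px / 2)))
  if (is.null(recon_iter)) recon_iter <- radius
  opened <- cpp_dilate_disc(cpp_erode_disc(scp$vessel, radius), radius)
  recon <- cpp_geodesic_dilate(opened, scp$vessel, as.integer(recon_iter))
  mask <- cpp_dilate_disc(recon, as.integer(dilation_px))
  structure(
    list(mask = mask, min_calibre_px = min_calibre_px,
         dilation_px = dilation_px, source = scp$plexus),
    class = "exclusion_mask"
  )
}

#' Exclude masked pixels from a deeper slab
#'
#' Marks the masked pixels as excluded on the target map. The vessel grid is
#' untouched; exclusion takes effect when metrics are computed (their
#' numerators and denominators both skip excluded pixels).
#'
#' @param map a [binary_vessel_map] (typically DCP or CC).
#' @param mask an `exclusion_mask` from [detect_large_vessels()], or a
#'   logical matrix.
#' @return the map with `excluded := excluded | mask`.
#' @export
apply_exclusion <- function(map, mask) {
  m <- if (inherits(mask, "exclusion_mask")) mask$mask else mask
  if (!identical(dim(m), dim(map$vessel))) stop("mask/map shape mismatch")
  binary_vessel_map(map$vessel, px_per_mm = map$px_per_mm,
                    excluded = map$excluded | m, plexus = map$plexus)
}
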