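#' En-face angiogram slab
#'
#' Container for one 8-bit grayscale en-face OCTA slab together with its
#' physical calibration and plexus label. Pixel values are integers in
#' \[0, 255\]; `px_per_mm` converts pixel pitch to physical units.
#'
#' @param pixels integer (or numeric) matrix of intensities in \[0, 255\].
#' @param px_per_mm pixels per millimetre (scalar > 0).
#' @param plexus one of `"SCP"`, `"DCP"`, `"CC"`.
#' @param eye_id,group optional identifiers carried through to metrics.
#' @return an object of class `en_face_image`.
#' @export
en_face_image <- function(pixels, px_per_mm, plexus = c("SCP", "DCP", "CC"),
                          eye_id = NA_character_, group = NA_character_) {
  plexus <- match.arg(plexus)
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (!is.numeric(px_per_mm) || length(px_per_mm) != 1L || !is.finite(px_per_mm) ||
      px_per_mm <= 0) {
    stop("`px_per_mm` must be a positive scalar")
  }
  px <- round(pixels)
  if (anyNA(px) || min(px) < 0 || max(px) > 255) {
    stop("intensities must lie in [0, 255]")
  }
  storage.mode(px) <- "integer"
  structure(
    list(pixels = px, px_per_mm = px_per_mm, plexus = plexus,
         eye_id = eye_id, group = group),
    class = "en_face_image"
  )
}

#' @export
print.en_face_image <- function(x, ...) {
  cat(sprintf("<en_face_image> %s %dx%d px, %.2f px/mm, eye=%s\n",
              x$plexus, nrow(x$pixels), ncol(x$pixels), x$px_per_mm, x$eye_id))
  invisible(x)
}

#' Binary vessel map
#'
#' A boolean vessel grid plus a same-shaped boolean exclusion grid. Excluded
#' pixels stay in the map (the vessel grid is never edited) but are ignored
#' by every metric, so one map supports masked and unmasked analyses.
#'
#' @param vessel logical matrix; `TRUE` marks vessel/flow pixels.
#' @param px_per_mm pixels per millimetre.
#' @param excluded optional logical matrix of pixels to drop from metrics;
#'   defaults to none.
#' @param plexus slab label, if known.
#' @return an object of class `binary_vessel_map`.
#' @export
binary_vessel_map <- function(vessel, px_per_mm, excluded = NULL, plexus = NA_character_) {
  if (!is.matrix(vessel) || !is.logical(vessel)) stop("`vessel` must be a logical matrix")
  if (is.null(excluded)) excluded <- matrix(FALSE, nrow(vessel), ncol(vessel))
  if (!is.matrix(excluded) || !is.logical(excluded) ||
      !identical(dim(excluded), dim(vessel))) {
    stop("`excluded` must be a logical matrix with the shape of `vessel`")
  }
  if (!is.numeric(px_per_mm) || px_per_mm <= 0) stop("`px_per_mm` must be positive")
  structure(
    list(vessel = vessel, excluded = excluded, px_per_mm = px_per_mm, plexus = plexus),
    class = "binary_vessel_map"
  )
}

#' @export
print.binary_vessel_map <- function(x, ...) {
  cat(sprintf("<binary_vessel_map> %dx%d px, %.1f%% vessel, %.1f%% excluded\n",
              nrow(x$vessel), ncol(x$vessel), 100 * mean(x$vessel),
              100 * mean(x$excluded)))
  invisible(x)
}

# internal: coerce an en_face_image or bare matrix to an intensity matrix
as_intensity <- function(image) {
  if (inherits(image, "en_face_image")) return(image$pixels)
  if (is.matrix(image)) {
    m <- round(image)
    storage.mode(m) <- "integer"
    return(m)
  }
  stop("expected an en_face_image or a matrix")
}
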