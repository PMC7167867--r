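#' Read an 8-bit grayscale slab from TIFF or PNG
#'
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @param px_per_mm physical calibration.
#' @param plexus,eye_id,group slab metadata.
#' @return an [en_face_image].
#' @export
read_slab <- function(path, px_per_mm, plexus, eye_id = NA_character_,
                      group = NA_character_) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop(sprintf("unsupported slab format '.%s'", ext))
  )
  if (length(dim(raw)) == 3) raw <- raw[, , 1]
  en_face_image(round(raw * 255), px_per_mm = px_per_mm, plexus = plexus,
                eye_id = eye_id, group = group)
}

#' Write a slab as 8-bit grayscale TIFF or PNG
#' @param image an [en_face_image].
#' @param path output path (`.tif`/`.tiff`/`.png`).
#' @export
write_slab <- function(image, path) {
  m <- image$pixels / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(m, path, bits.per.sample = 8L),
    png = png::writePNG(m, path),
    stop(sprintf("unsupported slab format '.%s'", ext))
  )
  invisible(path)
}

#' Write a binary map (or mask) as a 0/255 PNG with a JSON sidecar
#'
#' @param x a [binary_vessel_map], `exclusion_mask`, or logical matrix.
#' @param path output `.png` path; the sidecar goes to `<path>.json`.
#' @param meta named list recorded in the sidecar (method, parameters).
#' @export
write_binary_png <- function(x, path, meta = list()) {
  m <- if (is.matrix(x)) x else if (inherits(x, "exclusion_mask")) x$mask else x$vessel
  png::writePNG(m * 1, path)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write an ROI label map as an indexed PNG plus a geometry descriptor
#' @param roi a `roi_set`.
#' @param path output `.png` path.
#' @export
write_roi_png <- function(roi, path) {
  png::writePNG(roi$labels / length(roi$regions), path)
  desc <- list(regions = roi$regions, px_per_mm = roi$px_per_mm,
               fovea_center_px = roi$fovea_center_px, laterality = roi$laterality)
  jsonlite::write_json(desc, paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write a rendered cohort to disk
#'
#' Slabs go to `<eye_id>_<SCP|DCP|CC>.tif`, eye metadata to `manifest.csv`,
#' ground-truth region metrics to `truth.csv` and the generating polylines
#' to `networks.json` (when kept on the cohort object).
#'
#' @param cohort result of [generate_cohort()] with `render = "images"`.
#' @param dir output directory (created if needed).
#' @param format `"tiff"` or `"png"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("tiff", "png")) {
  format <- match.arg(format)
  ext <- if (format == "tiff") "tif" else "png"
  if (is.null(cohort$eyes)) stop("cohort has no rendered images")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (eye in cohort$eyes) {
    for (plex in names(eye$slabs)) {
      write_slab(eye$slabs[[plex]], file.path(dir, sprintf("%s_%s.%s", eye$eye_id, plex, ext)))
    }
    roi <- cohort$rois[[eye$laterality]]
    manifest[[length(manifest) + 1L]] <- data.frame(
      eye_id = eye$eye_id, group = eye$group, laterality = eye$laterality,
      fovea_x = roi$fovea_center_px[1], fovea_y = roi$fovea_center_px[2]
    )
  }
  utils::write.csv(do.call(rbind, manifest), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Write a vessel network's polylines as JSON
#' @param network a [vessel_network].
#' @param path output `.json` path.
#' @export
write_network_json <- function(network, path) {
  jsonlite::write_json(
    list(field_size_mm = network$field_size_mm,
         calibre_mm = network$calibre_mm,
         segments = lapply(network$segments, function(s) unname(as.matrix(s)))),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a vessel network written by [write_network_json()]
#' @param path `.json` path.
#' @export
read_network_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  segs <- lapply(x$segments, function(s) matrix(unlist(s), ncol = 2))
  vessel_network(segs, as.numeric(x$calibre_mm), x$field_size_mm)
}
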