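#' Region names of the widefield grid
#' @export
roi_regions <- function() {
  c("tight_central", "medium_central", "large_central",
    "superior", "temporal", "inferior")
}

#' Build the six-region widefield ROI grid
#'
#' The macular region is split into three mutually exclusive concentric
#' shells centred on the fovea — the tight central ring (disc, diameter
#' 1.5 mm), the medium central ring (annulus, 1.5–3 mm) and the large
#' central ring (annulus, 3–5 mm). The periphery is sampled by three
#' 3-mm-diameter circles externally tangent to the 5-mm circle (centre
#' distance 2.5 + 1.5 = 4 mm from the fovea): superior (image up), inferior
#' (image down) and temporal, whose side depends on laterality (`"OD"`:
#' image left; `"OS"`: image right, assuming fundus orientation).
#'
#' Pixel membership is decided by the pixel-centre distance; boundary pixels
#' at exact equality go to the inner region. Central regions take precedence
#' over peripheral circles at the tangency band.
#'
#' @param px_per_mm pixels per millimetre.
#' @param image_shape integer vector `c(nrow, ncol)`.
#' @param fovea_center_px fovea position `c(x, y)` in pixel units (pixel
#'   centres at half-integers); defaults to the image centre.
#' @param laterality `"OD"` (right eye) or `"OS"` (left eye).
#' @return an object of class `roi_set`: integer label matrix `labels`
#'   (0 = outside, 1..6 per [roi_regions()]), plus geometry fields.
#' @export
build_roi_set <- function(px_per_mm, image_shape, fovea_center_px = NULL,
                          laterality = c("OD", "OS")) {
  laterality <- match.arg(laterality)
  nr <- image_shape[1]
  nc <- image_shape[2]
  if (is.null(fovea_center_px)) fovea_center_px <- c(nc / 2, nr / 2)
  fx <- fovea_center_px[1]
  fy <- fovea_center_px[2]

  ring_r <- 1.5                      # peripheral circle radius, mm
  centre_d <- 2.5 + ring_r           # fovea-to-peripheral-centre distance, mm
  tdir <- if (laterality == "OD") -1 else 1
  centres <- list(
    superior = c(fx, fy - centre_d * px_per_mm),
    temporal = c(fx + tdir * centre_d * px_per_mm, fy),
    inferior = c(fx, fy + centre_d * px_per_mm)
  )
  for (nm in names(centres)) {
    cc <- centres[[nm]]
    rpx <- ring_r * px_per_mm
    if (cc[1] - rpx < 0 || cc[1] + rpx > nc || cc[2] - rpx < 0 || cc[2] + rpx > nr) {
      stop(sprintf("peripheral circle '%s' does not fit inside the image", nm))
    }
  }

  # pixel-centre coordinates in mm relative to the fovea
  x_mm <- ((seq_len(nc) - 0.5) - fx) / px_per_mm
  y_mm <- ((seq_len(nr) - 0.5) - fy) / px_per_mm
  x2 <- matrix(x_mm^2, nr, nc, byrow = TRUE)
  y2 <- matrix(y_mm^2, nr, nc)
  r <- sqrt(x2 + y2)

  labels <- matrix(0L, nr, nc)
  regions <- roi_regions()
  for (nm in names(centres)) {
    cc <- centres[[nm]]
    dx <- matrix((((seq_len(nc) - 0.5) - cc[1]) / px_per_mm)^2, nr, nc, byrow = TRUE)
    dy <- matrix((((seq_len(nr) - 0.5) - cc[2]) / px_per_mm)^2, nr, nc)
    labels[sqrt(dx + dy) <= ring_r] <- match(nm, regions)
  }
  labels[r <= 2.5] <- 3L
  labels[r <= 1.5] <- 2L
  labels[r <= 0.75] <- 1L

  structure(
    list(labels = labels, regions = regions, fovea_center_px = c(fx, fy),
         px_per_mm = px_per_mm, laterality = laterality,
         peripheral_centres_px = centres),
    class = "roi_set"
  )
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %dx%d px at %.2f px/mm, fovea (%.1f, %.1f), %s\n",
              nrow(x$labels), ncol(x$labels), x$px_per_mm,
              x$fovea_center_px[1], x$fovea_center_px[2], x$laterality))
  invisible(x)
}

#' Pixel-counted region areas
#'
#' @param roi a `roi_set`.
#' @return named numeric vector of region areas in mm^2.
#' @export
roi_region_areas <- function(roi) {
  counts <- tabulate(roi$labels[roi$labels > 0L], nbins = length(roi$regions))
  stats::setNames(counts / roi$px_per_mm^2, roi$regions)
}

#' Analytic region areas of the widefield grid (mm^2)
#' @export
roi_analytic_areas <- function() {
  stats::setNames(
    c(pi * 0.75^2, pi * (1.5^2 - 0.75^2), pi * (2.5^2 - 1.5^2),
      pi * 1.5^2, pi * 1.5^2, pi * 1.5^2),
    roi_regions()
  )
}

# internal: logical mask of a named region
region_mask <- function(roi, region) {
  code <- match(region, roi$regions)
  if (is.na(code)) stop(sprintf("unknown region '%s'", region))
  roi$labels == code
}
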