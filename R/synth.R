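#' Parameters of the synthetic angiogram generator
#'
#' The generator grows vessel trees as biased random walks with Bernoulli
#' branching (see [generate_vessel_tree()]) and paints them onto an 8-bit
#' two-level canvas, optionally followed by Gaussian speckle. Defaults are
#' realistic for retinal capillary slabs: mildly tortuous capillaries
#' (50-micron steps, 0.12 rad turning), ~25-micron calibre, anastomosing
#' growth, and a 12 x 12 mm field.
#'
#' @param seed RNG seed for the tree growth.
#' @param n_roots number of initial sprouting points; 0 yields an empty
#'   network.
#' @param field_size_mm side of the square field (mm).
#' @param target_vld total vessel length per unit area to grow, mm per mm^2.
#' @param step_mm walk step length (mm).
#' @param turn_sd per-step direction change SD (radians).
#' @param branch_prob_per_mm branching intensity per mm grown.
#' @param stop_prob_per_mm per-mm termination intensity of a branch tip.
#' @param calibre_mean_mm,calibre_sd_mm per-segment calibre distribution (mm).
#' @param large_vessel_count,large_vessel_calibre_mm number and calibre of
#'   large (arcade-like) vessels crossing the field; SCP only.
#' @param shadow_factor intensity attenuation applied to deeper slabs under
#'   the large-vessel footprint.
#' @param noise_sigma Gaussian speckle SD in intensity units.
#' @param background_level,vessel_level 8-bit intensities of background and
#'   vessel pixels before noise.
#' @return a validated `synth_params` list.
#' @export
synth_params <- function(seed = 1L, n_roots = 150L, field_size_mm = 12,
                         target_vld = 20, step_mm = 0.05, turn_sd = 0.12,
                         branch_prob_per_mm = 0.3, stop_prob_per_mm = 0.5,
                         calibre_mean_mm = 0.025, calibre_sd_mm = 0.005,
                         large_vessel_count = 4L, large_vessel_calibre_mm = 0.12,
                         shadow_factor = 0.35, noise_sigma = 20,
                         background_level = 50, vessel_level = 200) {
  p <- list(seed = as.integer(seed), n_roots = as.integer(n_roots),
            field_size_mm = field_size_mm, target_vld = target_vld,
            step_mm = step_mm, turn_sd = turn_sd,
            branch_prob_per_mm = branch_prob_per_mm,
            stop_prob_per_mm = stop_prob_per_mm,
            calibre_mean_mm = calibre_mean_mm, calibre_sd_mm = calibre_sd_mm,
            large_vessel_count = as.integer(large_vessel_count),
            large_vessel_calibre_mm = large_vessel_calibre_mm,
            shadow_factor = shadow_factor, noise_sigma = noise_sigma,
            background_level = background_level, vessel_level = vessel_level)
  num <- unlist(p[setdiff(names(p), character())], use.names = TRUE)
  if (any(!is.finite(num))) stop("synth_params: all parameters must be finite")
  if (p$noise_sigma < 0) stop("`noise_sigma` must be >= 0")
  if (p$target_vld < 0) stop("`target_vld` must be >= 0")
  if (p$vessel_level <= p$background_level) {
    stop("`vessel_level` must exceed `background_level`")
  }
  if (p$field_size_mm <= 0 || p$step_mm <= 0) stop("field and step must be positive")
  class(p) <- "synth_params"
  p
}

#' Vessel network with exact polyline ground truth
#'
#' @param segments list of polylines, each an n x 2 matrix of (x, y) vertices
#'   in mm within the field.
#' @param calibre_mm per-polyline calibre (mm, > 0).
#' @param field_size_mm field side (mm).
#' @return a `vessel_network`.
#' @export
vessel_network <- function(segments, calibre_mm, field_size_mm) {
  if (length(segments) != length(calibre_mm)) stop("one calibre per polyline required")
  for (s in segments) {
    if (!is.matrix(s) || ncol(s) != 2 || nrow(s) < 2) {
      stop("each polyline must be an n x 2 matrix with n >= 2")
    }
    if (min(s) < 0 || max(s) > field_size_mm) stop("polyline vertices outside the field")
  }
  if (length(calibre_mm) && any(calibre_mm <= 0)) stop("calibres must be > 0")
  structure(list(segments = segments, calibre_mm = calibre_mm,
                 field_size_mm = field_size_mm),
            class = "vessel_network")
}

#' Total polyline length of a network (mm)
#' @param network a `vessel_network`.
#' @export
network_length_mm <- function(network) {
  sum(vapply(network$segments, function(s) {
    sum(sqrt(rowSums((s[-1, , drop = FALSE] - s[-nrow(s), , drop = FALSE])^2)))
  }, numeric(1)))
}

# run `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Grow a synthetic capillary network
#'
#' Branches grow as biased random walks: at each `step_mm` step the heading
#' is perturbed by N(0, turn_sd), the walk reflects off the field border,
#' branches with probability `branch_prob_per_mm * step_mm` (new tip at
#' roughly +/- 60 degrees) and terminates with probability
#' `stop_prob_per_mm * step_mm`. Like a planar capillary bed, the network
#' anastomoses instead of crossing itself: a tip stepping onto an occupied
#' cell of a fine occupancy grid (35-micron cells) ends there. Growth starts
#' from `n_roots` uniformly placed roots; when all tips die before the
#' length budget `target_vld * field_area` is spent, fresh roots are sown,
#' so realized length density is spatially homogeneous and close to the
#' target. One calibre is drawn per polyline; the occupancy grid does not
#' depend on calibre, so the same seed yields the same geometry across a
#' calibre sweep.
#'
#' @param params a [synth_params] object.
#' @return a [vessel_network].
#' @export
generate_vessel_tree <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  fs <- params$field_size_mm
  if (params$n_roots == 0L || params$target_vld == 0) {
    return(vessel_network(list(), numeric(0), fs))
  }
  with_seed(params$seed, {
    budget <- params$target_vld * fs^2
    step <- params$step_mm
    p_branch <- params$branch_prob_per_mm * step
    p_stop <- params$stop_prob_per_mm * step
    cell <- 0.035                      # occupancy cell size, mm
    ncell <- ceiling(fs / cell)
    occ <- matrix(0L, ncell, ncell)    # 0 = free, else polyline id
    cell_of <- function(x, y) c(min(max(ceiling(x / cell), 1L), ncell),
                                min(max(ceiling(y / cell), 1L), ncell))
    new_root <- function() list(x = stats::runif(1, 0, fs), y = stats::runif(1, 0, fs),
                                dir = stats::runif(1, 0, 2 * pi))
    tips <- lapply(seq_len(params$n_roots), function(i) new_root())
    polylines <- list()
    total <- 0
    stalls <- 0L
    while (total < budget && stalls < 5000L) {
      if (length(tips) == 0L) tips <- list(new_root())
      tip <- tips[[length(tips)]]
      tips[[length(tips)]] <- NULL
      id <- length(polylines) + 1L
      verts <- matrix(c(tip$x, tip$y), 1, 2)
      dir <- tip$dir
      nsteps <- 0L
      recent <- matrix(-1L, 3, 2)      # last own cells: wiggling is not a collision
      repeat {
        dir <- dir + stats::rnorm(1, 0, params$turn_sd)
        nx <- verts[nrow(verts), 1] + step * cos(dir)
        ny <- verts[nrow(verts), 2] + step * sin(dir)
        if (nx < 0 || nx > fs) {           # bounce off vertical borders
          dir <- pi - dir
          nx <- min(max(nx, 0), fs)
        }
        if (ny < 0 || ny > fs) {           # bounce off horizontal borders
          dir <- -dir
          ny <- min(max(ny, 0), fs)
        }
        cl <- cell_of(nx, ny)
        hit <- occ[cl[1], cl[2]] != 0L && nsteps >= 2L &&
          !any(recent[, 1] == cl[1] & recent[, 2] == cl[2])
        seg_len <- sqrt((nx - verts[nrow(verts), 1])^2 + (ny - verts[nrow(verts), 2])^2)
        verts <- rbind(verts, c(nx, ny))
        total <- total + seg_len
        nsteps <- nsteps + 1L
        if (hit) break                     # anastomose into the existing vessel
        occ[cl[1], cl[2]] <- id
        recent <- rbind(recent[-1, , drop = FALSE], cl)
        if (stats::runif(1) < p_branch) {
          bdir <- dir + sample(c(-1, 1), 1) * stats::runif(1, pi / 4, pi / 3)
          tips[[length(tips) + 1L]] <- list(x = nx, y = ny, dir = bdir)
        }
        if (total >= budget || stats::runif(1) < p_stop) break
      }
      if (nrow(verts) >= 3) {
        polylines[[id]] <- verts
        stalls <- 0L
      } else {
        total <- total - seg_len         # degenerate stub: roll back
        stalls <- stalls + 1L
      }
    }
    calibres <- pmax(stats::rnorm(length(polylines), params$calibre_mean_mm,
                                  params$calibre_sd_mm), 0.004)
    vessel_network(polylines, calibres, fs)
  })
}

#' Grow large arcade-like vessels
#'
#' A handful of long, smooth, wide vessels entering from the field border,
#' used for the superficial slab so the deeper slabs have shadow artifacts
#' to exclude.
#'
#' @param params a [synth_params]; uses `large_vessel_count` and
#'   `large_vessel_calibre_mm`.
#' @param seed RNG seed (defaults to `params$seed + 1`).
#' @return a [vessel_network].
#' @export
generate_large_vessels <- function(params, seed = params$seed + 1L) {
  stopifnot(inherits(params, "synth_params"))
  n <- params$large_vessel_count
  fs <- params$field_size_mm
  if (n == 0L) return(vessel_network(list(), numeric(0), fs))
  with_seed(seed, {
    polylines <- lapply(seq_len(n), function(i) {
      side <- sample(4L, 1)
      t0 <- stats::runif(1, 0.2, 0.8) * fs
      start <- switch(side, c(0, t0), c(fs, t0), c(t0, 0), c(t0, fs))
      dir <- switch(side, 0, pi, pi / 2, -pi / 2) + stats::runif(1, -pi / 6, pi / 6)
      verts <- matrix(start, 1, 2)
      step <- 0.2
      for (k in seq_len(ceiling(1.5 * fs / step))) {
        dir <- dir + stats::rnorm(1, 0, 0.05)
        nx <- verts[nrow(verts), 1] + step * cos(dir)
        ny <- verts[nrow(verts), 2] + step * sin(dir)
        if (nx < 0 || nx > fs || ny < 0 || ny > fs) break
        verts <- rbind(verts, c(nx, ny))
      }
      verts
    })
    keep <- vapply(polylines, nrow, integer(1)) >= 2
    vessel_network(polylines[keep],
                   rep(params$large_vessel_calibre_mm, sum(keep)), fs)
  })
}

#' Rasterize a vessel network
#'
#' Strokes every polyline at its calibre (round caps; a pixel is vessel when
#' its centre lies within calibre/2 of a segment, with a floor of half a
#' pixel so sub-pixel capillaries still render connected) and returns both
#' the boolean truth map and the corresponding two-level 8-bit image.
#'
#' @param network a [vessel_network].
#' @param px_per_mm raster resolution (> 0).
#' @param image_shape optional `c(nrow, ncol)`; must agree with the field
#'   size at the given resolution to within one pixel. Default
#'   `round(field * px_per_mm)`.
#' @param vessel_level,background_level 8-bit intensities.
#' @param plexus,eye_id,group labels for the image.
#' @return list with `truth` (a [binary_vessel_map]) and `image`
#'   (an [en_face_image]).
#' @export
rasterize_network <- function(network, px_per_mm, image_shape = NULL,
                              vessel_level = 200, background_level = 50,
                              plexus = "SCP", eye_id = NA_character_,
                              group = NA_character_) {
  if (px_per_mm <= 0) stop("`px_per_mm` must be > 0")
  side <- round(network$field_size_mm * px_per_mm)
  if (is.null(image_shape)) image_shape <- c(side, side)
  if (any(abs(image_shape - network$field_size_mm * px_per_mm) > 1)) {
    stop("image_shape inconsistent with field size at this resolution")
  }
  nr <- image_shape[1]
  nc <- image_shape[2]
  if (length(network$segments) == 0L) {
    truth <- matrix(FALSE, nr, nc)
  } else {
    segs <- do.call(rbind, lapply(seq_along(network$segments), function(i) {
      v <- network$segments[[i]] * px_per_mm
      n <- nrow(v)
      cbind(v[-n, 1], v[-n, 2], v[-1, 1], v[-1, 2], i)
    }))
    hw <- pmax(network$calibre_mm[segs[, 5]] / 2 * px_per_mm, 0.5)
    truth <- cpp_stroke(nr, nc, segs[, 1:4, drop = FALSE], hw)
  }
  img <- matrix(background_level, nr, nc)
  img[truth] <- vessel_level
  list(truth = binary_vessel_map(truth, px_per_mm = px_per_mm, plexus = plexus),
       image = en_face_image(img, px_per_mm = px_per_mm, plexus = plexus,
                             eye_id = eye_id, group = group))
}

#' Add Gaussian speckle to a slab
#'
#' Adds seeded N(0, sigma) noise, rounds, and clips to the 8-bit range.
#' `sigma = 0` returns the image unchanged.
#'
#' @param image an [en_face_image].
#' @param sigma noise SD in intensity units (>= 0).
#' @param seed RNG seed.
#' @return an [en_face_image].
#' @export
add_speckle <- function(image, sigma, seed = 1L) {
  if (sigma < 0) stop("`sigma` must be >= 0")
  if (sigma == 0) return(image)
  px <- image$pixels
  noisy <- with_seed(seed, px + stats::rnorm(length(px), 0, sigma))
  px2 <- matrix(pmin(pmax(round(noisy), 0), 255), nrow(px), ncol(px))
  en_face_image(px2, px_per_mm = image$px_per_mm, plexus = image$plexus,
                eye_id = image$eye_id, group = image$group)
}

#' Ground-truth polyline length per region
#'
#' Integrates polyline length within each ROI region by fine subdivision
#' (sample spacing ~ a quarter pixel), yielding the true VLD each region
#' would have under perfect centerline recovery.
#'
#' @param network a [vessel_network].
#' @param roi a `roi_set` covering the field.
#' @return named numeric vector of true VLD (mm^-1) per region.
#' @export
truth_vld_by_region <- function(network, roi) {
  ppm <- roi$px_per_mm
  nr <- nrow(roi$labels)
  nc <- ncol(roi$labels)
  len <- stats::setNames(numeric(length(roi$regions)), roi$regions)
  sub <- 0.25 / ppm  # sample spacing in mm
  for (s in network$segments) {
    for (k in seq_len(nrow(s) - 1)) {
      a <- s[k, ]
      b <- s[k + 1, ]
      L <- sqrt(sum((b - a)^2))
      if (L == 0) next
      nsub <- max(1L, ceiling(L / sub))
      t <- (seq_len(nsub) - 0.5) / nsub
      xs <- a[1] + t * (b[1] - a[1])
      ys <- a[2] + t * (b[2] - a[2])
      i <- pmin(pmax(ceiling(ys * ppm), 1L), nr)
      j <- pmin(pmax(ceiling(xs * ppm), 1L), nc)
      lab <- roi$labels[cbind(i, j)]
      tab <- tabulate(lab[lab > 0L], nbins = length(roi$regions))
      len <- len + tab * (L / nsub)
    }
  }
  areas <- roi_region_areas(roi)
  len / areas
}

#' Ground-truth perfusion density per region from a truth raster
#'
#' @param truth a [binary_vessel_map] rasterized from ground-truth polylines.
#' @param roi a `roi_set`.
#' @return named numeric vector of true PD (percent) per region.
#' @export
truth_pd_by_region <- function(truth, roi) {
  vapply(stats::setNames(roi$regions, roi$regions),
         function(rg) perfusion_density(truth, roi, rg), numeric(1))
}

# coverage of the network stroked at a uniform calibre, measured over a
# central window at the target resolution
stroke_coverage <- function(network, calibre_mm, px_per_mm, win_mm = 4) {
  fs <- network$field_size_mm
  win_mm <- min(win_mm, fs)
  if (length(network$segments) == 0L) return(0)
  orig <- (fs - win_mm) / 2
  win_px <- max(1L, round(win_mm * px_per_mm))
  segs <- do.call(rbind, lapply(network$segments, function(v) {
    v <- (v - orig) * px_per_mm
    n <- nrow(v)
    cbind(v[-n, 1], v[-n, 2], v[-1, 1], v[-1, 2])
  }))
  hw <- rep(max(calibre_mm / 2 * px_per_mm, 0.5), nrow(segs))
  mean(cpp_stroke(win_px, win_px, segs, hw))
}

#' Calibrate a stroke calibre to hit a perfusion-density target
#'
#' Linear interpolation between the no-overlap calibre `pd / vld` and the
#' boolean-model calibre `-log(1 - pd) / vld`, anchored by the realized
#' coverage of the actual network on a central window. Network geometry is
#' independent of calibre, so this is exact up to interpolation error.
#'
#' @param network a [vessel_network].
#' @param vld the network's length density (mm^-1).
#' @param pd_target target coverage in percent.
#' @param px_per_mm raster resolution the calibration applies to.
#' @return calibre in mm.
#' @export
calibrate_calibre <- function(network, vld, pd_target, px_per_mm) {
  tgt <- pd_target / 100
  w1 <- tgt / vld
  w2 <- -log(1 - tgt) / vld
  c1 <- stroke_coverage(network, w1, px_per_mm)
  c2 <- stroke_coverage(network, w2, px_per_mm)
  if (abs(c2 - c1) < 1e-9) return(w1)
  w <- w1 + (w2 - w1) * (tgt - c1) / (c2 - c1)
  min(max(w, 0.25 * w1), 4 * w2)
}
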