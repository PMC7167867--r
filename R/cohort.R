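#' Control-group density targets per plexus
#'
#' Default generator targets: vessel length density (mm^-1) and perfusion
#' density (percent) of healthy eyes per plexus, at the level reported for
#' widefield scans of healthy adults (retinal plexuses around 20 mm^-1 and
#' 40-45%; choriocapillaris a dense slab around 11 mm^-1 and 84%).
#'
#' @return a tibble with `plexus`, `vld_mean`, `pd_mean`.
#' @export
plexus_targets <- function() {
  tibble::tibble(
    plexus = c("SCP", "DCP", "CC"),
    vld_mean = c(19.5, 22.3, 10.8),
    pd_mean = c(42.0, 45.6, 84.3)
  )
}

#' Two-group cohort specification
#'
#' Defines the simulated case-control study: eyes per group, the prescribed
#' case reductions in VLD and PD per plexus, and the between-eye spread. The
#' default effect is an 18% reduction of the control mean with the
#' between-eye SD calibrated so that effect/SD = 18/17, matching the power
#' assumption of the emulated study design (18% expected difference, pooled
#' SD 17, both on the percent-of-mean scale).
#'
#' @param n_controls,n_cases eyes per group (>= 0).
#' @param vld_effect case reduction in VLD (mm^-1); scalar or named per
#'   plexus. `NULL` = 18% of the control mean.
#' @param pd_effect case reduction in PD (percentage points); scalar or
#'   named per plexus. `NULL` = 18% of the control mean.
#' @param vld_sd,pd_sd between-eye SDs; `NULL` = effect * 17 / 18 (default
#'   effects), i.e. 17% of the control mean.
#' @param region_effects optional named numeric vector of additional VLD
#'   reductions (mm^-1) applied to cases in specific regions.
#' @param targets control-group targets, see [plexus_targets()].
#' @param seed cohort RNG seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_controls = 20L, n_cases = 20L, vld_effect = NULL,
                        pd_effect = NULL, vld_sd = NULL, pd_sd = NULL,
                        region_effects = NULL, targets = plexus_targets(),
                        seed = 1L) {
  if (n_controls < 0 || n_cases < 0) stop("group sizes must be >= 0")
  targets <- tibble::as_tibble(targets)
  expand <- function(x, default) {
    out <- stats::setNames(default, targets$plexus)
    if (is.null(x)) return(out)
    if (!all(is.finite(x))) stop("effects must be finite")
    if (is.null(names(x))) out[] <- x else out[names(x)] <- x
    out
  }
  vld_effect <- expand(vld_effect, 0.18 * targets$vld_mean)
  pd_effect <- expand(pd_effect, 0.18 * targets$pd_mean)
  vld_sd <- expand(vld_sd, vld_effect * 17 / 18)
  pd_sd <- expand(pd_sd, pd_effect * 17 / 18)
  # zero-effect cohorts still need spread: fall back to 17% of the mean
  vld_sd[vld_sd <= 0] <- 0.17 * targets$vld_mean[match(names(vld_sd)[vld_sd <= 0], targets$plexus)]
  pd_sd[pd_sd <= 0] <- 0.17 * targets$pd_mean[match(names(pd_sd)[pd_sd <= 0], targets$plexus)]
  if (!is.null(region_effects)) {
    if (is.null(names(region_effects)) ||
        !all(names(region_effects) %in% roi_regions())) {
      stop("`region_effects` must be named by region")
    }
  }
  structure(list(n_controls = as.integer(n_controls), n_cases = as.integer(n_cases),
                 vld_effect = vld_effect, pd_effect = pd_effect,
                 vld_sd = vld_sd, pd_sd = pd_sd,
                 region_effects = region_effects, targets = targets,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# per-eye, per-plexus truth draws (eye-level density targets)
draw_eye_targets <- function(spec) {
  n <- spec$n_controls + spec$n_cases
  groups <- rep(c("control", "case"), c(spec$n_controls, spec$n_cases))
  np <- nrow(spec$targets)
  eye <- rep(seq_len(n), each = np)
  plex <- rep(spec$targets$plexus, n)
  is_case <- groups[eye] == "case"
  mu_v <- rep(spec$targets$vld_mean, n) - ifelse(is_case, spec$vld_effect[plex], 0)
  mu_p <- rep(spec$targets$pd_mean, n) - ifelse(is_case, spec$pd_effect[plex], 0)
  tibble::tibble(
    eye_id = sprintf("eye%03d", eye), group = groups[eye], plexus = plex,
    vld_target = pmax(stats::rnorm(n * np, mu_v, spec$vld_sd[plex]), 0.5),
    pd_target = pmin(pmax(stats::rnorm(n * np, mu_p, spec$pd_sd[plex]), 1), 99)
  )
}

#' Generate a two-group synthetic cohort
#'
#' Draws per-eye density targets from the group distributions of `spec` and
#' either records them directly as ground-truth region metrics
#' (`render = "metrics"`, fast; used for statistical simulations) or grows,
#' rasterizes and degrades full slab triples per eye
#' (`render = "images"`), in which case the truth metrics are measured from
#' the generated polylines (VLD) and the noise-free truth rasters (PD).
#' Synthetic eyes are regionally homogeneous up to the prescribed
#' `region_effects` and the realization noise of the growth process.
#'
#' @param spec a [cohort_spec].
#' @param params a [synth_params]; growth/noise settings for image rendering.
#' @param render `"metrics"` or `"images"`.
#' @param px_per_mm raster resolution for image rendering.
#' @return a list with `truth` (tibble: eye_id, group, laterality, plexus,
#'   region, vld, pd) and, for image rendering, `eyes` (per-eye slab triples
#'   and truth maps) and `rois`.
#' @export
generate_cohort <- function(spec, params = synth_params(),
                            render = c("metrics", "images"),
                            px_per_mm = 1024 / params$field_size_mm) {
  render <- match.arg(render)
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    tar <- draw_eye_targets(spec)
    eye_ids <- unique(tar$eye_id)
    lat <- rep(c("OD", "OS"), length.out = length(eye_ids))
    names(lat) <- eye_ids
    reg_eff <- stats::setNames(numeric(length(roi_regions())), roi_regions())
    if (!is.null(spec$region_effects)) {
      reg_eff[names(spec$region_effects)] <- spec$region_effects
    }

    if (render == "metrics") {
      nr <- nrow(tar)
      nreg <- length(roi_regions())
      idx <- rep(seq_len(nr), each = nreg)
      region <- rep(roi_regions(), nr)
      eff <- ifelse(tar$group[idx] == "case", reg_eff[region], 0)
      truth <- tibble::tibble(
        eye_id = tar$eye_id[idx], group = tar$group[idx],
        laterality = unname(lat[tar$eye_id[idx]]), plexus = tar$plexus[idx],
        region = region,
        vld = pmax(tar$vld_target[idx] - eff, 0),
        pd = tar$pd_target[idx]
      )
      return(list(truth = truth, eyes = NULL, rois = NULL))
    }

    side <- round(params$field_size_mm * px_per_mm)
    eye_seeds <- sample.int(.Machine$integer.max - 1L, length(eye_ids))
    rois <- list(
      OD = build_roi_set(px_per_mm, c(side, side), laterality = "OD"),
      OS = build_roi_set(px_per_mm, c(side, side), laterality = "OS")
    )
    eyes <- list()
    truth_rows <- list()
    for (ei in seq_along(eye_ids)) {
      id <- eye_ids[ei]
      g <- tar$group[tar$eye_id == id][1]
      roi <- rois[[lat[id]]]
      lv <- generate_large_vessels(params, seed = eye_seeds[ei])
      lv_raster <- rasterize_network(lv, px_per_mm,
                                     vessel_level = params$vessel_level,
                                     background_level = params$background_level)
      slabs <- list()
      truth_maps <- list()
      for (k in seq_len(nrow(spec$targets))) {
        plex <- spec$targets$plexus[k]
        row <- tar[tar$eye_id == id & tar$plexus == plex, ]
        guess <- (row$pd_target / 100) / row$vld_target
        p_eye <- params
        p_eye$seed <- (eye_seeds[ei] + k) %% .Machine$integer.max
        p_eye$target_vld <- row$vld_target
        p_eye$calibre_mean_mm <- guess
        p_eye$calibre_sd_mm <- 0.15 * guess
        net <- generate_vessel_tree(p_eye)
        # network geometry does not depend on calibre, so the calibre can be
        # calibrated on the realized network to hit the eye's PD target
        calibre <- calibrate_calibre(net, row$vld_target, row$pd_target, px_per_mm)
        net$calibre_mm <- net$calibre_mm * (calibre / guess)
        ras <- rasterize_network(net, px_per_mm, plexus = plex, eye_id = id,
                                 group = g, vessel_level = params$vessel_level,
                                 background_level = params$background_level)
        truth_vessel <- ras$truth$vessel
        img <- ras$image$pixels
        true_vld <- truth_vld_by_region(net, roi)
        if (plex == "SCP") {
          truth_vessel <- truth_vessel | lv_raster$truth$vessel
          img[lv_raster$truth$vessel] <- params$vessel_level
          true_vld <- true_vld + truth_vld_by_region(lv, roi)
        } else {
          # large superficial vessels shadow the deeper slabs
          sh <- lv_raster$truth$vessel
          img[sh] <- round(img[sh] * params$shadow_factor)
        }
        tmap <- binary_vessel_map(truth_vessel, px_per_mm, plexus = plex)
        image <- en_face_image(img, px_per_mm, plexus = plex, eye_id = id, group = g)
        image <- add_speckle(image, params$noise_sigma,
                             seed = (eye_seeds[ei] + 100L + k) %% .Machine$integer.max)
        slabs[[plex]] <- image
        truth_maps[[plex]] <- tmap
        truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
          eye_id = id, group = g, laterality = lat[id], plexus = plex,
          region = roi$regions, vld = unname(true_vld),
          pd = unname(truth_pd_by_region(tmap, roi))
        )
      }
      eyes[[id]] <- list(eye_id = id, group = g, laterality = lat[id],
                         slabs = slabs, truth_maps = truth_maps,
                         lv_footprint = lv_raster$truth$vessel)
    }
    list(truth = do.call(rbind, truth_rows), eyes = eyes, rois = rois)
  })
}

#' Pivot long metrics to a per-eye table
#'
#' Turns the long (eye, plexus, region, pd, vld) metrics into one row per
#' eye with columns `<plexus>_<region>_<metric>`, the layout used by the
#' statistical layer.
#'
#' @param metrics long tibble as returned by [region_metrics()] /
#'   `generate_cohort()$truth`.
#' @return a wide tibble, one row per eye.
#' @export
cohort_table <- function(metrics) {
  eyes <- unique(metrics[, intersect(c("eye_id", "group", "laterality"),
                                     names(metrics))])
  if (anyDuplicated(eyes$eye_id)) stop("conflicting eye metadata")
  out <- eyes
  for (plex in unique(metrics$plexus)) {
    for (rg in unique(metrics$region)) {
      sel <- metrics$plexus == plex & metrics$region == rg
      sub <- metrics[sel, ]
      idx <- match(out$eye_id, sub$eye_id)
      for (m in c("pd", "vld")) {
        if (!m %in% names(sub)) next
        out[[paste(plex, rg, m, sep = "_")]] <- sub[[m]][idx]
      }
    }
  }
  tibble::as_tibble(out)
}
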