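#' Quantification parameters
#'
#' Method parameters of the binarization, artifact-exclusion and particle
#' steps, with the package defaults. All are exposed here so a run's
#' manifest fully determines its outputs.
#'
#' @param median_window_px local-median window side (odd px).
#' @param median_offset intensity offset above the local median.
#' @param phansalkar_radius_px disc radius of the Phansalkar window (px).
#' @param phansalkar_k,phansalkar_r,phansalkar_p,phansalkar_q Phansalkar
#'   constants.
#' @param min_particle_px minimum particle area kept on CC maps (px).
#' @param large_vessel_min_calibre_px minimum width treated as a major
#'   superficial vessel (px).
#' @param exclusion_dilation_px safety dilation of the exclusion mask (px).
#' @return a named list of class `pipeline_params`.
#' @export
pipeline_params <- function(median_window_px = 31L, median_offset = 0,
                            phansalkar_radius_px = 15L, phansalkar_k = 0.25,
                            phansalkar_r = 0.5, phansalkar_p = 2,
                            phansalkar_q = 10, min_particle_px = 10L,
                            large_vessel_min_calibre_px = 6L,
                            exclusion_dilation_px = 2L) {
  structure(list(
    median_window_px = as.integer(median_window_px),
    median_offset = median_offset,
    phansalkar_radius_px = as.integer(phansalkar_radius_px),
    phansalkar_k = phansalkar_k, phansalkar_r = phansalkar_r,
    phansalkar_p = phansalkar_p, phansalkar_q = phansalkar_q,
    min_particle_px = as.integer(min_particle_px),
    large_vessel_min_calibre_px = as.integer(large_vessel_min_calibre_px),
    exclusion_dilation_px = as.integer(exclusion_dilation_px)
  ), class = "pipeline_params")
}

#' Quantify one eye's slab triple
#'
#' Binarizes each available slab ([binarize_slab()]), derives the
#' large-superficial-vessel exclusion mask from the SCP map, applies it to
#' the DCP and CC maps, and computes per-region perfusion density and
#' vessel length density.
#'
#' @param slabs named list of [en_face_image]s (`SCP`, `DCP`, `CC`; any
#'   subset, but exclusion needs `SCP`).
#' @param roi a `roi_set` on the slabs' grid.
#' @param params a [pipeline_params].
#' @return long metrics tibble, plus the exclusion mask as an attribute
#'   `"exclusion"`.
#' @export
quantify_eye <- function(slabs, roi, params = pipeline_params()) {
  maps <- lapply(slabs, binarize_slab, params = params)
  exclusion <- NULL
  if (!is.null(maps$SCP)) {
    # detect from the global-threshold map: the local-median branch hollows
    # out wide bright structures (window median reaches the vessel level),
    # so the AND map under-segments exactly the vessels to be excluded
    scp_global <- threshold_binarize(slabs$SCP, huang_threshold(slabs$SCP))
    exclusion <- detect_large_vessels(
      scp_global, min_calibre_px = params$large_vessel_min_calibre_px,
      dilation_px = params$exclusion_dilation_px)
    for (plex in intersect(c("DCP", "CC"), names(maps))) {
      maps[[plex]] <- apply_exclusion(maps[[plex]], exclusion)
    }
  } else {
    warning("no SCP slab: skipping large-vessel exclusion")
  }
  out <- do.call(rbind, lapply(names(maps), function(plex) {
    img <- slabs[[plex]]
    region_metrics(maps[[plex]], roi, eye_id = img$eye_id, group = img$group)
  }))
  attr(out, "exclusion") <- exclusion
  out
}

# fill a config list with defaults
pipeline_config_defaults <- function() {
  list(mode = "synthetic", seed = 1L, out_dir = "octaquant_run",
       n_controls = 3L, n_cases = 3L, px_per_mm = 1024 / 12,
       image_px = NULL, laterality = "OD", input_dir = NULL,
       write_images = FALSE, synth = list(), cohort = list(), params = list())
}

#' Run the full quantification pipeline
#'
#' Orchestrates an end-to-end run: synthesize (or load) slab triples,
#' binarize, exclude large-vessel footprints, build the widefield ROI grid,
#' compute per-eye region metrics, and run the group-comparison and
#' correlation statistics. Every output is written under `out_dir` together
#' with a JSON parameter manifest; runs are deterministic given the seed.
#'
#' @param config a named list (see `pipeline_config_defaults` fields:
#'   `mode` "synthetic" or "directory", `seed`, `out_dir`, group sizes,
#'   `px_per_mm`, `synth`/`params` overrides, `input_dir` for directory
#'   mode), or the path of a YAML file holding one.
#' @return the output bundle: list with `metrics`, `comparisons`,
#'   `correlations`, `truth` (synthetic mode), `config`, `out_dir`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(pipeline_config_defaults(), config)
  params <- do.call(pipeline_params, cfg$params)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  truth <- NULL
  if (cfg$mode == "synthetic") {
    sp <- do.call(synth_params, utils::modifyList(list(seed = cfg$seed), cfg$synth))
    spec <- do.call(cohort_spec, utils::modifyList(
      list(n_controls = cfg$n_controls, n_cases = cfg$n_cases, seed = cfg$seed),
      cfg$cohort))
    cohort <- generate_cohort(spec, sp, render = "images", px_per_mm = cfg$px_per_mm)
    if (cfg$n_controls + cfg$n_cases == 0L) stop("empty cohort")
    truth <- cohort$truth
    eyes <- cohort$eyes
    rois <- cohort$rois
    get_roi <- function(eye) rois[[eye$laterality]]
    if (isTRUE(cfg$write_images)) write_cohort(cohort, file.path(cfg$out_dir, "slabs"))
  } else if (cfg$mode == "directory") {
    manifest <- utils::read.csv(file.path(cfg$input_dir, "manifest.csv"),
                                stringsAsFactors = FALSE)
    if (nrow(manifest) == 0L) stop("empty cohort")
    eyes <- list()
    roi_cache <- list()
    for (i in seq_len(nrow(manifest))) {
      row <- manifest[i, ]
      slabs <- list()
      ok <- TRUE
      for (plex in c("SCP", "DCP", "CC")) {
        hits <- Sys.glob(file.path(cfg$input_dir,
                                   sprintf("%s_%s.*", row$eye_id, plex)))
        img <- tryCatch(
          read_slab(hits[1], cfg$px_per_mm, plex, row$eye_id, row$group),
          error = function(e) NULL)
        if (is.null(img)) {
          warning(sprintf("eye %s: unreadable or missing %s slab, eye skipped",
                          row$eye_id, plex))
          ok <- FALSE
          break
        }
        slabs[[plex]] <- img
      }
      if (!ok) next
      eyes[[row$eye_id]] <- list(eye_id = row$eye_id, group = row$group,
                                 laterality = row$laterality, slabs = slabs,
                                 fovea = c(row$fovea_x, row$fovea_y))
    }
    if (length(eyes) == 0L) stop("no readable eyes in input directory")
    get_roi <- function(eye) {
      key <- paste(eye$laterality, paste(round(eye$fovea), collapse = ","))
      if (is.null(roi_cache[[key]])) {
        shape <- dim(eye$slabs[[1]]$pixels)
        roi_cache[[key]] <<- build_roi_set(cfg$px_per_mm, shape,
                                           fovea_center_px = eye$fovea,
                                           laterality = eye$laterality)
      }
      roi_cache[[key]]
    }
  } else {
    stop(sprintf("unknown mode '%s'", cfg$mode))
  }

  metrics <- do.call(rbind, lapply(eyes, function(eye) {
    message(sprintf("quantifying %s (%s)", eye$eye_id, eye$group))
    quantify_eye(eye$slabs, get_roi(eye), params)
  }))
  rownames(metrics) <- NULL
  utils::write.csv(metrics, file.path(cfg$out_dir, "metrics.csv"), row.names = FALSE)
  if (!is.null(truth)) {
    utils::write.csv(truth, file.path(cfg$out_dir, "truth.csv"), row.names = FALSE)
  }

  wide <- cohort_table(metrics)
  comparisons <- NULL
  correlations <- NULL
  both_groups <- all(c("control", "case") %in% wide$group)
  if (both_groups && min(table(wide$group)) >= 3) {
    vars <- setdiff(names(wide), c("eye_id", "group", "laterality"))
    comparisons <- compare_groups(wide, vars)
    utils::write.csv(comparisons, file.path(cfg$out_dir, "comparisons.csv"),
                     row.names = FALSE)
    central <- grep("_large_central_", vars, value = TRUE)
    peripheral <- grep("_(superior|temporal|inferior)_", vars, value = TRUE)
    correlations <- pearson_matrix(wide, central, peripheral, group = "group")
    utils::write.csv(correlations, file.path(cfg$out_dir, "correlations.csv"),
                     row.names = FALSE)
  } else {
    warning("fewer than 3 eyes in a group: comparison statistics skipped")
  }

  bundle <- list(metrics = tibble::as_tibble(metrics), comparisons = comparisons,
                 correlations = correlations, truth = truth, config = cfg,
                 out_dir = cfg$out_dir)
  manifest <- c(cfg[setdiff(names(cfg), c("synth", "params"))],
                list(synth = cfg$synth, params = unclass(params),
                     package_version = as.character(utils::packageVersion("octaquant"))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  report_path <- file.path(cfg$out_dir, "report.md")
  if (both_groups) {
    writeLines(make_report(bundle), report_path)
  }
  bundle
}

#' Render a human-readable summary of a run
#'
#' Produces a markdown report with one table per metric (perfusion density,
#' vessel length density): 3 plexuses x 6 regions rows, group mean +/- SD
#' columns, and the controls-minus-cases comparison when available.
#'
#' @param bundle output of [run_pipeline()] (needs `metrics` with both
#'   groups present).
#' @return character vector of markdown lines.
#' @export
make_report <- function(bundle) {
  m <- bundle$metrics
  if (is.null(m) || nrow(m) == 0) stop("incomplete bundle: no metrics")
  if (!all(c("control", "case") %in% m$group)) {
    stop("report needs both a control and a case group")
  }
  lines <- c("# Widefield OCTA quantification report", "")
  for (metric in c("pd", "vld")) {
    label <- if (metric == "pd") "Perfusion density (%)" else "Vessel length density (mm^-1)"
    lines <- c(lines, sprintf("## %s", label), "",
               "| Plexus | Region | Controls | Cases |",
               "|---|---|---|---|")
    for (plex in c("SCP", "DCP", "CC")) {
      for (rg in roi_regions()) {
        sel <- m$plexus == plex & m$region == rg
        if (!any(sel)) stop("incomplete bundle: missing plexus/region cells")
        fmt <- function(g) {
          v <- m[[metric]][sel & m$group == g]
          sprintf("%.2f ± %.2f", mean(v), stats::sd(v))
        }
        lines <- c(lines, sprintf("| %s | %s | %s | %s |",
                                  plex, rg, fmt("control"), fmt("case")))
      }
    }
    lines <- c(lines, "")
  }
  lines
}
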