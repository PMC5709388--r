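#' Analysis run configuration
#'
#' Collects every tunable of a full analysis run. The defaults are the
#' published workflow's operating point: adaptive-threshold sensitivity
#' 0.55 over a 65x65 px neighborhood, 1950 um^2 size threshold, a 2 px
#' background dilation radius, and a 0.4 multiplier on the Otsu live/dead
#' area thresholds.
#'
#' @param segmentation a \code{\link{segmentation_params}}.
#' @param background_radius dilation radius (px) for background estimation.
#' @param live_threshold_factor,dead_threshold_factor multipliers on the raw
#'   Otsu area thresholds.
#' @param normalize normalize viabilities to the no-treatment median.
#' @param dose_response_model model for the dose-response fit.
#' @param render_maps write viability heatmaps and live-area maps per image.
#' @return object of class \code{"run_config"}.
#' @export
run_config <- function(segmentation = segmentation_params(),
                       background_radius = 2L,
                       live_threshold_factor = 0.4,
                       dead_threshold_factor = 0.4,
                       normalize = TRUE,
                       dose_response_model = "exponential_decay",
                       render_maps = TRUE) {
  if (background_radius < 0) stop("background_radius must be >= 0")
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from a JSON file
#'
#' Recognized keys mirror the \code{\link{run_config}} and
#' \code{\link{segmentation_params}} arguments (segmentation keys live
#' under \code{"segmentation"}). Unknown keys raise an error so typos never
#' silently fall back to defaults.
#'
#' @param path JSON file.
#' @return a \code{\link{run_config}}.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::fromJSON(path)
  seg_args <- raw$segmentation %||% list()
  bad <- setdiff(names(seg_args), names(formals(segmentation_params)))
  if (length(bad)) stop("unknown segmentation key(s): ",
                        paste(bad, collapse = ", "))
  raw$segmentation <- NULL
  bad <- setdiff(names(raw), setdiff(names(formals(run_config)),
                                     "segmentation"))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  args <- c(list(segmentation = do.call(segmentation_params, seg_args)), raw)
  do.call(run_config, args)
}

# Segment one image set: brightfield mask + size filter, then the
# out-of-focus fluorescence filter. Returns the definitive label map and
# stage-wise object counts for the run log.
segment_image_set <- function(iset, params) {
  fg <- adaptive_binarize(iset$brightfield, params)
  pre <- label_and_size_filter(fg, segmentation_params(
    neighborhood_size = params$neighborhood_size,
    sensitivity = params$sensitivity, polarity = params$polarity,
    min_object_area = 0, connectivity = params$connectivity,
    otsu_bins = params$otsu_bins), iset$pixel_area)
  sized <- label_and_size_filter(fg, params, iset$pixel_area)
  final <- focus_filter(sized, iset$live, iset$dead, params)
  list(label_map = final,
       counts = c(pre_size_filter = length(pre$object_ids),
                  post_size_filter = length(sized$object_ids),
                  post_focus_filter = length(final$object_ids)))
}

#' Run the full analysis workflow on a plate
#'
#' Executes, in order: load all images; segment the no-treatment controls
#' (brightfield mask, size filter, focus filter); estimate the fluorescence
#' background from their dilated inverse masks; subtract it experiment-wide;
#' re-segment every image so the focus filter sees corrected fluorescence;
#' calibrate the fixed live (no-treatment) and dead (total-killing) area
#' thresholds; quantify every image nodule-by-nodule; normalize viabilities
#' to the no-treatment median; summarize groups, fit the dose response when
#' a dose series is present, fit the per-group viability-vs-area
#' regressions; and write the per-object CSV, group summary CSV, run-report
#' JSON and (optionally) per-image heatmap/live-map PNGs.
#'
#' @param manifest a \code{plate_manifest} (from \code{\link{read_manifest}})
#'   or a path to one.
#' @param config a \code{\link{run_config}}.
#' @param out_dir output directory; created if needed.
#' @param pixel_area pixel scale, required only when \code{manifest} is a
#'   CSV path without a pixel_area column.
#' @return (invisibly) a list: \code{records} (per-object data frame),
#'   \code{summaries}, \code{background}, \code{live_threshold},
#'   \code{dead_threshold}, \code{dose_response}, \code{regressions},
#'   \code{label_maps}, \code{report}.
#' @export
run_analyze <- function(manifest, config = run_config(), out_dir = NULL,
                        pixel_area = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest, pixel_area)
  validate_manifest(manifest)
  params <- config$segmentation
  sets <- lapply(seq_len(nrow(manifest)),
                 function(i) load_image_set(manifest[i, , drop = FALSE],
                                            attr(manifest, "pixel_area")))
  names(sets) <- manifest$well_id
  is_nt <- manifest$group == "no_treatment"
  is_tk <- manifest$group == "total_killing"

  # first-pass segmentation of the controls on raw fluorescence, for the
  # background estimate only
  nt_first <- lapply(sets[is_nt], function(s)
    list(image_set = s, label_map = segment_image_set(s, params)$label_map))
  bg <- estimate_background(nt_first, config$background_radius)

  corrected <- lapply(sets, subtract_background, bg = bg)

  # definitive segmentation: focus filter on corrected channels
  segs <- lapply(corrected, segment_image_set, params = params)
  lmaps <- lapply(segs, `[[`, "label_map")
  counts <- t(vapply(segs, `[[`, numeric(3), "counts"))

  pair <- function(keep) lapply(which(keep), function(i)
    list(image_set = corrected[[i]], label_map = lmaps[[i]]))
  live_thr <- calibrate_live_threshold(pair(is_nt),
                                       config$live_threshold_factor,
                                       bins = params$otsu_bins)
  dead_thr <- tryCatch(
    calibrate_dead_threshold(pair(is_tk), config$dead_threshold_factor,
                             bins = params$otsu_bins),
    error = function(e) NULL)

  records <- do.call(rbind, lapply(seq_along(corrected), function(i)
    quantify_objects(corrected[[i]], lmaps[[i]], live_thr, dead_thr)))
  if (config$normalize && any(!is.na(records$viability[records$group ==
                                                       "no_treatment"]))) {
    records <- normalize_viability(records,
                                   records[records$group == "no_treatment", ])
  }

  grp_key <- ifelse(records$group == "treatment",
                    paste0("treatment@", records$dose), records$group)
  summaries <- lapply(split(records, grp_key), summarize_group)

  tx <- records$group == "treatment"
  dose_fit <- NULL
  if (any(tx)) {
    med <- vapply(split(records$viability[tx], records$dose[tx]),
                  stats::median, numeric(1), na.rm = TRUE)
    dlev <- as.numeric(names(med))
    need <- if (config$dose_response_model == "linear") 3L else 4L
    if (length(dlev) >= need)
      dose_fit <- dose_response_fit(dlev, med, config$dose_response_model)
  }

  regressions <- lapply(split(records, grp_key), function(r) {
    tryCatch(linear_fit(r$total_area, r$viability), error = function(e) NULL)
  })

  report <- list(
    package_version = as.character(utils::packageVersion("OrganoidScreen")),
    n_images = nrow(manifest),
    pixel_area = attr(manifest, "pixel_area"),
    parameters = list(
      sensitivity = params$sensitivity,
      neighborhood_size = params$neighborhood_size,
      min_object_area = params$min_object_area,
      connectivity = params$connectivity,
      polarity = params$polarity,
      focus_mode = params$focus_mode,
      background_radius = config$background_radius,
      live_threshold_factor = config$live_threshold_factor,
      dead_threshold_factor = config$dead_threshold_factor,
      dose_response_model = config$dose_response_model,
      normalize = config$normalize),
    background = list(live = bg$live_background, dead = bg$dead_background,
                      n_images = bg$n_images),
    live_threshold = list(raw_otsu = live_thr$raw_otsu,
                          factor = live_thr$factor, value = live_thr$value),
    dead_threshold = if (!is.null(dead_thr))
      list(raw_otsu = dead_thr$raw_otsu, factor = dead_thr$factor,
           value = dead_thr$value),
    object_counts = as.data.frame(cbind(well_id = rownames(counts),
                                        as.data.frame(counts))),
    n_objects_total = nrow(records))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(records, file.path(out_dir, "per_object.csv"),
                     row.names = FALSE)
    sumdf <- do.call(rbind, lapply(names(summaries), function(k) {
      s <- summaries[[k]]
      data.frame(group = k, metric = names(s$mean_of_medians),
                 mean_of_medians = unname(s$mean_of_medians),
                 sd = unname(s$sd), sem = unname(s$sem),
                 n_images = s$n_images, row.names = NULL)
    }))
    utils::write.csv(sumdf, file.path(out_dir, "group_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(dose_fit))
      jsonlite::write_json(
        list(model = dose_fit$model, params = dose_fit$params,
             rss = dose_fit$rss, doses = dose_fit$doses,
             responses = dose_fit$responses),
        file.path(out_dir, "dose_response.json"), auto_unbox = TRUE,
        digits = NA, pretty = TRUE)
    if (isTRUE(config$render_maps)) {
      for (i in seq_along(lmaps)) {
        w <- names(lmaps)[i]
        r <- records[records$well_id == w, , drop = FALSE]
        write_map_png(render_viability_heatmap(lmaps[[i]], r),
                      file.path(out_dir, sprintf("%s_viability.png", w)))
        write_map_png(render_live_area_map(lmaps[[i]], corrected[[i]]$live,
                                           live_thr),
                      file.path(out_dir, sprintf("%s_livearea.png", w)))
      }
    }
  }

  invisible(list(records = records, summaries = summaries, background = bg,
                 live_threshold = live_thr, dead_threshold = dead_thr,
                 dose_response = dose_fit, regressions = regressions,
                 label_maps = lmaps, report = report))
}

#' Simulate a plate from a scene configuration
#'
#' Thin wrapper over \code{\link{simulate_plate}} accepting a preset name,
#' a \code{scene_config}, or a JSON file of \code{scene_config} arguments.
#'
#' @param config preset name, \code{\link{scene_config}}, or JSON path.
#' @param out_dir output directory.
#' @param ... passed to \code{\link{simulate_plate}}.
#' @return see \code{\link{simulate_plate}}.
#' @export
run_simulate <- function(config, out_dir, ...) {
  if (is.character(config)) {
    if (file.exists(config)) {
      args <- jsonlite::fromJSON(config)
      bad <- setdiff(names(args), names(formals(scene_config)))
      if (length(bad)) stop("unknown scene config key(s): ",
                            paste(bad, collapse = ", "))
      config <- do.call(scene_config, args)
    } else config <- scene_preset(config)
  }
  simulate_plate(config, out_dir, ...)
}
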