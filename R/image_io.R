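#' Experimental group labels
#'
#' Every image belongs to one of three groups: an untreated control
#' (\code{"no_treatment"}), a fixed-and-permeabilized total-killing control
#' (\code{"total_killing"}) that anchors the dead end of the dynamic range,
#' or a \code{"treatment"} well (optionally carrying a dose).
#' @keywords internal
GROUP_LEVELS <- c("no_treatment", "total_killing", "treatment")

#' Construct an image set
#'
#' Bundles one field of view's registered brightfield, live-channel
#' (calcein-AM) and dead-channel (propidium iodide) rasters together with the
#' physical pixel scale and experimental-group metadata. All downstream
#' operations consume and return this container.
#'
#' @param brightfield,live,dead numeric matrices of identical dimensions;
#'   intensities in arbitrary units, finite and non-negative.
#' @param pixel_area area covered by one pixel, in square micrometres.
#' @param well_id character well/field identifier.
#' @param group one of \code{"no_treatment"}, \code{"total_killing"},
#'   \code{"treatment"}.
#' @param dose optional scalar dose for treatment wells.
#' @param dose_unit optional unit label for \code{dose} (e.g. \code{"J/cm2"}).
#' @return An object of class \code{"image_set"}.
#' @export
image_set <- function(brightfield, live, dead, pixel_area, well_id = "well",
                      group = "treatment", dose = NA_real_,
                      dose_unit = NA_character_) {
  assert_raster(brightfield); assert_raster(live); assert_raster(dead)
  if (!identical(dim(brightfield), dim(live)) ||
      !identical(dim(brightfield), dim(dead)))
    stop("brightfield, live and dead rasters must have identical dimensions")
  if (min(brightfield) < 0 || min(live) < 0 || min(dead) < 0)
    stop("negative raw intensities are not allowed")
  if (!is.numeric(pixel_area) || length(pixel_area) != 1 || pixel_area <= 0)
    stop("pixel_area must be a positive scalar (um^2 per pixel)")
  group <- match.arg(group, GROUP_LEVELS)
  structure(
    list(brightfield = brightfield, live = live, dead = dead,
         pixel_area = pixel_area, well_id = as.character(well_id),
         group = group, dose = as.numeric(dose),
         dose_unit = as.character(dose_unit)),
    class = "image_set")
}

#' @export
print.image_set <- function(x, ...) {
  cat(sprintf("<image_set> %s  [%d x %d px, %.3f um^2/px]  group=%s%s\n",
              x$well_id, nrow(x$brightfield), ncol(x$brightfield),
              x$pixel_area, x$group,
              if (is.finite(x$dose)) sprintf(" dose=%g %s", x$dose,
                                             x$dose_unit) else ""))
  invisible(x)
}

#' Read a grayscale TIFF as a numeric matrix
#'
#' Integer rasters (8- or 16-bit) are returned at their native integer values
#' converted to double, so relative intensities within an experiment are never
#' rescaled. Float TIFFs are returned as stored. Multi-channel files are
#' reduced with \code{channel}.
#'
#' @param path file path.
#' @param channel for multi-channel TIFFs, which plane to extract (1-based).
#' @return numeric matrix.
#' @export
read_gray_tiff <- function(path, channel = NULL) {
  if (!file.exists(path)) stop(sprintf("image file not found: %s", path))
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3) {
    if (is.null(channel))
      stop(sprintf("multi-channel TIFF (%d planes) needs a channel index: %s",
                   dim(img)[3], path))
    img <- img[, , channel]
  }
  if (!is.matrix(img)) stop(sprintf("not a 2D grayscale raster: %s", path))
  storage.mode(img) <- "double"
  if (min(img) < 0) stop(sprintf("negative intensities in %s", path))
  img
}

#' Write a numeric matrix as a grayscale TIFF
#'
#' Integer-valued matrices round-trip exactly through
#' \code{\link{read_gray_tiff}} at the requested bit depth.
#'
#' @param img numeric matrix; values must fit the target bit depth.
#' @param path output path.
#' @param bits bits per sample, 8 or 16.
#' @export
write_gray_tiff <- function(img, path, bits = 16L) {
  assert_raster(img)
  maxval <- 2^bits - 1
  if (min(img) < 0 || max(img) > maxval)
    stop(sprintf("intensities out of range for %d-bit output", bits))
  tiff::writeTIFF(img / maxval, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Read a plate manifest
#'
#' The manifest assigns each image triplet to a well and experimental group.
#' Two on-disk forms are accepted: a CSV with columns \code{well_id},
#' \code{group}, \code{dose}, \code{dose_unit}, \code{path_brightfield},
#' \code{path_live}, \code{path_dead} (plus either a \code{pixel_area} column
#' or the \code{pixel_area} argument), or a JSON object with keys
#' \code{experiment_id}, \code{pixel_area} and \code{entries}. Relative image
#' paths are resolved against the manifest's directory.
#'
#' The pixel scale is deliberately a required input with no default: it must
#' come from the acquisition metadata of the experiment at hand.
#'
#' @param path manifest file (.csv or .json).
#' @param pixel_area pixel scale in um^2/px; required for CSV manifests that
#'   lack a \code{pixel_area} column.
#' @return A data frame of class \code{"plate_manifest"} with attributes
#'   \code{pixel_area} and \code{experiment_id}.
#' @export
read_manifest <- function(path, pixel_area = NULL) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  base <- dirname(path)
  if (ext == "json") {
    m <- jsonlite::fromJSON(path)
    entries <- as.data.frame(m$entries, stringsAsFactors = FALSE)
    pixel_area <- pixel_area %||% m$pixel_area
    experiment_id <- m$experiment_id %||% "experiment"
  } else if (ext == "csv") {
    entries <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (is.null(pixel_area)) {
      if (!"pixel_area" %in% names(entries))
        stop("pixel_area must be given: add a pixel_area column or argument")
      pixel_area <- unique(entries$pixel_area)
      if (length(pixel_area) != 1)
        stop("pixel_area column is not constant across the manifest")
    }
    experiment_id <- "experiment"
  } else stop("manifest must be .csv or .json")
  needed <- c("well_id", "group", "path_brightfield", "path_live", "path_dead")
  missing_cols <- setdiff(needed, names(entries))
  if (length(missing_cols))
    stop("manifest is missing columns: ", paste(missing_cols, collapse = ", "))
  if (!"dose" %in% names(entries)) entries$dose <- NA_real_
  if (!"dose_unit" %in% names(entries)) entries$dose_unit <- NA_character_
  bad <- setdiff(unique(entries$group), GROUP_LEVELS)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  for (col in c("path_brightfield", "path_live", "path_dead")) {
    rel <- !file.exists(entries[[col]])
    entries[[col]][rel] <- file.path(base, entries[[col]][rel])
  }
  if (!is.numeric(pixel_area) || length(pixel_area) != 1 || pixel_area <= 0)
    stop("pixel_area must be a positive scalar")
  structure(entries, class = c("plate_manifest", "data.frame"),
            pixel_area = as.numeric(pixel_area),
            experiment_id = as.character(experiment_id))
}

#' Validate a plate manifest for a full analysis run
#'
#' A full run needs both control groups to set the dynamic range: at least one
#' no-treatment and one total-killing entry. Also checks that every referenced
#' image file exists.
#'
#' @param manifest a \code{plate_manifest}.
#' @param require_controls if \code{TRUE} (default), fail when either control
#'   group is absent.
#' @return the manifest, invisibly, if valid.
#' @export
validate_manifest <- function(manifest, require_controls = TRUE) {
  if (require_controls) {
    for (g in c("no_treatment", "total_killing"))
      if (!any(manifest$group == g))
        stop(sprintf(paste0("manifest has no '%s' entries; analysis requires ",
                            "no-treatment and total-killing control groups"), g))
  }
  for (col in c("path_brightfield", "path_live", "path_dead")) {
    miss <- !file.exists(manifest[[col]])
    if (any(miss))
      stop("missing image file(s): ",
           paste(manifest[[col]][miss], collapse = ", "))
  }
  invisible(manifest)
}

#' Load one manifest entry as an image set
#'
#' @param entry one row of a \code{plate_manifest} (data frame with the
#'   manifest columns).
#' @param pixel_area pixel scale in um^2/px; defaults to the manifest
#'   attribute when \code{entry} is subset from a \code{plate_manifest}.
#' @param channel_order for multi-channel TIFFs, plane indices for
#'   brightfield, live and dead, in that order.
#' @return an \code{\link{image_set}}.
#' @export
load_image_set <- function(entry, pixel_area = attr(entry, "pixel_area"),
                           channel_order = NULL) {
  if (is.null(pixel_area)) stop("pixel_area is required")
  ch <- function(i) if (is.null(channel_order)) NULL else channel_order[i]
  bf <- read_gray_tiff(entry$path_brightfield, ch(1))
  lv <- read_gray_tiff(entry$path_live, ch(2))
  dd <- read_gray_tiff(entry$path_dead, ch(3))
  if (!identical(dim(bf), dim(lv)) || !identical(dim(bf), dim(dd)))
    stop(sprintf("channel shape mismatch for well %s", entry$well_id))
  image_set(bf, lv, dd, pixel_area = pixel_area, well_id = entry$well_id,
            group = entry$group, dose = entry$dose,
            dose_unit = entry$dose_unit %||% NA_character_)
}

#' Assemble four tiles into a 2x2 mosaic
#'
#' Confocal acquisition often covers a well with four 512x512 tiles; this
#' concatenates them seamlessly (top-left, top-right, bottom-left,
#' bottom-right) so organoids spanning tile seams become single objects
#' downstream.
#'
#' @param image_sets list of exactly four \code{image_set}s with identical
#'   shapes and pixel scale, from the same well.
#' @return a single \code{image_set} with doubled dimensions.
#' @export
tile_mosaic <- function(image_sets) {
  if (length(image_sets) != 4) stop("a mosaic requires exactly 4 tiles")
  dims <- lapply(image_sets, function(s) dim(s$brightfield))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all tiles must share the same dimensions")
  pas <- vapply(image_sets, function(s) s$pixel_area, numeric(1))
  if (length(unique(pas)) != 1) stop("all tiles must share the same pixel_area")
  wells <- unique(vapply(image_sets, function(s) s$well_id, character(1)))
  if (length(wells) != 1) stop("all tiles must come from the same well")
  stitch <- function(chan) {
    g <- lapply(image_sets, `[[`, chan)
    rbind(cbind(g[[1]], g[[2]]), cbind(g[[3]], g[[4]]))
  }
  s1 <- image_sets[[1]]
  image_set(stitch("brightfield"), stitch("live"), stitch("dead"),
            pixel_area = s1$pixel_area, well_id = s1$well_id,
            group = s1$group, dose = s1$dose, dose_unit = s1$dose_unit)
}
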