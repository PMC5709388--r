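#' Per-object mean channel intensity
#'
#' Arithmetic mean of a (background-corrected) channel over each indexed
#' object's pixels. The viability ratio is invariant to using sums instead of
#' means, since both channels integrate over the same pixel set; means are
#' reported for size-independent interpretability.
#'
#' @param lmap a \code{\link{label_map}}.
#' @param channel numeric matrix of the label map's shape.
#' @return named numeric vector, one mean per object id.
#' @export
object_intensities <- function(lmap, channel) {
  assert_raster(channel)
  if (!identical(dim(channel), dim(lmap$labels)))
    stop("channel shape must match the label map")
  n <- length(lmap$object_ids)
  if (n == 0L) return(stats::setNames(numeric(0), character(0)))
  idx <- lmap$labels > 0L
  sums <- rowsum(channel[idx], lmap$labels[idx])
  cnts <- tabulate(lmap$labels[idx], nbins = n)
  stats::setNames(as.numeric(sums) / cnts, rownames(sums))
}

#' Per-object viability ratio
#'
#' \code{viability = live / (live + dead)}, the intensity-ratio health metric
#' for one organoid: 1 = fully live, 0 = fully dead. When both intensities
#' are zero the ratio is undefined and \code{NA} is returned (the object is
#' still reported, so area statistics remain complete). Vectorized.
#'
#' @param mean_live,mean_dead non-negative mean channel intensities.
#' @return numeric in [0,1], or \code{NA} where both inputs are zero.
#' @export
viability <- function(mean_live, mean_dead) {
  if (any(mean_live < 0, na.rm = TRUE) || any(mean_dead < 0, na.rm = TRUE))
    stop("intensities must be non-negative (background-corrected and clipped)")
  tot <- mean_live + mean_dead
  out <- ifelse(tot > 0, mean_live / tot, NA_real_)
  as.numeric(out)
}

#' Calibrate the fixed live-area threshold on no-treatment controls
#'
#' One fixed threshold is applied to every image of an experiment to binarize
#' the live channel into viable vs non-viable area. Otsu's method is applied
#' to the pooled within-mask live pixels of the no-treatment group (where
#' total area equals live area) and the result multiplied by a factor
#' (default 0.4) that sets the dynamic range so total-killing controls yield
#' zero live area and untreated controls near-total live area.
#'
#' @param control_sets list of \code{list(image_set = , label_map = )} pairs,
#'   background-corrected, for the calibration group.
#' @param factor positive multiplier on the raw Otsu value.
#' @param channel \code{"live"} (default) or \code{"dead"}; the dead-area
#'   threshold is calibrated symmetrically on total-killing controls.
#' @param bins Otsu histogram bins.
#' @return object of class \code{"area_threshold"}: fields \code{raw_otsu},
#'   \code{factor}, \code{value}, \code{channel}.
#' @export
calibrate_live_threshold <- function(control_sets, factor = 0.4,
                                     channel = c("live", "dead"),
                                     bins = 256L) {
  channel <- match.arg(channel)
  if (!length(control_sets)) stop("need at least one control image")
  if (factor <= 0) stop("factor must be positive")
  pooled <- unlist(lapply(control_sets, function(cs) {
    cs$image_set[[channel]][cs$label_map$labels > 0L]
  }))
  if (!length(pooled)) stop("no within-mask pixels in the calibration group")
  raw <- otsu_threshold(pooled, bins)
  structure(list(raw_otsu = raw, factor = factor, value = raw * factor,
                 channel = channel),
            class = "area_threshold")
}

#' @rdname calibrate_live_threshold
#' @export
calibrate_dead_threshold <- function(control_sets, factor = 0.4,
                                     bins = 256L) {
  calibrate_live_threshold(control_sets, factor, channel = "dead", bins = bins)
}

#' @export
print.area_threshold <- function(x, ...) {
  cat(sprintf("<area_threshold> %s: %.4f (raw Otsu %.4f x factor %.2f)\n",
              x$channel, x$value, x$raw_otsu, x$factor))
  invisible(x)
}

# Shared worker: per-object thresholded area on one channel.
thresholded_area <- function(lmap, channel, threshold) {
  n <- length(lmap$object_ids)
  if (n == 0L)
    return(list(area = numeric(0), frac = numeric(0)))
  idx <- lmap$labels > 0L
  above <- channel[idx] > threshold       # strictly exceeding the threshold
  npos <- rowsum(above * 1, lmap$labels[idx])
  cnts <- tabulate(lmap$labels[idx], nbins = n)
  area <- as.numeric(npos) * lmap$pixel_area
  list(area = area, frac = as.numeric(npos) / cnts)
}

#' Per-object live area and fractional live area
#'
#' Counts each object's pixels whose background-corrected live intensity
#' strictly exceeds the calibrated threshold, converts to um^2, and divides
#' by the object's total (brightfield-derived) area for the fractional live
#' area.
#'
#' @param lmap a \code{\link{label_map}}.
#' @param live background-corrected live channel.
#' @param threshold an \code{area_threshold} from
#'   \code{\link{calibrate_live_threshold}}, or a bare scalar.
#' @return data frame with columns \code{object_id}, \code{live_area},
#'   \code{frac_live_area}.
#' @export
object_live_area <- function(lmap, live, threshold) {
  thr <- if (inherits(threshold, "area_threshold")) threshold$value else threshold
  res <- thresholded_area(lmap, live, thr)
  data.frame(object_id = lmap$object_ids, live_area = res$area,
             frac_live_area = res$frac)
}

#' Per-object dead area and fractional dead area
#'
#' Mirror of \code{\link{object_live_area}} on the dead channel, using a
#' threshold calibrated on total-killing controls.
#'
#' @inheritParams object_live_area
#' @param dead background-corrected dead channel.
#' @return data frame with columns \code{object_id}, \code{dead_area},
#'   \code{frac_dead_area}.
#' @export
object_dead_area <- function(lmap, dead, threshold) {
  thr <- if (inherits(threshold, "area_threshold")) threshold$value else threshold
  res <- thresholded_area(lmap, dead, thr)
  data.frame(object_id = lmap$object_ids, dead_area = res$area,
             frac_dead_area = res$frac)
}

#' Nodule-by-nodule quantification of one image
#'
#' Produces one row per indexed organoid: pixel and physical areas, mean
#' channel intensities, the viability ratio, thresholded live (and
#' optionally dead) areas with their fractions, and the 0-based centroid.
#' The object id is the label-map index, kept unique through the full
#' analysis so all readouts stay linked.
#'
#' @param iset a background-corrected \code{\link{image_set}}.
#' @param lmap the definitive (post-focus-filter) \code{\link{label_map}}.
#' @param live_threshold an \code{area_threshold} (or scalar) for the live
#'   channel.
#' @param dead_threshold optional \code{area_threshold} (or scalar) for the
#'   dead channel; when \code{NULL} the dead-area columns are \code{NA}.
#' @return data frame of organoid records, with \code{well_id}, \code{group}
#'   and \code{dose} prepended.
#' @export
quantify_objects <- function(iset, lmap, live_threshold,
                             dead_threshold = NULL) {
  ids <- lmap$object_ids
  n <- length(ids)
  if (n == 0L) {
    out <- data.frame(well_id = character(0), group = character(0),
                      dose = numeric(0), object_id = integer(0),
                      area_px = integer(0), total_area = numeric(0),
                      mean_live = numeric(0), mean_dead = numeric(0),
                      viability = numeric(0), live_area = numeric(0),
                      frac_live_area = numeric(0), dead_area = numeric(0),
                      frac_dead_area = numeric(0), centroid_row = numeric(0),
                      centroid_col = numeric(0))
    return(out)
  }
  idx <- which(lmap$labels > 0L)
  labs <- lmap$labels[idx]
  cnts <- tabulate(labs, nbins = n)
  nr <- nrow(lmap$labels)
  rows <- (idx - 1L) %% nr      # 0-based
  cols <- (idx - 1L) %/% nr
  mlive <- object_intensities(lmap, iset$live)
  mdead <- object_intensities(lmap, iset$dead)
  la <- object_live_area(lmap, iset$live, live_threshold)
  if (!is.null(dead_threshold)) {
    da <- object_dead_area(lmap, iset$dead, dead_threshold)
  } else {
    da <- data.frame(dead_area = rep(NA_real_, n),
                     frac_dead_area = rep(NA_real_, n))
  }
  data.frame(
    well_id = iset$well_id, group = iset$group, dose = iset$dose,
    object_id = ids,
    area_px = cnts,
    total_area = cnts * lmap$pixel_area,
    mean_live = as.numeric(mlive),
    mean_dead = as.numeric(mdead),
    viability = viability(as.numeric(mlive), as.numeric(mdead)),
    live_area = la$live_area,
    frac_live_area = la$frac_live_area,
    dead_area = da$dead_area,
    frac_dead_area = da$frac_dead_area,
    centroid_row = as.numeric(rowsum(rows, labs)) / cnts,
    centroid_col = as.numeric(rowsum(cols, labs)) / cnts)
}

#' Normalize viabilities to the no-treatment control group
#'
#' Divides each record's viability by the median viability of the
#' no-treatment control records, the conventional presentation of treated
#' groups relative to untreated cultures. Monotone, so within-group ordering
#' is preserved; undefined viabilities stay \code{NA}.
#'
#' @param records data frame of organoid records (from
#'   \code{\link{quantify_objects}}).
#' @param control_records records of the no-treatment group.
#' @return \code{records} with a \code{normalized_viability} column.
#' @export
normalize_viability <- function(records, control_records) {
  cv <- control_records$viability
  cv <- cv[!is.na(cv)]
  if (!length(cv)) stop("control records carry no defined viability")
  m <- stats::median(cv)
  if (m == 0) stop("control median viability is zero: cannot normalize")
  records$normalized_viability <- records$viability / m
  records
}
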