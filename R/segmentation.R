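#' Segmentation parameters
#'
#' Parameters of the brightfield masking stage. Defaults follow the published
#' workflow: adaptive local-mean thresholding at sensitivity 0.55 over a
#' 65x65 px neighborhood, a 1950 um^2 minimum object size (about five
#' clustered cells of 400 um^2), dark objects on a bright background, and
#' 8-connectivity so touching organoid lobes count as one nodule.
#'
#' @param neighborhood_size odd window side, in pixels, for the local mean.
#' @param sensitivity scalar in (0,1); 0.5 reduces to plain local-mean
#'   thresholding, the default 0.55 demands a 10\% deviation above it.
#' @param polarity \code{"dark_objects"} (transmitted-light silhouettes,
#'   default) or \code{"bright_objects"}.
#' @param min_object_area minimum retained object area in um^2.
#' @param connectivity pixel connectivity for labeling, 4 or 8.
#' @param otsu_bins histogram bins for Otsu thresholding.
#' @param fill_holes fill interior holes of the brightfield mask before
#'   labeling. Off by default: interior holes are handled implicitly by the
#'   fluorescence intersection.
#' @param focus_mode how the out-of-focus filter applies the fluorescence
#'   binarization: \code{"pixelwise"} (intersect masks, then re-apply the size
#'   filter) or \code{"whole_object"} (drop objects whose in-focus fraction is
#'   below one half, keeping survivors' full extent).
#' @return object of class \code{"segmentation_params"}.
#' @export
segmentation_params <- function(neighborhood_size = 65L, sensitivity = 0.55,
                                polarity = c("dark_objects", "bright_objects"),
                                min_object_area = 1950, connectivity = 8L,
                                otsu_bins = 256L, fill_holes = FALSE,
                                focus_mode = c("pixelwise", "whole_object")) {
  polarity <- match.arg(polarity)
  focus_mode <- match.arg(focus_mode)
  if (neighborhood_size < 3 || neighborhood_size %% 2 == 0)
    stop("neighborhood_size must be odd and >= 3")
  if (sensitivity <= 0 || sensitivity >= 1)
    stop("sensitivity must lie strictly between 0 and 1")
  if (min_object_area < 0) stop("min_object_area must be >= 0")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  if (otsu_bins < 2) stop("otsu_bins must be >= 2")
  structure(list(neighborhood_size = as.integer(neighborhood_size),
                 sensitivity = sensitivity, polarity = polarity,
                 min_object_area = min_object_area,
                 connectivity = as.integer(connectivity),
                 otsu_bins = as.integer(otsu_bins),
                 fill_holes = isTRUE(fill_holes), focus_mode = focus_mode),
            class = "segmentation_params")
}

#' Local mean filter
#'
#' Mean intensity over a square window centered at each pixel, with replicate
#' padding at the borders (edge rows/columns extended outward), the basis of
#' the adaptive threshold.
#'
#' @param image numeric matrix.
#' @param window odd window side in pixels, at most \code{min(dim(image))}.
#' @return numeric matrix of the same dimensions.
#' @export
local_mean <- function(image, window) {
  assert_raster(image)
  if (window %% 2 == 0 || window < 1) stop("window must be an odd positive integer")
  if (window > min(dim(image)))
    stop("window exceeds the image dimensions")
  kern <- matrix(1 / window^2, window, window)
  as.matrix(EBImage::filter2(image, kern, boundary = "replicate"))
}

#' Adaptive local-mean binarization
#'
#' Non-uniform illumination defeats any single global threshold on
#' brightfield images, so each pixel is compared against a threshold derived
#' from its own neighborhood. The image is first min-max rescaled to [0,1];
#' for dark objects the working image is the complement \code{1 - I}. A pixel
#' is foreground when its working value exceeds
#' \code{2 * sensitivity} times the local mean of the working image, so
#' sensitivity 0.5 is plain local-mean thresholding.
#'
#' @param image numeric matrix, finite and non-negative.
#' @param params a \code{\link{segmentation_params}}.
#' @return logical matrix (TRUE = foreground).
#' @export
adaptive_binarize <- function(image, params = segmentation_params()) {
  assert_raster(image)
  scaled <- rescale01(image)
  if (is.null(scaled)) {
    warning("constant image: rescaling undefined, returning empty foreground")
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  work <- if (params$polarity == "dark_objects") 1 - scaled else scaled
  fg <- work > (2 * params$sensitivity) * local_mean(work, params$neighborhood_size)
  if (params$fill_holes)
    fg <- as.matrix(EBImage::fillHull(fg * 1)) > 0
  fg
}

# Union-find with path compression, used to merge label equivalences.
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Connected-component labeling
#'
#' Labels connected foreground regions under 4- or 8-connectivity. Labels are
#' assigned 1..N in raster-scan order (top row first, left to right) of each
#' component's first pixel, so labeling is fully deterministic.
#'
#' @param binary logical or 0/1 matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix, 0 = background.
#' @export
label_components <- function(binary, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  lab <- as.matrix(EBImage::bwlabel(binary * 1))  # 4-connectivity pass
  storage.mode(lab) <- "integer"
  nlab <- max(lab)
  if (nlab == 0L) return(lab)
  if (connectivity == 8L && nlab > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    # merge components touching only diagonally
    a <- c(lab[-nr, -nc], lab[-nr, -1])      # up-left of down-right, up-right of down-left
    b <- c(lab[-1, -1],  lab[-1, -nc])
    keep <- a > 0L & b > 0L & a != b
    if (any(keep)) {
      pairs <- unique(cbind(a[keep], b[keep]))
      parent <- seq_len(nlab)
      for (k in seq_len(nrow(pairs))) {
        ra <- uf_find(parent, pairs[k, 1]); rb <- uf_find(parent, pairs[k, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      roots <- vapply(seq_len(nlab), function(i) uf_find(parent, i), integer(1))
      lab[lab > 0L] <- roots[lab[lab > 0L]]
    }
  }
  relabel_raster_order(lab)
}

# Renumber labels 1..N by raster-scan order (row-major) of each component's
# topmost-leftmost pixel.
relabel_raster_order <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  if (!length(ids)) {
    storage.mode(lab) <- "integer"
    return(lab)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  idx <- which(lab > 0L)
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  rmaj <- (row - 1L) * nc + col
  first <- tapply(rmaj, lab[idx], min)
  order_ids <- as.integer(names(first))[order(first)]
  map <- integer(max(ids)); map[order_ids] <- seq_along(order_ids)
  out <- lab
  out[idx] <- map[lab[idx]]
  storage.mode(out) <- "integer"
  out
}

#' Construct a label map container
#'
#' @param labels integer matrix, 0 background, 1..N objects (contiguous).
#' @param pixel_area um^2 per pixel.
#' @return object of class \code{"label_map"} with fields \code{labels},
#'   \code{pixel_area} and \code{object_ids}.
#' @export
label_map <- function(labels, pixel_area) {
  storage.mode(labels) <- "integer"
  n <- if (length(labels)) max(labels) else 0L
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) && !identical(ids, seq_len(n)))
    stop("labels must be contiguous 1..N")
  structure(list(labels = labels, pixel_area = as.numeric(pixel_area),
                 object_ids = ids),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d x %d px, %d objects, %.3f um^2/px\n",
              nrow(x$labels), ncol(x$labels), length(x$object_ids),
              x$pixel_area))
  invisible(x)
}

#' Label foreground and remove sub-threshold objects
#'
#' Connected components smaller than \code{min_object_area} (culture debris,
#' individual migrating cells) are discarded; retention is inclusive at
#' exactly the threshold. Survivors are relabeled 1..N in raster-scan order.
#'
#' @param binary logical or 0/1 matrix.
#' @param params a \code{\link{segmentation_params}}.
#' @param pixel_area um^2 per pixel.
#' @return a \code{\link{label_map}}.
#' @export
label_and_size_filter <- function(binary, params = segmentation_params(),
                                  pixel_area) {
  lab <- label_components(binary, params$connectivity)
  if (max(lab) > 0L) {
    px <- tabulate(lab[lab > 0L], nbins = max(lab))
    drop <- which(px * pixel_area < params$min_object_area)
    if (length(drop)) {
      lab[lab %in% drop] <- 0L
      lab <- relabel_raster_order(lab)
    }
  }
  label_map(lab, pixel_area)
}

#' Otsu threshold of an intensity sample
#'
#' Builds an equal-width histogram over the sample range and returns the
#' interior bin edge that maximizes the between-class variance (equivalently,
#' minimizes the pooled within-class variance). Class means are computed from
#' bin midpoints. Ties are broken toward the lowest qualifying edge.
#'
#' @param values numeric vector with at least two distinct values.
#' @param bins number of histogram bins.
#' @return scalar threshold (a histogram bin edge, on the input scale).
#' @export
otsu_threshold <- function(values, bins = 256L) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need at least two values")
  rng <- range(values)
  if (rng[1] == rng[2])
    stop("constant sample: no separable classes for Otsu thresholding")
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  bin <- pmin(pmax(findInterval(values, breaks, rightmost.closed = TRUE), 1L),
              bins)
  counts <- tabulate(bin, nbins = bins)
  mids <- (breaks[-1] + breaks[-(bins + 1)]) / 2
  w <- cumsum(counts)                 # pixels at or below edge k (bins 1..k)
  m <- cumsum(counts * mids)
  n <- w[bins]; mtot <- m[bins]
  k <- seq_len(bins - 1)
  w0 <- w[k]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, bins - 1)
  mu0 <- m[k][valid] / w0[valid]
  mu1 <- (mtot - m[k][valid]) / w1[valid]
  bcv[valid] <- (w0[valid] / n) * (w1[valid] / n) * (mu0 - mu1)^2
  best <- which(bcv == max(bcv))[1]   # ties -> lowest edge
  breaks[best + 1]
}

#' Out-of-focus object filter
#'
#' Organoids visible in brightfield but out of the imaged focal plane carry
#' almost no fluorescence; keeping them would corrupt every intensity
#' readout. The live and dead channels are summed, min-max rescaled to [0,1],
#' and binarized by Otsu's method over all pixels; the brightfield mask is
#' then intersected with that binarization. In the default pixelwise mode the
#' size filter is re-applied afterwards (the intersection can shrink objects
#' below the size threshold) and survivors are relabeled; the result is the
#' definitive index set for all downstream analysis. In whole-object mode an
#' object is dropped when less than half its pixels are fluorescence-positive
#' and survivors keep their full brightfield extent.
#'
#' @param lmap a \code{\link{label_map}} from the brightfield mask.
#' @param live,dead numeric matrices matching the label map's shape.
#' @param params a \code{\link{segmentation_params}}.
#' @return a \code{\link{label_map}}.
#' @export
focus_filter <- function(lmap, live, dead, params = segmentation_params()) {
  assert_raster(live); assert_raster(dead)
  if (!identical(dim(live), dim(lmap$labels)) ||
      !identical(dim(dead), dim(lmap$labels)))
    stop("fluorescence rasters must match the label map's shape")
  s <- rescale01(live + dead)
  if (is.null(s)) {
    warning("constant summed fluorescence: all objects removed")
    return(label_map(matrix(0L, nrow(lmap$labels), ncol(lmap$labels)),
                     lmap$pixel_area))
  }
  b <- s > otsu_threshold(as.vector(s), params$otsu_bins)
  if (params$focus_mode == "pixelwise") {
    fg <- lmap$labels > 0L & b
    label_and_size_filter(fg, params, lmap$pixel_area)
  } else {
    lab <- lmap$labels
    if (max(lab) > 0L) {
      idx <- lab > 0L
      frac <- tapply(b[idx], lab[idx], mean)
      drop <- as.integer(names(frac))[frac < 0.5]
      if (length(drop)) lab[lab %in% drop] <- 0L
      lab <- relabel_raster_order(lab)
    }
    label_and_size_filter(lab > 0L, params, lmap$pixel_area)
  }
}

#' Segment the brightfield image of an image set
#'
#' Convenience wrapper chaining \code{\link{adaptive_binarize}} and
#' \code{\link{label_and_size_filter}} on the brightfield channel. Apply
#' \code{\link{focus_filter}} afterwards (with background-corrected
#' fluorescence) to obtain the definitive label map.
#'
#' @param iset an \code{\link{image_set}}.
#' @param params a \code{\link{segmentation_params}}.
#' @return a \code{\link{label_map}}.
#' @export
segment_brightfield <- function(iset, params = segmentation_params()) {
  fg <- adaptive_binarize(iset$brightfield, params)
  label_and_size_filter(fg, params, iset$pixel_area)
}
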