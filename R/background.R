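#' Dilate an object mask with a discrete disk
#'
#' Used before inverting the mask for background estimation, so that pixels
#' hugging organoid boundaries (partial-volume fluorescence) do not leak into
#' the background sample. The structuring element contains offset (i, j) iff
#' \code{i^2 + j^2 <= radius^2}; radius 2 gives the 13-pixel discrete disk.
#'
#' @param lmap a \code{\link{label_map}}, or a logical matrix.
#' @param radius non-negative integer radius in pixels.
#' @return logical matrix (TRUE = inside the dilated mask).
#' @export
dilate_mask <- function(lmap, radius = 2L) {
  mask <- if (inherits(lmap, "label_map")) lmap$labels > 0L else lmap > 0
  if (radius < 0 || radius != round(radius))
    stop("radius must be a non-negative integer")
  if (radius == 0L) return(mask)
  off <- seq(-radius, radius)
  kern <- outer(off, off, function(i, j) (i^2 + j^2 <= radius^2) * 1)
  as.matrix(EBImage::dilate(mask * 1, kern)) > 0
}

#' Estimate fluorescence background from no-treatment controls
#'
#' Bright loci from detached cells and debris litter the inter-organoid
#' space, so a mean would overcorrect; the median is robust to them. Per
#' control image and channel, the median intensity over pixels outside the
#' dilated object mask is taken; per channel, those medians are averaged
#' across images.
#'
#' @param control_sets list of \code{list(image_set = , label_map = )} pairs
#'   for the no-treatment group, each label map being that image's final
#'   (post-focus-filter) segmentation.
#' @param radius dilation radius in pixels (default 2).
#' @return object of class \code{"background_estimate"}: fields
#'   \code{live_background}, \code{dead_background}, \code{n_images}.
#' @export
estimate_background <- function(control_sets, radius = 2L) {
  if (!length(control_sets)) stop("need at least one control image")
  med <- vapply(control_sets, function(cs) {
    outside <- !dilate_mask(cs$label_map, radius)
    if (mean(outside) < 0.01)
      stop("dilated mask covers >= 99% of an image: no background sample")
    c(stats::median(cs$image_set$live[outside]),
      stats::median(cs$image_set$dead[outside]))
  }, numeric(2))
  structure(list(live_background = mean(med[1, ]),
                 dead_background = mean(med[2, ]),
                 n_images = length(control_sets)),
            class = "background_estimate")
}

#' @export
print.background_estimate <- function(x, ...) {
  cat(sprintf("<background_estimate> live=%.3f dead=%.3f (n=%d images)\n",
              x$live_background, x$dead_background, x$n_images))
  invisible(x)
}

#' Subtract the estimated background from an image set
#'
#' Applied uniformly to every image of an experiment, controls and treated
#' wells alike. Results are clipped at zero: negative intensities are
#' non-physical and would corrupt the viability ratio. Brightfield is left
#' untouched.
#'
#' @param iset an \code{\link{image_set}}.
#' @param bg a \code{\link{estimate_background}} result.
#' @return a corrected \code{\link{image_set}}.
#' @export
subtract_background <- function(iset, bg) {
  if (!all(is.finite(c(bg$live_background, bg$dead_background))))
    stop("background estimate must be finite")
  out <- iset
  out$live <- pmax(iset$live - bg$live_background, 0)
  out$dead <- pmax(iset$dead - bg$dead_background, 0)
  out
}
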