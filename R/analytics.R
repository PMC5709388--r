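#' Group summary: mean of the per-image medians
#'
#' Pooling all organoids of a group would let crowded images dominate, so
#' the summary statistic is the median of each metric per image, then the
#' mean (with SD and SEM) of those medians across the group's images.
#' Undefined viabilities are excluded from medians; images with zero objects
#' contribute no median and are counted in \code{dropped_images}.
#'
#' @param records data frame of organoid records with a \code{well_id}
#'   column identifying the image each row came from.
#' @param metrics character vector of record columns to summarize.
#' @return object of class \code{"group_summary"}: per-image medians plus
#'   mean/sd/sem per metric.
#' @export
summarize_group <- function(records,
                            metrics = c("total_area", "frac_live_area",
                                        "viability")) {
  wells <- unique(records$well_id)
  n_total <- length(wells)
  if (!nrow(records) || !n_total) stop("need at least one image with objects")
  per_image <- lapply(metrics, function(m) {
    med <- vapply(wells, function(w) {
      v <- records[[m]][records$well_id == w]
      v <- v[!is.na(v)]
      if (length(v)) stats::median(v) else NA_real_
    }, numeric(1))
    med
  })
  names(per_image) <- metrics
  kept <- !Reduce(`|`, lapply(per_image, is.na))
  per_image <- lapply(per_image, function(v) v[kept])
  n <- sum(kept)
  if (!n) stop("every image was dropped (no objects with defined metrics)")
  stat <- function(f) vapply(per_image, f, numeric(1))
  mean_of_medians <- stat(mean)
  sd_ <- if (n > 1) stat(stats::sd) else stat(function(v) 0)
  structure(list(group = unique(records$group),
                 dose = unique(records$dose),
                 n_images = n,
                 dropped_images = n_total - n,
                 per_image_medians = per_image,
                 mean_of_medians = mean_of_medians,
                 sd = sd_,
                 sem = sd_ / sqrt(n)),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> %s%s: %d image(s)%s\n",
              paste(x$group, collapse = "/"),
              if (any(is.finite(x$dose))) sprintf(" dose=%g", x$dose[1]) else "",
              x$n_images,
              if (x$dropped_images) sprintf(" (%d dropped)", x$dropped_images)
              else ""))
  for (m in names(x$mean_of_medians))
    cat(sprintf("  %-16s mean of medians %.4g (sd %.3g, sem %.3g)\n", m,
                x$mean_of_medians[[m]], x$sd[[m]], x$sem[[m]]))
  invisible(x)
}

#' Histogram counts of a per-object metric
#'
#' Bins are left-closed, right-open; the last bin additionally includes its
#' right edge, so edges spanning the data range conserve the count of
#' non-missing values.
#'
#' @param records data frame of organoid records, or a numeric vector.
#' @param metric column name when \code{records} is a data frame.
#' @param bin_edges strictly increasing numeric vector of bin boundaries.
#' @return integer vector of counts, length \code{length(bin_edges) - 1}.
#' @export
metric_histogram <- function(records, metric = NULL, bin_edges) {
  x <- if (is.data.frame(records)) records[[metric]] else records
  x <- x[!is.na(x)]
  if (length(bin_edges) < 2 || any(diff(bin_edges) <= 0))
    stop("bin_edges must be strictly increasing")
  x <- x[x >= bin_edges[1] & x <= bin_edges[length(bin_edges)]]
  bin <- findInterval(x, bin_edges, rightmost.closed = TRUE)
  tabulate(bin, nbins = length(bin_edges) - 1)
}

#' Ordinary least-squares fit between two per-object readouts
#'
#' Used for the pairwise correlations between viability, size and fractional
#' live area that distinguish size-dependent from homogeneous treatment
#' effects.
#'
#' @param x,y numeric vectors; at least 3 finite pairs, \code{x} not
#'   constant.
#' @return object of class \code{"regression_fit"}: \code{slope},
#'   \code{intercept}, \code{r_squared}, \code{n_points}.
#' @export
linear_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 finite pairs")
  if (stats::var(x) == 0) stop("x is constant: slope undefined")
  fit <- stats::lm.fit(cbind(1, x), y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  structure(list(slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 r_squared = if (tss > 0) 1 - rss / tss else 1,
                 n_points = length(x)),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> slope=%.4g intercept=%.4g r2=%.4f (n=%d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

# Profiled RSS of the exponential-decay model at a fixed rate k:
# R(d) = plateau + A * exp(-k d) is linear in (plateau, A) given k, so the
# inner problem is solved in closed form, with non-negativity of plateau and
# R0 = plateau + A enforced by projection.
.expdecay_profile <- function(k, d, y) {
  if (k == 0) {
    mu <- max(mean(y), 0)
    return(list(rss = sum((y - mu)^2), plateau = mu, r0 = mu))
  }
  e <- exp(-k * d)
  fit <- stats::lm.fit(cbind(1, e), y)
  plateau <- unname(fit$coefficients[1]); a <- unname(fit$coefficients[2])
  if (!is.finite(plateau) || !is.finite(a)) return(list(rss = Inf))
  if (plateau < 0 || plateau + a < 0) {
    # project onto the feasible boundary: plateau = 0, A >= 0
    a <- max(sum(y * e) / sum(e^2), 0)
    plateau <- 0
  }
  pred <- plateau + a * e
  list(rss = sum((y - pred)^2), plateau = plateau, r0 = plateau + a)
}

#' Least-squares dose-response fit
#'
#' Fits \code{response = plateau + (R0 - plateau) * exp(-k * dose)} with
#' \code{R0, plateau, k >= 0} (default), or a straight line. The decay fit
#' profiles out the linear coefficients at each rate, scans a fixed
#' logarithmic grid of rates (plus zero), and polishes the best bracket by
#' golden-section search, so the result is deterministic; RSS ties resolve
#' to the smallest rate.
#'
#' @param doses,responses numeric vectors of equal length.
#' @param model \code{"exponential_decay"} (default) or \code{"linear"}.
#' @return object of class \code{"dose_response_fit"}: \code{model},
#'   \code{params} (named list), \code{rss}, \code{doses}, \code{responses}.
#' @export
dose_response_fit <- function(doses, responses,
                              model = c("exponential_decay", "linear")) {
  model <- match.arg(model)
  ok <- is.finite(doses) & is.finite(responses)
  d <- doses[ok]; y <- responses[ok]
  npar <- if (model == "linear") 2L else 3L
  if (length(unique(d)) < npar + 1L)
    stop(sprintf("need at least %d distinct dose levels for the %s model",
                 npar + 1L, model))
  if (model == "linear") {
    lf <- linear_fit(d, y)
    pred <- lf$intercept + lf$slope * d
    return(structure(list(model = model,
                          params = list(slope = lf$slope,
                                        intercept = lf$intercept),
                          rss = sum((y - pred)^2),
                          doses = d, responses = y),
                     class = "dose_response_fit"))
  }
  dmax <- max(d[d > 0])
  kgrid <- c(0, 10^seq(log10(0.01 / dmax), log10(100 / dmax), length.out = 61))
  prof <- vapply(kgrid, function(k) .expdecay_profile(k, d, y)$rss, numeric(1))
  best <- which(prof == min(prof))[1]            # ties -> smallest k
  lo <- kgrid[max(best - 1, 1)]; hi <- kgrid[min(best + 1, length(kgrid))]
  k <- if (lo < hi) {
    stats::optimize(function(k) .expdecay_profile(k, d, y)$rss,
                    interval = c(lo, hi), tol = 1e-12)$minimum
  } else kgrid[best]
  cand <- rbind(c(k, .expdecay_profile(k, d, y)$rss),
                c(kgrid[best], prof[best]))
  k <- cand[which.min(cand[, 2]), 1]
  sol <- .expdecay_profile(k, d, y)
  structure(list(model = model,
                 params = list(r0 = sol$r0, plateau = sol$plateau, k = k),
                 rss = sol$rss, doses = d, responses = y),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (x$model == "linear") {
    cat(sprintf("<dose_response_fit> linear: slope=%.4g intercept=%.4g rss=%.4g\n",
                x$params$slope, x$params$intercept, x$rss))
  } else {
    cat(sprintf("<dose_response_fit> R(d) = %.4g + (%.4g - %.4g) exp(-%.4g d), rss=%.4g\n",
                x$params$plateau, x$params$r0, x$params$plateau, x$params$k,
                x$rss))
  }
  invisible(x)
}

#' Predict from a dose-response fit
#'
#' @param object a \code{dose_response_fit}.
#' @param doses doses at which to evaluate the fitted curve (defaults to the
#'   fitted doses).
#' @param ... unused.
#' @return numeric vector of fitted responses.
#' @export
predict.dose_response_fit <- function(object, doses = object$doses, ...) {
  p <- object$params
  if (object$model == "linear") p$intercept + p$slope * doses
  else p$plateau + (p$r0 - p$plateau) * exp(-p$k * doses)
}

#' Render a per-object viability heatmap
#'
#' Paints each organoid's pixels with its (optionally normalized) viability
#' through a documented colormap; background is black and objects with
#' undefined viability use a sentinel color. Values are clamped to [0,1]
#' before color lookup (normalized viabilities can exceed 1). A fully killed
#' well therefore renders completely dark.
#'
#' @param lmap a \code{\link{label_map}}.
#' @param records organoid records covering every label id, with a
#'   \code{viability} (or \code{normalized_viability}) column.
#' @param normalized use \code{normalized_viability} instead of
#'   \code{viability}.
#' @param colormap vector of colors interpolated over [0,1]; default 256-step
#'   viridis.
#' @param missing_color sentinel color for undefined viability.
#' @return array [rows, cols, 3] of RGB values in [0,1].
#' @export
render_viability_heatmap <- function(lmap, records, normalized = FALSE,
                                     colormap = grDevices::hcl.colors(256, "viridis"),
                                     missing_color = "magenta") {
  col <- if (normalized) "normalized_viability" else "viability"
  vals <- records[[col]][match(lmap$object_ids, records$object_id)]
  if (length(lmap$object_ids) && anyNA(match(lmap$object_ids, records$object_id)))
    stop("records must cover every label id")
  nstep <- length(colormap)
  rgbmap <- t(grDevices::col2rgb(colormap) / 255)
  sentinel <- as.numeric(grDevices::col2rgb(missing_color) / 255)
  out <- array(0, c(nrow(lmap$labels), ncol(lmap$labels), 3))
  for (i in seq_along(lmap$object_ids)) {
    id <- lmap$object_ids[i]
    pix <- which(lmap$labels == id)
    if (is.na(vals[i])) {
      rgbv <- sentinel
    } else {
      v <- min(max(vals[i], 0), 1)
      rgbv <- rgbmap[1 + round(v * (nstep - 1)), ]
    }
    for (ch in 1:3) out[pix + (ch - 1) * length(lmap$labels)] <- rgbv[ch]
  }
  out
}

#' Render the binary live-area map
#'
#' White where an object pixel's background-corrected live intensity strictly
#' exceeds the calibrated threshold, black elsewhere; by construction a
#' subset of the object mask. Total-killing wells render all black.
#'
#' @param lmap a \code{\link{label_map}}.
#' @param live background-corrected live channel.
#' @param threshold an \code{area_threshold} or scalar.
#' @return logical matrix (TRUE = live pixel).
#' @export
render_live_area_map <- function(lmap, live, threshold) {
  thr <- if (inherits(threshold, "area_threshold")) threshold$value else threshold
  lmap$labels > 0L & live > thr
}

#' Write an RGB array or binary map as a PNG file
#'
#' @param img array [rows, cols, 3] in [0,1], or a logical/0-1 matrix.
#' @param path output path.
#' @export
write_map_png <- function(img, path) {
  if (is.matrix(img)) img <- array(rep(img * 1, 3), c(dim(img), 3))
  png::writePNG(img, path)
  invisible(path)
}
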