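#' Synthetic scene configuration
#'
#' Describes a simulated well: organoid count and log-normal size
#' distribution, lobed non-spheroidal shapes (heterotypic-coculture mimic),
#' a core-shell viability gradient (hypoxic-core mimic), multiplicative
#' illumination gradient, per-channel backgrounds, Gaussian plus
#' signal-dependent noise, sub-threshold debris, detached bright single
#' cells in inter-organoid space, and a fraction of organoids rendered
#' out-of-focus (fluorescence attenuated and blurred, brightfield silhouette
#' unchanged). The seed fixes every random draw.
#'
#' @param image_shape rows, cols in pixels.
#' @param pixel_area um^2 per pixel.
#' @param n_organoids organoids to place.
#' @param size_meanlog,size_sdlog log-normal parameters of true organoid
#'   area, in um^2.
#' @param lobes integer range of ellipse lobes per organoid; more than one
#'   lobe yields non-spheroidal unions of overlapping ellipses.
#' @param core_shell_depth viability drop from rim to center, in [0,1]:
#'   per-pixel viability is \code{base * (1 - depth * d)} with \code{d} the
#'   normalized distance from the organoid boundary (1 at the center), so
#'   cores are least viable.
#' @param base_viability_range per-organoid baseline viability is drawn
#'   uniformly from this range; \code{c(1, 1)} models healthy untreated
#'   cultures, a wide range models heterogeneous treatment response.
#' @param illumination_gradient multiplicative brightfield illumination
#'   range across the field of view.
#' @param background named per-channel background levels (a.u., 16-bit
#'   scale): \code{brightfield}, \code{live}, \code{dead}.
#' @param fluor_gain fluorescence signal amplitude (a.u.) for viability 1.
#' @param silhouette fractional brightfield darkening inside objects.
#' @param noise_sd additive Gaussian noise SD (a.u.).
#' @param noise_signal_coef signal-dependent noise: the per-pixel SD is
#'   \code{noise_sd + coef * signal}.
#' @param debris_density dark sub-threshold specks per mm^2.
#' @param debris_max_area maximum debris area (um^2); kept below half the
#'   default 1950 um^2 size threshold so debris never survives filtering.
#' @param detached_cell_density bright fluorescent singles per mm^2.
#' @param out_of_focus_fraction fraction of organoids imaged out of the
#'   focal plane.
#' @param oof_attenuation fluorescence attenuation factor for out-of-focus
#'   organoids (>= 10 defeats the focus filter's target regime).
#' @param oof_blur_sigma Gaussian blur SD (px) for out-of-focus fluorescence.
#' @param seed integer seed fixing the scene and its rendering.
#' @return object of class \code{"scene_config"}.
#' @export
scene_config <- function(image_shape = c(512L, 512L), pixel_area = 38.62,
                         n_organoids = 55L,
                         size_meanlog = log(20000), size_sdlog = 0.45,
                         lobes = c(1L, 3L), core_shell_depth = 0.2,
                         base_viability_range = c(1, 1),
                         illumination_gradient = c(0.7, 1.3),
                         background = c(brightfield = 40000, live = 1500,
                                        dead = 1200),
                         fluor_gain = 20000, silhouette = 0.6,
                         noise_sd = 150, noise_signal_coef = 0.01,
                         debris_density = 3, debris_max_area = 900,
                         detached_cell_density = 5,
                         out_of_focus_fraction = 0.1, oof_attenuation = 15,
                         oof_blur_sigma = 3, seed = 1L) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 64),
            pixel_area > 0, n_organoids >= 0, size_sdlog >= 0,
            core_shell_depth >= 0, core_shell_depth <= 1,
            all(base_viability_range >= 0), all(base_viability_range <= 1),
            debris_density >= 0, detached_cell_density >= 0,
            out_of_focus_fraction >= 0, out_of_focus_fraction <= 1,
            oof_attenuation >= 1, fluor_gain > 0,
            silhouette > 0, silhouette < 1)
  structure(as.list(environment()), class = "scene_config")
}

#' Named scene presets
#'
#' Fixed-seed regimes referenced throughout the test suite so cross-module
#' checks are reproducible: \code{"segmentation_snr"} (strong illumination
#' gradient, debris and out-of-focus organoids present; the regime in which
#' segmentation recovery is asserted), \code{"quantification_snr"} (milder
#' optics, heterogeneous per-organoid viability; the regime for viability
#' recovery), and \code{"reference_plate"} (plate-scale layout for end-to-end
#' runs).
#'
#' @param name preset name.
#' @return a \code{\link{scene_config}}.
#' @export
scene_preset <- function(name = c("segmentation_snr", "quantification_snr",
                                  "reference_plate")) {
  name <- match.arg(name)
  switch(name,
    segmentation_snr = scene_config(
      n_organoids = 55L, illumination_gradient = c(0.7, 1.3),
      out_of_focus_fraction = 0.15, debris_density = 3,
      detached_cell_density = 5, seed = 101L),
    quantification_snr = scene_config(
      n_organoids = 60L, illumination_gradient = c(0.85, 1.15),
      base_viability_range = c(0.15, 1), noise_sd = 100,
      noise_signal_coef = 0.005, out_of_focus_fraction = 0.05,
      debris_density = 2, detached_cell_density = 3, seed = 202L),
    reference_plate = scene_config(
      n_organoids = 45L, illumination_gradient = c(0.8, 1.2),
      out_of_focus_fraction = 0.1, seed = 303L))
}

# Rasterize one lobed organoid: a union of overlapping ellipses, rescaled so
# the rasterized area approximates the drawn target area. Returns a logical
# matrix trimmed to its bounding box. Consumes RNG.
make_blob <- function(target_px, lobes = c(1L, 3L)) {
  k <- if (lobes[1] == lobes[2]) lobes[1] else sample(lobes[1]:lobes[2], 1)
  aspect <- stats::runif(1, 1, 2.2)
  theta0 <- stats::runif(1, 0, pi)
  rel <- if (k > 1) stats::runif(k - 1, 0.3, 0.7) else numeric(0)
  dirs <- if (k > 1) stats::runif(k - 1, 0, 2 * pi) else numeric(0)
  offs <- if (k > 1) stats::runif(k - 1, 0.5, 0.9) else numeric(0)
  thetas <- c(theta0, stats::runif(max(k - 1, 0), 0, pi))
  rasterize <- function(scale) {
    # main ellipse of area ~ scale^2 * pi * a * b
    a1 <- scale * sqrt(aspect); b1 <- scale / sqrt(aspect)
    cx <- c(0, offs * a1 * cos(dirs)); cy <- c(0, offs * a1 * sin(dirs))
    aa <- c(a1, a1 * sqrt(rel)); bb <- c(b1, b1 * sqrt(rel))
    ext <- max(abs(cx) + pmax(aa, bb), abs(cy) + pmax(aa, bb))
    r <- ceiling(ext) + 1L
    g <- seq(-r, r)
    xs <- matrix(g, 2 * r + 1, 2 * r + 1)
    ys <- t(xs)
    m <- matrix(FALSE, 2 * r + 1, 2 * r + 1)
    for (e in seq_len(k)) {
      dx <- xs - cx[e]; dy <- ys - cy[e]
      u <- (dx * cos(thetas[e]) + dy * sin(thetas[e])) / aa[e]
      v <- (-dx * sin(thetas[e]) + dy * cos(thetas[e])) / bb[e]
      m <- m | (u^2 + v^2 <= 1)
    }
    m
  }
  s0 <- sqrt(target_px / pi)           # first guess ignoring lobes/overlap
  m <- rasterize(s0)
  got <- sum(m)
  if (got > 0) m <- rasterize(s0 * sqrt(target_px / got))
  rows <- range(which(rowSums(m) > 0)); cols <- range(which(colSums(m) > 0))
  m[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
}

# Normalized distance-from-boundary field of a mask (0 at the rim, 1 at the
# deepest interior pixel), via a padded Euclidean distance transform.
boundary_depth <- function(mask) {
  pad <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)
  pad[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask * 1
  d <- as.matrix(EBImage::distmap(pad))[2:(nrow(mask) + 1),
                                        2:(ncol(mask) + 1)]
  mx <- max(d)
  if (mx > 0) d / mx else d
}

#' Generate a ground-truthed synthetic scene
#'
#' Places lobed organoids without overlap (pairwise-disjoint masks with a
#' small guard gap), assigns each a per-pixel viability field with a
#' core-shell gradient, marks a fraction out-of-focus, and scatters
#' sub-threshold debris and detached bright cells in the inter-organoid
#' space. Fully reproducible from the config seed.
#'
#' @param config a \code{\link{scene_config}}.
#' @return object of class \code{"ground_truth_scene"}: \code{organoids}
#'   (list of id, pixel indices, per-pixel viability, true area, in-focus
#'   flag), \code{truth_labels} (integer raster of true organoid ids),
#'   \code{debris_pixels}, \code{detached} (data frame), and the config.
#' @export
generate_scene <- function(config = scene_config()) {
  with_seed(derive_seed(config$seed, "scene"), {
    nr <- config$image_shape[1]; nc <- config$image_shape[2]
    truth <- matrix(0L, nr, nc)
    blocked <- matrix(FALSE, nr, nc)    # occupancy + guard gap
    organoids <- vector("list", config$n_organoids)
    areas_um2 <- if (config$n_organoids > 0)
      stats::rlnorm(config$n_organoids, config$size_meanlog, config$size_sdlog)
    else numeric(0)
    bases <- if (config$n_organoids > 0)
      stats::runif(config$n_organoids, config$base_viability_range[1],
                   config$base_viability_range[2]) else numeric(0)
    gap_kernel <- matrix(1, 5, 5)       # 2 px guard gap between organoids
    for (i in seq_len(config$n_organoids)) {
      m <- make_blob(areas_um2[i] / config$pixel_area, config$lobes)
      mh <- nrow(m); mw <- ncol(m)
      if (mh > nr - 8 || mw > nc - 8)
        stop("organoid larger than the field of view; shrink the size distribution")
      placed <- FALSE
      for (try in seq_len(250)) {
        r0 <- sample.int(nr - mh - 6, 1) + 3L
        c0 <- sample.int(nc - mw - 6, 1) + 3L
        sub <- blocked[r0:(r0 + mh - 1), c0:(c0 + mw - 1)]
        if (!any(sub & m)) { placed <- TRUE; break }
      }
      if (!placed)
        stop("could not place all organoids: configuration too crowded")
      loc <- which(m)
      rr <- r0 + (loc - 1L) %% mh
      cc <- c0 + (loc - 1L) %/% mh
      pix <- rr + (cc - 1L) * nr
      truth[pix] <- i
      padm <- matrix(0, mh + 4L, mw + 4L)
      padm[3:(mh + 2L), 3:(mw + 2L)] <- m * 1
      grown <- as.matrix(EBImage::dilate(padm, gap_kernel)) > 0
      gr0 <- r0 - 2L; gc0 <- c0 - 2L
      rs <- max(gr0, 1L):min(gr0 + mh + 3L, nr)
      cs <- max(gc0, 1L):min(gc0 + mw + 3L, nc)
      blocked[rs, cs] <- blocked[rs, cs] | grown[rs - gr0 + 1L, cs - gc0 + 1L]
      depth <- boundary_depth(m)[loc]
      organoids[[i]] <- list(
        id = i, pixels = pix,
        viability = bases[i] * (1 - config$core_shell_depth * depth),
        true_area = length(pix) * config$pixel_area,
        in_focus = TRUE)
    }
    n_oof <- round(config$out_of_focus_fraction * config$n_organoids)
    if (n_oof > 0) {
      oof_ids <- sample(seq_len(config$n_organoids), n_oof)
      for (i in oof_ids) organoids[[i]]$in_focus <- FALSE
    }
    area_mm2 <- nr * nc * config$pixel_area / 1e6
    free <- which(!blocked)
    # debris: dark specks below half the size threshold
    n_debris <- round(config$debris_density * area_mm2)
    debris_pixels <- integer(0)
    if (n_debris > 0) {
      for (d in seq_len(n_debris)) {
        m <- make_blob(stats::runif(1, 3, config$debris_max_area /
                                         config$pixel_area),
                       c(1L, 1L))
        mh <- nrow(m); mw <- ncol(m)
        for (try in seq_len(50)) {
          r0 <- sample.int(nr - mh - 2, 1) + 1L
          c0 <- sample.int(nc - mw - 2, 1) + 1L
          sub <- blocked[r0:(r0 + mh - 1), c0:(c0 + mw - 1)]
          if (!any(sub & m)) {
            loc <- which(m)
            pix <- (r0 + (loc - 1L) %% mh) +
              (c0 + (loc - 1L) %/% mh - 1L) * nr
            debris_pixels <- c(debris_pixels, pix)
            break
          }
        }
      }
    }
    # detached single bright cells in inter-organoid space
    n_cells <- round(config$detached_cell_density * area_mm2)
    detached <- data.frame(pixel = integer(0), channel = character(0))
    if (n_cells > 0 && length(free) > n_cells) {
      pix <- sample(free, n_cells)
      detached <- data.frame(
        pixel = pix,
        channel = sample(c("live", "dead"), n_cells, replace = TRUE,
                         prob = c(0.6, 0.4)))
    }
    structure(list(organoids = organoids, truth_labels = truth,
                   debris_pixels = debris_pixels, detached = detached,
                   config = config, treatment = NULL),
              class = "ground_truth_scene")
  })
}

#' @export
print.ground_truth_scene <- function(x, ...) {
  cat(sprintf("<ground_truth_scene> %d x %d px, %d organoids (%d in focus), %d debris px%s\n",
              nrow(x$truth_labels), ncol(x$truth_labels),
              length(x$organoids),
              sum(vapply(x$organoids, `[[`, logical(1), "in_focus")),
              length(x$debris_pixels),
              if (!is.null(x$treatment))
                sprintf(", treated: %s dose=%g", x$treatment$model,
                        x$treatment$dose) else ""))
  invisible(x)
}

#' Ground-truth table of a scene
#'
#' @param scene a \code{ground_truth_scene}.
#' @return data frame: \code{truth_id}, \code{true_area} (um^2),
#'   \code{true_mean_viability}, \code{in_focus}.
#' @export
scene_truth <- function(scene) {
  data.frame(
    truth_id = vapply(scene$organoids, `[[`, numeric(1), "id"),
    true_area = vapply(scene$organoids, `[[`, numeric(1), "true_area"),
    true_mean_viability = vapply(scene$organoids,
                                 function(o) mean(o$viability), numeric(1)),
    in_focus = vapply(scene$organoids, `[[`, logical(1), "in_focus"))
}

#' Apply a treatment model to a scene's viability fields
#'
#' \code{uniform_kill} scales every organoid's per-pixel viability by
#' \code{exp(-alpha * dose)}, the signature of a drug acting independently
#' of organoid size. \code{size_dependent_kill} scales organoid \code{i} by
#' \code{exp(-alpha * dose * (a_ref / area_i)^gamma)}, hitting small
#' organoids harder — the signature of light-based therapy sparing large
#' organoids. Dose 0 is the identity.
#'
#' @param scene a \code{ground_truth_scene}.
#' @param model \code{"uniform_kill"} or \code{"size_dependent_kill"}.
#' @param dose non-negative dose (same arbitrary axis as the analysis).
#' @param alpha kill rate per dose unit.
#' @param gamma size-dependence exponent.
#' @param a_ref reference area (um^2); defaults to the scene's median true
#'   area.
#' @return the treated scene.
#' @export
apply_treatment <- function(scene,
                            model = c("uniform_kill", "size_dependent_kill"),
                            dose, alpha = 0.05, gamma = 1, a_ref = NULL) {
  model <- match.arg(model)
  if (dose < 0) stop("dose must be >= 0")
  areas <- vapply(scene$organoids, `[[`, numeric(1), "true_area")
  if (is.null(a_ref)) a_ref <- stats::median(areas)
  for (i in seq_along(scene$organoids)) {
    f <- if (model == "uniform_kill") exp(-alpha * dose)
         else exp(-alpha * dose * (a_ref / areas[i])^gamma)
    scene$organoids[[i]]$viability <- scene$organoids[[i]]$viability * f
  }
  scene$treatment <- list(model = model, dose = dose, alpha = alpha,
                          gamma = gamma, a_ref = a_ref)
  scene
}

#' Render a scene into an image set
#'
#' Brightfield is the background level under a multiplicative linear
#' illumination gradient, with object (and debris) pixels darkened by the
#' silhouette coefficient; out-of-focus organoids keep their silhouette.
#' Live fluorescence is background plus gain times the viability field;
#' dead fluorescence is its complement over the organoid mask. Out-of-focus
#' organoids' fluorescence is attenuated and Gaussian-blurred. A
#' total-killing render forces the viability field to zero (fixed,
#' permeabilized cells: full PI, no calcein). Noise is Gaussian with a
#' signal-dependent SD; channels are clipped to [0, 65535] and rounded to
#' integers (16-bit).
#'
#' @param scene a \code{ground_truth_scene}.
#' @param group group label of the rendered well; \code{"total_killing"}
#'   zeroes the viability field.
#' @param well_id well identifier carried into the image set.
#' @param dose dose recorded in the metadata.
#' @param seed_offset extra term in the render seed, so repeated wells of
#'   one group get independent noise.
#' @return an \code{\link{image_set}}.
#' @export
render_scene <- function(scene, group = "no_treatment", well_id = "sim",
                         dose = NA_real_, seed_offset = 0L) {
  cfg <- scene$config
  with_seed(derive_seed(cfg$seed, "render", group, well_id, seed_offset), {
    nr <- cfg$image_shape[1]; nc <- cfg$image_shape[2]
    illum <- matrix(seq(cfg$illumination_gradient[1],
                        cfg$illumination_gradient[2], length.out = nc),
                    nr, nc, byrow = TRUE)
    obj_mask <- scene$truth_labels > 0L
    bf <- cfg$background[["brightfield"]] * illum
    dark <- obj_mask
    dark[scene$debris_pixels] <- TRUE
    bf[dark] <- bf[dark] * (1 - cfg$silhouette)
    vfield <- matrix(0, nr, nc)
    focus <- matrix(TRUE, nr, nc)
    for (o in scene$organoids) {
      vfield[o$pixels] <- if (group == "total_killing") 0 else o$viability
      if (!o$in_focus) focus[o$pixels] <- FALSE
    }
    live_sig <- cfg$fluor_gain * vfield
    dead_sig <- matrix(0, nr, nc)
    dead_sig[obj_mask] <- cfg$fluor_gain * (1 - vfield[obj_mask])
    # split in-focus vs out-of-focus contributions; blur + attenuate the latter
    oof <- obj_mask & !focus
    if (any(oof)) {
      blur <- function(sig) {
        out <- matrix(0, nr, nc)
        out[oof] <- sig[oof] / cfg$oof_attenuation
        as.matrix(EBImage::gblur(out, sigma = cfg$oof_blur_sigma))
      }
      live_oof <- blur(live_sig); dead_oof <- blur(dead_sig)
      live_sig[oof] <- 0; dead_sig[oof] <- 0
      live_sig <- live_sig + live_oof
      dead_sig <- dead_sig + dead_oof
    }
    live <- cfg$background[["live"]] + live_sig
    dead <- cfg$background[["dead"]] + dead_sig
    # faint debris fluorescence in both channels
    if (length(scene$debris_pixels)) {
      live[scene$debris_pixels] <- live[scene$debris_pixels] +
        0.05 * cfg$fluor_gain
      dead[scene$debris_pixels] <- dead[scene$debris_pixels] +
        0.05 * cfg$fluor_gain
    }
    if (nrow(scene$detached)) {
      lv <- scene$detached$pixel[scene$detached$channel == "live"]
      dd <- scene$detached$pixel[scene$detached$channel == "dead"]
      live[lv] <- live[lv] + 0.8 * cfg$fluor_gain
      dead[dd] <- dead[dd] + 0.8 * cfg$fluor_gain
    }
    noisy <- function(x) {
      sdpx <- cfg$noise_sd + cfg$noise_signal_coef * x
      x <- x + stats::rnorm(length(x), 0, sdpx)
      matrix(pmin(pmax(round(x), 0), 65535), nr, nc)
    }
    image_set(noisy(bf), noisy(live), noisy(dead),
              pixel_area = cfg$pixel_area, well_id = well_id, group = group,
              dose = dose)
  })
}

#' Match analysis objects to ground-truth organoids
#'
#' Pairs every label-map object with the ground-truth organoid it overlaps
#' most, reporting the intersection-over-union, and lists unrecovered
#' truth organoids.
#'
#' @param lmap a \code{\link{label_map}} from analyzing the rendered scene.
#' @param scene the \code{ground_truth_scene} behind it.
#' @return data frame: \code{object_id}, \code{truth_id} (NA when an object
#'   overlaps no truth organoid), \code{iou}.
#' @export
match_objects <- function(lmap, scene) {
  ids <- lmap$object_ids
  out <- data.frame(object_id = ids, truth_id = NA_integer_,
                    iou = NA_real_)
  truth_px <- lapply(scene$organoids, `[[`, "pixels")
  for (i in seq_along(ids)) {
    obj <- which(lmap$labels == ids[i])
    ov <- vapply(truth_px, function(tp) length(intersect(obj, tp)),
                 numeric(1))
    if (length(ov) && max(ov) > 0) {
      j <- which.max(ov)
      out$truth_id[i] <- scene$organoids[[j]]$id
      out$iou[i] <- ov[j] / length(union(obj, truth_px[[j]]))
    }
  }
  out
}

#' Simulate a complete analyzable plate on disk
#'
#' Writes per-well 16-bit TIFF triplets, a CSV manifest that passes
#' \code{\link{validate_manifest}}, and a per-organoid ground-truth CSV.
#' The plate layout covers both control groups plus a dose series of the
#' chosen treatment model; each well is an independent scene drawn from the
#' same configuration with a well-specific sub-seed.
#'
#' @param config a \code{\link{scene_config}} (the base; per-well seeds are
#'   derived from its seed).
#' @param out_dir output directory (created if needed).
#' @param doses dose levels of the treatment series.
#' @param n_control_wells wells per control group.
#' @param n_wells_per_dose wells per dose level.
#' @param treatment_model kill model for the dose series.
#' @param alpha,gamma treatment model parameters.
#' @param dose_unit unit label written to the manifest.
#' @return list with \code{manifest} (path), \code{ground_truth} (path) and
#'   \code{scenes} (named list of the generated scenes).
#' @export
simulate_plate <- function(config = scene_preset("reference_plate"), out_dir,
                           doses = c(5, 10, 25, 50),
                           n_control_wells = 3L, n_wells_per_dose = 2L,
                           treatment_model = "size_dependent_kill",
                           alpha = 0.05, gamma = 1, dose_unit = "J/cm2") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list(); scenes <- list()
  add_well <- function(well_id, group, dose, scene) {
    iset <- render_scene(scene, group = group, well_id = well_id,
                         dose = dose)
    paths <- file.path(out_dir, sprintf("%s_%s.tif", well_id,
                                        c("bf", "live", "dead")))
    write_gray_tiff(iset$brightfield, paths[1])
    write_gray_tiff(iset$live, paths[2])
    write_gray_tiff(iset$dead, paths[3])
    rows[[length(rows) + 1]] <<- data.frame(
      well_id = well_id, group = group, dose = dose, dose_unit = dose_unit,
      path_brightfield = basename(paths[1]), path_live = basename(paths[2]),
      path_dead = basename(paths[3]), pixel_area = config$pixel_area)
    scenes[[well_id]] <<- scene
  }
  well_scene <- function(well_id) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, "well", well_id)
    generate_scene(cfg)
  }
  for (w in seq_len(n_control_wells)) {
    id <- sprintf("NT%02d", w)
    add_well(id, "no_treatment", NA_real_, well_scene(id))
  }
  for (w in seq_len(n_control_wells)) {
    id <- sprintf("TK%02d", w)
    add_well(id, "total_killing", NA_real_, well_scene(id))
  }
  for (d in seq_along(doses)) for (w in seq_len(n_wells_per_dose)) {
    id <- sprintf("TX%02d_%02d", d, w)
    sc <- apply_treatment(well_scene(id), treatment_model, doses[d],
                          alpha = alpha, gamma = gamma)
    add_well(id, "treatment", doses[d], sc)
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  gt <- do.call(rbind, lapply(names(scenes), function(w) {
    tr <- scene_truth(scenes[[w]])
    cbind(well_id = w, tr)
  }))
  gpath <- file.path(out_dir, "ground_truth.csv")
  utils::write.csv(gt, gpath, row.names = FALSE)
  list(manifest = mpath, ground_truth = gpath, scenes = scenes)
}
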