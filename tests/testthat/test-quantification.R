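test_that("per-object means are exact and sums-vs-means leaves viability invariant", {
  lab <- matrix(0L, 8, 8)
  lab[2, 2:5] <- 1L; lab[5:6, 5:6] <- 2L
  lm <- label_map(lab, 38.62)
  ch <- matrix(0, 8, 8)
  ch[2, 2:5] <- c(0, 10, 20, 30)
  ch[lab == 2L] <- 50
  mi <- object_intensities(lm, ch)
  expect_equal(unname(mi), c(15, 50))
  set.seed(12)
  for (i in 1:10) {
    n <- sample(3:40, 1)
    live <- runif(n, 0, 100); dead <- runif(n, 0, 100)
    expect_equal(viability(mean(live), mean(dead)),
                 viability(sum(live), sum(dead)))
  }
})

test_that("the viability ratio hits its closed-form anchors and bounds", {
  expect_equal(viability(30, 0), 1)
  expect_equal(viability(0, 25), 0)
  expect_equal(viability(30, 10), 0.75)
  expect_true(is.na(viability(0, 0)))
  expect_error(viability(-1, 2), "non-negative")
  set.seed(2)
  v <- viability(runif(100, 0, 50), runif(100, 0, 50))
  expect_true(all(v >= 0 & v <= 1))
})

test_that("live threshold calibration is pooled Otsu times the factor", {
  set.seed(6)
  nr <- 50
  mk <- function(seed) {
    set.seed(seed)
    mask <- matrix(FALSE, nr, nr); mask[10:40, 10:40] <- TRUE
    live <- matrix(rnorm(nr * nr, 40, 5), nr, nr)
    live[mask] <- rnorm(sum(mask), 400, 60)
    live <- pmax(live, 0)
    list(image_set = image_set(matrix(1, nr, nr), live, live, 38.62,
                               group = "no_treatment"),
         label_map = mask_label_map(mask))
  }
  sets <- list(mk(1), mk(2))
  pooled <- unlist(lapply(sets, function(cs)
    cs$image_set$live[cs$label_map$labels > 0]))
  thr <- calibrate_live_threshold(sets, factor = 0.4)
  expect_equal(thr$raw_otsu, brute_otsu(pooled))
  expect_equal(thr$value, thr$raw_otsu * 0.4)
  thr1 <- calibrate_live_threshold(sets, factor = 1)
  expect_equal(thr1$value, thr1$raw_otsu)
})

test_that("thresholded areas count strictly-exceeding pixels in physical units", {
  mask <- matrix(FALSE, 12, 12); mask[2:9, 2:11] <- TRUE  # 80 px
  lm <- mask_label_map(mask, 38.62)
  live <- matrix(0, 12, 12)
  live[2:5, 2:11] <- 100     # 40 of 80 px above
  la <- object_live_area(lm, live, 50)
  expect_equal(la$live_area, 40 * 38.62)
  expect_equal(la$frac_live_area, 0.5)
  expect_equal(object_live_area(lm, live, 100)$frac_live_area, 0)  # strict >
  live[mask] <- 100
  expect_equal(object_live_area(lm, live, 50)$frac_live_area, 1)
  dead <- matrix(0, 12, 12); dead[mask] <- 100
  da <- object_dead_area(lm, dead, 50)
  expect_equal(da$frac_dead_area, 1)
  expect_equal(object_dead_area(lm, live * 0, 50)$dead_area, 0)
})

test_that("quantify_objects assembles consistent per-organoid records", {
  lab <- matrix(0L, 10, 10)
  lab[2:3, 2:3] <- 1L; lab[6:9, 5:9] <- 2L
  lm <- label_map(lab, 10)
  live <- matrix(0, 10, 10); dead <- matrix(0, 10, 10)
  live[lab == 1L] <- 30; dead[lab == 1L] <- 10
  dead[lab == 2L] <- 20
  iset <- image_set(matrix(1, 10, 10), live, dead, 10, well_id = "w",
                    group = "treatment", dose = 5)
  rec <- quantify_objects(iset, lm, live_threshold = 15, dead_threshold = 15)
  expect_equal(rec$object_id, c(1L, 2L))
  expect_equal(rec$total_area, rec$area_px * 10)
  expect_equal(rec$viability, c(0.75, 0))
  expect_equal(rec$live_area, c(4 * 10, 0))
  expect_equal(rec$frac_dead_area, c(0, 1))
  expect_true(all(rec$live_area <= rec$total_area))
  expect_equal(rec$centroid_row[1], mean(c(1, 2)))   # 0-based
  expect_equal(rec$centroid_col[2], mean(4:8))
  # live_area plus the area of pixels at-or-below threshold is total_area
  below <- tabulate(lab[lab > 0 & live <= 15], nbins = 2) * 10
  expect_equal(rec$live_area + below, rec$total_area)
})

test_that("normalization divides by the control median and preserves order", {
  ctrl <- data.frame(viability = c(0.7, 0.8, 0.9))
  rec <- data.frame(viability = c(0.8, 0.4, NA, 0.2))
  out <- normalize_viability(rec, ctrl)
  expect_equal(out$normalized_viability, c(1, 0.5, NA, 0.25))
  expect_identical(order(out$normalized_viability[-3]),
                   order(rec$viability[-3]))
  expect_error(normalize_viability(rec, data.frame(viability = c(0, 0))),
               "zero")
  expect_error(normalize_viability(rec, data.frame(viability = NA_real_)),
               "no defined viability")
})

test_that("measured viability tracks ground truth on the quantification preset", {
  cfg <- scene_preset("quantification_snr")
  ctrl_cfg <- cfg; ctrl_cfg$base_viability_range <- c(1, 1)
  ctrl_cfg$seed <- 777L
  csc <- generate_scene(ctrl_cfg)
  cset <- render_scene(csc, "no_treatment", "NT01")
  sc <- generate_scene(cfg)
  tset <- render_scene(sc, "treatment", "TX01", dose = 25)
  seg <- function(s) focus_filter(segment_brightfield(s), s$live, s$dead)
  bg <- estimate_background(list(list(image_set = cset,
                                      label_map = seg(cset))))
  tcor <- subtract_background(tset, bg)
  tlm <- seg(tcor)
  rec <- quantify_objects(tcor, tlm, live_threshold = 1)
  d <- merge(merge(rec, match_objects(tlm, sc), by = "object_id"),
             scene_truth(sc), by = "truth_id")
  expect_gte(nrow(d), 50)
  expect_lte(max(abs(d$viability - d$true_mean_viability)), 0.05)
  expect_gte(cor(d$viability, d$true_mean_viability, method = "spearman"),
             0.95)
  expect_true(all(d$viability >= 0 & d$viability <= 1, na.rm = TRUE))
})
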