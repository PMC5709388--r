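test_that("16-bit TIFFs round-trip pixel-identically and carry metadata", {
  dir <- withr::local_tempdir()
  set.seed(4)
  imgs <- replicate(3, matrix(sample.int(65536, 64 * 64, TRUE) - 1L, 64, 64),
                    simplify = FALSE)
  paths <- file.path(dir, c("bf.tif", "live.tif", "dead.tif"))
  for (i in 1:3) write_gray_tiff(imgs[[i]], paths[i])
  expect_identical(read_gray_tiff(paths[1]) * 1, imgs[[1]] * 1)
  entry <- data.frame(well_id = "A1", group = "total_killing", dose = NA,
                      path_brightfield = paths[1], path_live = paths[2],
                      path_dead = paths[3])
  iset <- load_image_set(entry, pixel_area = 38.62)
  expect_s3_class(iset, "image_set")
  expect_identical(dim(iset$live), c(64L, 64L))
  expect_equal(iset$group, "total_killing")
  expect_equal(iset$pixel_area, 38.62)
})

test_that("channel shape mismatches and missing files are rejected", {
  dir <- withr::local_tempdir()
  big <- matrix(0L, 64, 64); small <- matrix(0L, 32, 32)
  p <- file.path(dir, c("bf.tif", "live.tif", "dead.tif"))
  write_gray_tiff(big, p[1]); write_gray_tiff(big, p[2])
  write_gray_tiff(small, p[3])
  entry <- data.frame(well_id = "A1", group = "treatment", dose = 1,
                      path_brightfield = p[1], path_live = p[2],
                      path_dead = p[3])
  expect_error(load_image_set(entry, pixel_area = 38.62), "mismatch")
  entry$path_dead <- file.path(dir, "absent.tif")
  expect_error(load_image_set(entry, pixel_area = 38.62), "absent.tif")
  expect_error(image_set(big, big, big - 5L, 38.62), "negative")
})

test_that("2x2 mosaic concatenates tiles and rejects inconsistent inputs", {
  z <- matrix(7, 32, 32)
  tiles <- lapply(1:4, function(i)
    image_set(z + i, z, z, 38.62, well_id = "A1"))
  mos <- tile_mosaic(tiles)
  expect_identical(dim(mos$brightfield), c(64L, 64L))
  expect_equal(mos$brightfield[1, 1], 8)        # tile 1 top-left
  expect_equal(mos$brightfield[1, 64], 9)       # tile 2 top-right
  expect_equal(mos$brightfield[64, 1], 10)      # tile 3 bottom-left
  expect_equal(mos$brightfield[64, 64], 11)     # tile 4 bottom-right
  expect_error(tile_mosaic(tiles[1:3]), "4 tiles")
  tiles2 <- tiles; tiles2[[2]]$pixel_area <- 10
  expect_error(tile_mosaic(tiles2), "pixel_area")
})

test_that("analyzing a mosaic equals analyzing the pre-assembled image", {
  cfg <- scene_config(n_organoids = 12L, seed = 31L,
                      out_of_focus_fraction = 0, debris_density = 0,
                      detached_cell_density = 0)
  sc <- generate_scene(cfg)
  whole <- render_scene(sc, "no_treatment", "A1")
  slice <- function(ch, rs, cs) ch[rs, cs]
  halves <- list(1:256, 257:512)
  tiles <- list()
  for (r in 1:2) for (cc in 1:2) {
    tiles[[length(tiles) + 1]] <- image_set(
      slice(whole$brightfield, halves[[r]], halves[[cc]]),
      slice(whole$live, halves[[r]], halves[[cc]]),
      slice(whole$dead, halves[[r]], halves[[cc]]),
      whole$pixel_area, well_id = "A1", group = "no_treatment")
  }
  mos <- tile_mosaic(tiles)
  expect_identical(mos$brightfield, whole$brightfield)
  seg <- function(s) focus_filter(segment_brightfield(s), s$live, s$dead)
  lm_m <- seg(mos); lm_w <- seg(whole)
  expect_identical(lm_m$labels, lm_w$labels)
  thr <- 500
  expect_equal(quantify_objects(mos, lm_m, thr),
               quantify_objects(whole, lm_w, thr))
})

test_that("manifests parse, resolve paths and demand both control groups", {
  dir <- withr::local_tempdir()
  z <- matrix(0L, 16, 16)
  for (f in c("a_bf.tif", "a_l.tif", "a_d.tif"))
    write_gray_tiff(z, file.path(dir, f))
  df <- data.frame(well_id = "A1", group = "no_treatment", dose = NA,
                   dose_unit = NA, path_brightfield = "a_bf.tif",
                   path_live = "a_l.tif", path_dead = "a_d.tif",
                   pixel_area = 38.62)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(df, mpath, row.names = FALSE)
  man <- read_manifest(mpath)
  expect_equal(attr(man, "pixel_area"), 38.62)
  expect_true(file.exists(man$path_brightfield[1]))
  expect_error(validate_manifest(man), "total_killing")
  df2 <- df; df2$pixel_area <- NULL
  write.csv(df2, mpath, row.names = FALSE)
  expect_error(read_manifest(mpath), "pixel_area")
})
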