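test_that("group summaries are means of per-image medians with SD and SEM", {
  rec <- function(w, v) data.frame(well_id = w, group = "treatment",
                                   dose = 1, total_area = v * 100,
                                   frac_live_area = v / 2, viability = v)
  r <- rbind(rec("a", c(0.1, 0.2, 0.9)), rec("b", c(0.4)),
             rec("c", c(0.5, 0.7)))
  s <- summarize_group(r)
  expect_equal(unname(s$per_image_medians$viability), c(0.2, 0.4, 0.6))
  expect_equal(unname(s$mean_of_medians["viability"]), 0.4)
  expect_equal(unname(s$sd["viability"]), 0.2)
  expect_equal(unname(s$sem["viability"]), 0.2 / sqrt(3))
  # even-count image: median is the mean of the two central values
  expect_equal(unname(s$per_image_medians$viability[3]), mean(c(0.5, 0.7)))
  # identical images have SEM 0
  s0 <- summarize_group(rbind(rec("a", c(0.3, 0.5)), rec("b", c(0.3, 0.5)),
                              rec("c", c(0.3, 0.5))))
  expect_equal(unname(s0$sem["viability"]), 0)
  # invariant to row order
  s_shuf <- summarize_group(r[sample(nrow(r)), ])
  expect_equal(s_shuf$mean_of_medians, s$mean_of_medians)
  # image with only missing viability is dropped and counted
  r2 <- rbind(r, rec("d", NA_real_))
  expect_equal(summarize_group(r2)$dropped_images, 1L)
})

test_that("metric histograms use left-closed bins with a closed last bin", {
  expect_equal(metric_histogram(c(0.1, 0.5, 0.9), bin_edges = c(0, 0.5, 1)),
               c(1, 2))
  expect_equal(metric_histogram(c(0, 0.5, 1), bin_edges = c(0, 0.5, 1)),
               c(1, 2))                      # interior edge -> right bin
  set.seed(1)
  x <- runif(200)
  expect_equal(sum(metric_histogram(x, bin_edges = seq(0, 1, 0.1))), 200)
  df <- data.frame(viability = c(0.2, NA, 0.8))
  expect_equal(sum(metric_histogram(df, "viability", c(0, 1))), 2)
  expect_error(metric_histogram(x, bin_edges = c(0, 0.5, 0.5)), "increasing")
})

test_that("linear_fit reproduces closed-form least squares", {
  x <- c(1, 2, 3, 4); y <- 2 * x + 1
  f <- linear_fit(x, y)
  expect_equal(f$slope, 2); expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)
  set.seed(10)
  x <- rnorm(60); y <- 1.5 * x - 2 + rnorm(60)
  f <- linear_fit(x, y)
  # normal-equations oracle
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(f$intercept, beta[1]); expect_equal(f$slope, beta[2])
  expect_error(linear_fit(rep(1, 5), 1:5), "constant")
  expect_error(linear_fit(1:2, 1:2), "3 finite pairs")
})

test_that("dose-response fit recovers noiseless exponential-decay parameters", {
  d <- c(0, 2, 5, 10, 20, 40)
  truth <- list(r0 = 0.95, plateau = 0.12, k = 0.15)
  y <- truth$plateau + (truth$r0 - truth$plateau) * exp(-truth$k * d)
  fit <- dose_response_fit(d, y)
  expect_lt(abs(fit$params$r0 - truth$r0) / truth$r0, 0.01)
  expect_lt(abs(fit$params$plateau - truth$plateau) / truth$plateau, 0.01)
  expect_lt(abs(fit$params$k - truth$k) / truth$k, 0.01)
  expect_lt(fit$rss, 1e-8)
  # constant responses: zero rate, both levels at the constant
  cf <- dose_response_fit(c(0, 1, 2, 4), rep(0.8, 4))
  expect_equal(cf$params$k, 0)
  expect_equal(cf$params$r0, 0.8); expect_equal(cf$params$plateau, 0.8)
  # linear model delegates to linear_fit
  lf <- dose_response_fit(d, 0.9 - 0.01 * d, model = "linear")
  expect_equal(lf$params$slope, linear_fit(d, 0.9 - 0.01 * d)$slope)
  expect_error(dose_response_fit(c(0, 1, 2), c(1, 0.5, 0.3)), "4 distinct")
})

test_that("viability heatmaps paint objects by viability with a missing sentinel", {
  lab <- matrix(0L, 10, 10)
  lab[2:3, 2:3] <- 1L; lab[6:7, 6:7] <- 2L; lab[2:3, 7:8] <- 3L
  lm <- label_map(lab, 1)
  rec <- data.frame(object_id = 1:3, viability = c(0, 1, NA))
  h <- render_viability_heatmap(lm, rec)
  cols <- apply(matrix(h, ncol = 3)[which(lab > 0), ], 1, paste,
                collapse = ",")
  expect_equal(length(unique(cols)), 3)         # two viabilities + sentinel
  expect_true(all(h[cbind(1, 1, 1:3)] == 0))    # background black
  expect_identical(h, render_viability_heatmap(lm, rec))  # deterministic
  # fully killed well renders dark: viability 0 maps to the lowest color
  rec0 <- data.frame(object_id = 1:3, viability = 0)
  h0 <- render_viability_heatmap(lm, rec0,
                                 colormap = grDevices::gray(seq(0, 1, length.out = 64)))
  expect_true(all(h0 == 0))
})

test_that("live-area maps are subsets of the object mask and dark for killed wells", {
  lab <- matrix(0L, 8, 8); lab[3:6, 3:6] <- 1L
  lm <- label_map(lab, 1)
  live <- matrix(0, 8, 8); live[3:4, 3:6] <- 10
  m <- render_live_area_map(lm, live, 5)
  expect_true(all(lab[m] > 0))
  expect_equal(sum(m), 8)
  expect_false(any(render_live_area_map(lm, live * 0, 5)))
})
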