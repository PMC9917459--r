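test_that("background region selection finds the dimmest quiet region", {
  # constant movie: any region qualifies, background level recovered
  flat <- fluor_movie(matrix(100, 50, 24 * 24), 24, 24, 25, 0.5,
                      stimulus_frames = c(10L, 30L))
  bg <- select_background_roi(flat)
  expect_equal(unique(bg$series), 100)

  # bright static spot on a 50-count background: region avoids the spot
  dat <- matrix(50, 50, 24 * 24)
  spot_px <- as.vector(outer(10:14, (9:13) * 24, `+`))
  dat[, spot_px] <- 500
  mv <- fluor_movie(dat, 24, 24, 25, 0.5, stimulus_frames = c(10L, 30L))
  bg2 <- select_background_roi(mv)
  expect_equal(unique(bg2$series), 50)
  expect_true(!any(bg2$pixels %in% spot_px))

  # spatially varying static background: chosen region at the minimum
  grad <- matrix(rep(seq(60, 200, length.out = 24), each = 24), 1)
  dat3 <- matrix(rep(grad, 50), 50, byrow = TRUE)
  mv3 <- fluor_movie(dat3, 24, 24, 25, 0.5, stimulus_frames = c(10L, 30L))
  bg3 <- select_background_roi(mv3)
  img_mean <- matrix(colMeans(dat3), 24, 24)
  expect_lte(bg3$mean, sort(unique(as.vector(img_mean)))[3])
})

test_that("dF/F computation is exact, robust and offset-invariant", {
  raw <- rep(100, 20)
  d <- compute_dff(raw, 0, 1:5)
  expect_true(all(d$dff == 0))

  raw2 <- c(rep(100, 10), 110, rep(100, 9))
  d2 <- compute_dff(raw2, 0, 1:5)
  expect_equal(d2$dff[11], 0.10)

  # median baseline shrugs off a single artifact frame
  raw3 <- c(98, 100, 102, 100, 400, rep(100, 10))
  d3 <- compute_dff(raw3, 0, 1:5)
  expect_equal(d3$f0, 100, ignore_attr = TRUE)

  # adding a common constant to raw and background cancels exactly
  set.seed(4)
  raw4 <- 100 + cumsum(rnorm(30))
  bg <- rep(20, 30)
  a <- compute_dff(raw4, bg, 1:6)
  b <- compute_dff(raw4 + 37, bg + 37, 1:6)
  expect_equal(a$dff, b$dff, tolerance = 1e-12)

  # non-positive F0 flags the series invalid
  d5 <- compute_dff(cbind(rep(100, 10), rep(5, 10)), 10, 1:4)
  expect_equal(d5$valid, c(TRUE, FALSE))
  expect_true(all(is.na(d5$dff[, 2])))
})

test_that("movie-derived dF/F matches the generating traces", {
  gt <- study_gt(seed = 6, noise_sd = 0)
  pr <- small_protocol(trains = 2)
  sim <- simulate_experiment(2, gt, pr)
  mv <- simulate_movie(sim, rbind(c(8.5, 8.5), c(16.5, 16.5)),
                       dim = c(24, 24), spot_f0 = 400, background = 60)
  tiles <- fluor_movie(mv$data, 24, 24, mv$frame_rate_hz, 0.5,
                       mv$stimulus_frames, mv$stim_table)
  rois <- merge_contiguous(structure(
    data.frame(tile_row = c(2, 4), tile_col = c(2, 4), n_events = 30L,
               f0 = 1, noise = 1, accepted = TRUE),
    tile_size_px = 4L, grid_dim = c(6L, 6L), pixel_size_um = 0.5,
    image_dim = c(24L, 24L)))
  ts <- movie_to_traceset(tiles, rois)
  sf <- sim$stim_table$frame
  expect_equal(ts$dff[sf, 1], sim$dff[sf, 1], tolerance = 1e-6)
  expect_equal(ts$dff[sf, 2], sim$dff[sf, 2], tolerance = 1e-6)
})

test_that("per-train F0 stability quantifies baseline drift", {
  st <- data.frame(condition = "2", train = rep(1:4, each = 2),
                   stimulus_index = rep(1:2, 4), global_train = rep(1:4, each = 2),
                   time_s = 0, frame = rep(c(30, 35) + 40 * 0:3, each = 1) +
                     rep(c(0, 5), 4))
  st$frame <- as.integer(30 + (st$train - 1) * 40 + (st$stimulus_index - 1) * 5)
  nf <- 200
  # identical trials -> zero drift
  raw <- matrix(100, nf, 1)
  f <- f0_stability(raw, st)
  expect_equal(unname(f$drift_fraction), 0)

  # planted 10% linear F0 decay across trials
  per_train_f0 <- seq(100, 90, length.out = 4)
  raw2 <- matrix(rep(per_train_f0, each = 40)[1:nf], nf, 1)
  f2 <- f0_stability(raw2, st)
  expect_equal(unname(f2$drift_fraction), -0.10, tolerance = 0.02)

  st1 <- st[st$train == 1, ]
  expect_error(f0_stability(raw, st1), "2 trains")
})
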