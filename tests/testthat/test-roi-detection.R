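test_that("tiles over a planted spot are accepted, background is not", {
  mv <- planted_spot_movie(n_events = 25, event_dff = 0.12, noise_sd = 6,
                           seed = 2)
  tiles <- scan_tiles(mv)
  hit <- tiles$accepted[tiles$tile_row == 4 & tiles$tile_col == 4]
  expect_true(hit)

  # pure constant background: no tiles accepted (zero-variance rejected)
  flat <- fluor_movie(matrix(100, 300, 24 * 24), 24, 24, 25, 0.5,
                      stimulus_frames = seq(50, 290, by = 10))
  expect_true(!any(scan_tiles(flat)$accepted))

  # exactly 20 transients: rejected (threshold is strictly > 20)
  mv20 <- planted_spot_movie(n_events = 20, event_dff = 0.2, noise_sd = 0,
                             seed = 3)
  t20 <- scan_tiles(mv20)
  expect_true(!any(t20$accepted))
  expect_gte(max(t20$n_events), 20)
  mv21 <- planted_spot_movie(n_events = 21, event_dff = 0.2, noise_sd = 0,
                             seed = 3)
  expect_true(any(scan_tiles(mv21)$accepted))

  expect_error(scan_tiles(fluor_movie(matrix(1, 1, 16), 4, 4, 25, 0.5)),
               "frames")
})

test_that("raising thresholds never enlarges the accepted tile set", {
  mv <- planted_spot_movie(n_events = 25, event_dff = 0.12, noise_sd = 8,
                           seed = 5)
  base <- scan_tiles(mv, tile_criteria(min_event_dff = 0.05, min_snr = 2))
  for (crit in list(tile_criteria(min_event_dff = 0.10, min_snr = 2),
                    tile_criteria(min_event_dff = 0.05, min_snr = 4),
                    tile_criteria(min_event_dff = 0.12, min_snr = 5))) {
    harder <- scan_tiles(mv, crit)
    expect_true(all(which(harder$accepted) %in% which(base$accepted)))
  }
})

fake_tiles <- function(coords, grid = c(8, 8), ts = 4, px = 0.5) {
  coords <- matrix(coords, ncol = 2)
  n <- nrow(coords)
  out <- data.frame(tile_row = coords[, 1], tile_col = coords[, 2],
                    n_events = rep(25L, n), f0 = rep(100, n),
                    noise = rep(0.01, n), accepted = rep(TRUE, n))
  attr(out, "tile_size_px") <- ts
  attr(out, "grid_dim") <- grid
  attr(out, "pixel_size_um") <- px
  attr(out, "image_dim") <- grid * ts
  out
}

test_that("contiguous tiles merge under 4-connectivity", {
  # two edge-adjacent tiles -> one ROI of 32 pixels
  r1 <- merge_contiguous(fake_tiles(rbind(c(2, 2), c(2, 3))))
  expect_equal(nrow(r1), 1)
  expect_equal(r1$pixel_count, 32)
  expect_equal(r1$area_um2, 32 * 0.25)

  # diagonal-only tiles stay separate
  r2 <- merge_contiguous(fake_tiles(rbind(c(2, 2), c(3, 3))))
  expect_equal(nrow(r2), 2)

  # k isolated tiles -> k ROIs, 16k pixels in total
  iso <- fake_tiles(rbind(c(1, 1), c(1, 5), c(4, 3), c(7, 7), c(5, 1)))
  r3 <- merge_contiguous(iso)
  expect_equal(nrow(r3), 5)
  expect_equal(sum(r3$pixel_count), 16 * 5)

  # pixel conservation and disjointness for a mixed layout
  mix <- fake_tiles(rbind(c(2, 2), c(2, 3), c(3, 3), c(6, 6), c(1, 8)))
  r4 <- merge_contiguous(mix)
  px <- unlist(lapply(seq_len(nrow(r4)), function(i) roi_pixels(r4, i)))
  expect_equal(length(px), 16 * 5)
  expect_equal(anyDuplicated(px), 0)

  # merging is deterministic / idempotent on the same input
  expect_identical(merge_contiguous(mix), r4)
})

test_that("ROI summaries report counts and areas", {
  r <- merge_contiguous(fake_tiles(rbind(c(2, 2), c(2, 3))))
  s <- roi_count_and_sizes(r)
  expect_equal(s$count, 1)
  expect_equal(s$mean_area, 8)

  empty <- merge_contiguous(fake_tiles(matrix(numeric(), ncol = 2)))
  s0 <- roi_count_and_sizes(empty)
  expect_equal(s0$count, 0)
  expect_true(is.na(s0$mean_area))

  expect_equal(roi_count_and_sizes(
    data.frame(area_um2 = c(4, 12)))$mean_area, 8)
})

test_that("ROI masks round-trip to TIFF and CSV", {
  r <- merge_contiguous(fake_tiles(rbind(c(2, 2), c(5, 5))))
  tif <- tempfile(fileext = ".tiff")
  csvf <- tempfile(fileext = ".csv")
  write_roi_masks(r, tif, csvf)
  mask <- tiff::readTIFF(tif) * 65535
  expect_equal(sort(unique(round(as.vector(mask)))), c(0, 1, 2))
  tab <- read.csv(csvf)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$pixel_count, c(16, 16))
})
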