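test_that("release counts honour the model and its degenerate limits", {
  pr <- small_protocol()
  gt0 <- study_gt(p_release = c("0.5" = 0, "2" = 0, "4" = 0))
  expect_true(all(simulate_release_counts(gt0, pr)$count == 0))

  gt1 <- study_gt(p_release = c("0.5" = 1, "2" = 1, "4" = 1))
  expect_true(all(simulate_release_counts(gt1, pr)$count == gt1$n_sites))

  expect_error(simulate_release_counts(study_gt(), pr, model = "gamma"),
               "binomial.*poisson|poisson.*binomial")
  expect_error(simulate_release_counts(
    study_gt(p_release = c(a = 0.5)), pr), "p_release")
})

test_that("binomial draws match the enumerated PMF", {
  # sample mean within 3 SE of N * P_R
  gt <- ground_truth(n_sites = 5, p_release = c("2" = 0.4), seed = 11)
  pr <- stim_protocol(conditions = "2", trains_per_condition = 2000)
  counts <- simulate_release_counts(gt, pr)$count
  se <- sqrt(5 * 0.4 * 0.6 / length(counts))
  expect_lt(abs(mean(counts) - 2.0), 3 * se)

  # chi-squared against brute-force enumeration of site outcomes
  for (case in list(c(1, 0.5), c(5, 0.4), c(8, 0.1))) {
    n <- case[1]; p <- case[2]
    gt <- ground_truth(n_sites = n, p_release = c("2" = p), seed = 21 + n)
    k <- simulate_release_counts(gt, pr)$count
    pmf <- enum_binom_weights(n, p)
    obs <- tabulate(k + 1, nbins = n + 1)
    keep <- pmf * length(k) >= 5
    obs2 <- c(obs[keep], sum(obs[!keep]))
    pmf2 <- c(pmf[keep], sum(pmf[!keep]))
    if (sum(!keep) == 0) { obs2 <- obs; pmf2 <- pmf }
    chi <- suppressWarnings(stats::chisq.test(obs2, p = pmf2))
    expect_gt(chi$p.value, 0.01)
  }
})

test_that("trace forward model is exact and summates exponentially", {
  pr <- stim_protocol(conditions = "2", trains_per_condition = 1,
                      stimuli_per_train = 1)
  gt <- ground_truth(p_release = c("2" = 1), noise_sd = 0, seed = 1)
  st <- stimulus_table(pr)

  # flat zero trace for zero counts
  ct <- transform(st, count = 0)
  expect_equal(simulate_trace(ct, gt, pr), rep(0, protocol_frames(pr)),
               ignore_attr = TRUE)

  # single stimulus, count 3, q 0.09 -> peak exactly 0.27
  ct$count <- 3
  tr <- simulate_trace(ct, gt, pr)
  expect_equal(tr[ct$frame], 0.27)
  expect_equal(max(tr), 0.27)

  # two stimuli 200 ms apart: second peak carries e^(-0.2/0.4) of the first
  pr2 <- stim_protocol(conditions = "2", trains_per_condition = 1,
                       stimuli_per_train = 2)
  ct2 <- transform(stimulus_table(pr2), count = 1)
  tr2 <- simulate_trace(ct2, gt, pr2)
  peaks <- tr2[ct2$frame]
  expect_equal(peaks[2] - peaks[1] * exp(-0.2 / 0.4), gt$q,
               tolerance = 1e-12)
})

test_that("same seed gives bit-identical traces and movies", {
  gt <- study_gt(seed = 9)
  pr <- small_protocol(trains = 2)
  a <- simulate_experiment(3, gt, pr)
  b <- simulate_experiment(3, gt, pr)
  expect_identical(a$dff, b$dff)
  ctr <- rbind(c(8, 8), c(12, 16), c(18, 6))
  m1 <- simulate_movie(a, ctr, dim = c(24, 24),
                       spot_f0 = 300, noise_sd = 5, seed = 4)
  m2 <- simulate_movie(b, ctr, dim = c(24, 24),
                       spot_f0 = 300, noise_sd = 5, seed = 4)
  expect_identical(m1$data, m2$data)
})

test_that("EPSC trains depress geometrically", {
  pr <- stim_protocol(conditions = "2", trains_per_condition = 3)
  gt <- ground_truth(p_release = c("2" = 1), seed = 2)
  ct <- simulate_release_counts(gt, pr)

  flat <- simulate_epsc_trains(gt, pr, 1, counts = ct)
  expect_true(all(tapply(flat$epsc_pa, flat$train, function(x)
    diff(range(x))) == 0))

  dep <- simulate_epsc_trains(gt, pr, 0.9, counts = ct)
  a <- dep$epsc_pa[dep$train == 1]
  expect_equal(a[5] / a[1], 0.9^4, tolerance = 1e-12)

  ct0 <- transform(ct, count = 0)
  expect_true(all(simulate_epsc_trains(gt, pr, 0.9,
                                       counts = ct0)$epsc_pa == 0))
  expect_error(simulate_epsc_trains(gt, pr, 0), "depression")
})

test_that("movie rendering is linear with the prescribed Gaussian mass", {
  nf <- 6
  dff <- matrix(0, nf, 1)
  # all-zero traces, no noise -> every frame equals background
  m0 <- simulate_movie(dff, matrix(c(12, 12), ncol = 2), dim = c(24, 24),
                       background = 80)
  expect_true(all(m0$data == 80))

  # added mass per frame ~ amplitude * 2 pi sigma^2 / px^2
  dff[3, 1] <- 0.5
  gain <- 200
  m1 <- simulate_movie(dff, matrix(c(12.5, 12.5), ncol = 2),
                       dim = c(24, 24), spot_sigma_um = 0.5,
                       pixel_size_um = 0.5, background = 80, spot_f0 = 0,
                       gain = gain)
  added <- sum(m1$data[3, ] - 80)
  expect_equal(added, gain * 0.5 * 2 * pi * (0.5 / 0.5)^2,
               tolerance = 0.02)

  # >= 95% of added intensity within a 5x5 window for sigma 0.3 um
  m2 <- simulate_movie(dff, matrix(c(12.5, 12.5), ncol = 2),
                       dim = c(24, 24), spot_sigma_um = 0.3,
                       pixel_size_um = 0.5, background = 0, spot_f0 = 0,
                       gain = gain)
  img <- movie_frame(m2, 3)
  expect_gt(sum(img[10:14, 10:14]) / sum(img), 0.95)

  # two spots with identical traces double the single-spot signal
  m3 <- simulate_movie(cbind(dff, dff),
                       rbind(c(8.5, 8.5), c(16.5, 16.5)), dim = c(24, 24),
                       spot_sigma_um = 0.3, pixel_size_um = 0.5,
                       background = 80, spot_f0 = 0, gain = gain)
  expect_equal(sum(m3$data[3, ] - 80), 2 * sum(m2$data[3, ]),
               tolerance = 1e-8)

  expect_error(simulate_movie(dff, matrix(c(40, 12), ncol = 2),
                              dim = c(24, 24)), "inside the frame")
})

test_that("trace and movie round-trip through CSV and TIFF", {
  gt <- study_gt(seed = 3)
  pr <- small_protocol(trains = 2)
  sim <- simulate_experiment(2, gt, pr)
  csv <- tempfile(fileext = ".csv")
  write_traces_csv(sim, csv)
  back <- read_traces_csv(csv)
  expect_equal(unname(back$dff), unname(sim$dff), tolerance = 1e-12)
  expect_equal(back$stim_table$frame, sim$stim_table$frame)

  mv <- simulate_movie(sim, rbind(c(8, 8), c(16, 16)), dim = c(24, 24),
                       spot_f0 = 300)
  tif <- tempfile(fileext = ".tiff")
  write_movie_tiff(mv, tif)
  back_mv <- read_movie_tiff(tif)
  expect_equal(back_mv$data, round(mv$data), tolerance = 1e-6)
  expect_equal(back_mv$stimulus_frames, mv$stimulus_frames)
})
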