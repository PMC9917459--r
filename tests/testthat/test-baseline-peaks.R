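test_that("ALS baseline matches a dense oracle and tracks drift not peaks", {
  set.seed(7)
  n <- 80
  y <- sin(seq(0, 3, length.out = n)) + rnorm(n, 0, 0.05)
  ours <- als_baseline(y, smoothness = 50, asymmetry = 0.1)
  oracle <- dense_als(y, 50, 0.1)
  expect_equal(as.numeric(ours), as.numeric(oracle), tolerance = 1e-8)

  # constant trace -> baseline equals the trace
  const <- als_baseline(rep(2.5, 40))
  expect_equal(as.numeric(const), rep(2.5, 40), tolerance = 1e-9)

  # pure linear drift: recovered with RMSE < 1% of the drift range
  drift <- seq(0, 0.5, length.out = 500)
  b <- suppressWarnings(als_baseline(drift))
  expect_lt(sqrt(mean((b - drift)^2)), 0.005)

  # drift + planted transients: baseline follows drift, peaks survive
  tr <- drift
  peaks_at <- seq(50, 450, by = 50)
  for (s in peaks_at) tr[s + 0:9] <- tr[s + 0:9] + 0.3 * exp(-(0:9) / 4)
  b2 <- als_baseline(tr)
  corrected <- tr - b2
  # onset increment relative to the immediately preceding frame
  expect_lt(max(abs(corrected[peaks_at] - corrected[peaks_at - 1] - 0.3)),
            0.015)
})

test_that("wavelet peak finder detects transients and resists noise", {
  set.seed(12)
  n <- 1000
  noise <- rnorm(n, 0, 0.02)
  y <- noise
  y[400 + 0:9] <- y[400 + 0:9] + 0.2 * exp(-(0:9) / 4)  # SNR 10
  pk <- find_peaks_wavelet(y)
  expect_equal(length(pk), 1)
  expect_lte(abs(pk - 400), 2)

  # null false-positive rate below 5% of nominal stimuli
  set.seed(13)
  n_stim <- 0; n_fp <- 0
  for (i in 1:20) {
    z <- rnorm(1000, 0, 0.02)
    n_fp <- n_fp + length(find_peaks_wavelet(z))
    n_stim <- n_stim + 50
  }
  expect_lt(n_fp / n_stim, 0.05)

  # two transients 5 frames apart resolve with narrow widths
  y2 <- rnorm(300, 0, 0.005)
  for (s in c(150, 155)) y2[s + 0:6] <- y2[s + 0:6] + 0.2 * exp(-(0:6) / 3)
  pk2 <- find_peaks_wavelet(y2, widths = c(1, 2, 3))
  expect_gte(sum(pk2 >= 148 & pk2 <= 158), 2)

  expect_identical(find_peaks_wavelet(numeric(0)), integer(0))

  # headless curation: add and remove
  pk3 <- find_peaks_wavelet(y, add = 700)
  expect_true(700 %in% pk3)
  pk4 <- find_peaks_wavelet(y, remove = 401)
  expect_identical(pk4, integer(0))
})

test_that("template extraction recovers noise-free amplitudes exactly", {
  gt <- ground_truth(seed = 31, noise_sd = 0)
  pr <- small_protocol(trains = 3)
  sim <- simulate_experiment(3, gt, pr)
  pk <- extract_peaks_at_template(sim)
  m <- merge(pk, sim$counts,
             by = c("roi_id", "condition", "train", "stimulus_index"))
  expect_lt(max(abs(m$amplitude - m$count * gt$q)), 0.01)
  # failures recorded as exactly 0
  expect_true(all(m$amplitude[m$count == 0] == 0))
  expect_true(all(m$is_failure[m$count == 0]))

  # single-ROI set: the ROI is its own mean waveform
  one <- simulate_experiment(1, gt, pr)
  pk1 <- extract_peaks_at_template(one)
  m1 <- merge(pk1, one$counts,
              by = c("roi_id", "condition", "train", "stimulus_index"))
  expect_lt(max(abs(m1$amplitude - m1$count * gt$q)), 0.01)

  expect_error(extract_peaks_at_template(sim, template = integer()),
               "template")
})

test_that("SNR and rundown exclusions flag ROIs with reasons", {
  amps <- list(
    good = rep(c(0.3, 0.28, 0.29, 0.3, 0.31), 10),
    fading = 0.3 * 0.9^(0:49),
    weak = rep(c(0.02, 0), 25))
  pk <- make_peak_table(amps, per_train = 5)
  pk$snr[pk$roi_id == "weak" & !pk$is_failure] <- 2.9  # boundary case
  out <- snr_and_exclusion(pk, min_snr = 3, rundown_cut = 0.5)
  expect_true(all(!out$excluded[out$roi_id == "good"]))
  expect_true(all(out$excluded[out$roi_id == "fading"]))
  expect_equal(unique(out$reason[out$roi_id == "fading"]), "rundown")
  expect_true(all(out$excluded[out$roi_id == "weak"]))
  expect_equal(unique(out$reason[out$roi_id == "weak"]), "low SNR")

  # exclusion is monotone in its thresholds
  loose <- snr_and_exclusion(pk, min_snr = 1, rundown_cut = 0.1)
  expect_true(all(which(loose$excluded) %in% which(out$excluded)))
  expect_lte(sum(loose$excluded), sum(out$excluded))
})
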