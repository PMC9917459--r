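# Shared fixtures for the test suite. Everything is generated in code.

# study-condition ground truth and protocol (small variants for speed)
study_gt <- function(seed = 1L, ...) {
  ground_truth(seed = seed, ...)
}

small_protocol <- function(trains = 4) {
  stim_protocol(trains_per_condition = trains)
}

# brute-force enumeration of binomial site outcomes: the independent oracle
# for the mixture weights (probability of k of N sites releasing)
enum_binom_weights <- function(n_sites, p) {
  w <- numeric(n_sites + 1)
  for (code in 0:(2^n_sites - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(n_sites)]
    k <- sum(bits)
    w[k + 1] <- w[k + 1] + p^k * (1 - p)^(n_sites - k)
  }
  w
}

# dense base-R ALS oracle (same iteration, dense linear algebra)
dense_als <- function(y, lambda, p, maxit = 10) {
  n <- length(y)
  D <- diff(diag(n), differences = 2)
  P <- lambda * crossprod(D)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(maxit)) {
    z <- solve(diag(w) + P, w * y)
    w_new <- ifelse(y > z, p, 1 - p)
    if (all(w_new == w)) break
    w <- w_new
  }
  z
}

# hand-built peak table with given per-(roi, condition, train) amplitudes
make_peak_table <- function(amplitudes, conditions = "2", n_train = NULL,
                            per_train = NULL) {
  rows <- list()
  for (r in names(amplitudes)) {
    a <- amplitudes[[r]]
    n <- length(a)
    pt <- per_train %||% n
    tr <- rep(seq_len(n / pt), each = pt)
    si <- rep(seq_len(pt), times = n / pt)
    for (cd in conditions) {
      rows[[paste(r, cd)]] <- data.frame(
        roi_id = r, condition = cd, train = tr, stimulus_index = si,
        frame = seq_len(n), amplitude = a, is_failure = a == 0,
        snr = ifelse(a == 0, 0, 10), ignored = FALSE, excluded = FALSE,
        reason = "", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "roi_stats") <- data.frame(roi_id = names(amplitudes),
                                       noise_sd = 0.01,
                                       stringsAsFactors = FALSE)
  class(out) <- c("peak_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny single-spot movie for detection tests: n_events transients whose
# TILE-LEVEL raw dF/F equals event_dff, on a constant background. The trace
# dF/F is scaled up to undo the background dilution of the 4x4 tile mean.
planted_spot_movie <- function(n_events = 25, event_dff = 0.12,
                               noise_sd = 0, background = 100,
                               spot_f0 = 900, dim = c(32, 32),
                               centre = c(14.5, 14.5), seed = 1L) {
  fr <- 25
  sigma_px <- 0.3 / 0.5
  # spot contribution to its central 4x4 tile mean (centre mid-tile)
  g <- expand.grid(dr = -1:2, dc = -1:2) - 0.5
  m <- spot_f0 * sum(exp(-(g$dr^2 + g$dc^2) / (2 * sigma_px^2))) / 16
  trace_dff <- event_dff * (background + m) / m
  n_frames <- 60 + n_events * 10
  sf <- as.integer(50 + (seq_len(n_events) - 1) * 10)
  dff <- numeric(n_frames)
  for (s in sf) {
    j <- 0:min(3, n_frames - s)
    dff[s + j] <- pmax(dff[s + j], trace_dff * exp(-j / 2))
  }
  simulate_movie(matrix(dff, ncol = 1), matrix(centre, ncol = 2),
                 dim = dim, spot_sigma_um = 0.3, pixel_size_um = 0.5,
                 background = background, spot_f0 = spot_f0,
                 noise_sd = noise_sd, frame_rate_hz = fr,
                 stimulus_frames = sf, seed = seed)
}
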