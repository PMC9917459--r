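ricker <- function(width, support = 5L) {
  t <- seq(-support * width, support * width)
  a <- width
  psi <- (1 - (t / a)^2) * exp(-t^2 / (2 * a^2))
  psi / sqrt(sum(psi^2))
}

cwt_ricker <- function(y, widths) {
  n <- length(y)
  out <- matrix(0, n, length(widths))
  for (j in seq_along(widths)) {
    psi <- ricker(widths[j])
    cf <- stats::filter(y, psi, sides = 2)
    cf[is.na(cf)] <- 0
    out[, j] <- cf
  }
  out
}

#' Wavelet-based peak detection
#'
#' Continuous wavelet transform with L2-normalised ricker (Mexican hat)
#' kernels over a range of widths. Candidate peaks are local maxima of the
#' across-scale maximum coefficient; a candidate is kept when its
#' coefficient clears `min_snr` times the noise scale on at least half of
#' the scales (a ridge requirement that suppresses single-scale noise
#' spikes). The `add`/`remove` arguments are the headless
#' curation hook: indices to force in or out of the result.
#'
#' @param y baseline-corrected series.
#' @param widths transient widths probed, in frames; should span the
#'   expected transient width.
#' @param min_snr coefficient signal-to-noise threshold.
#' @param noise optional noise scale; defaults to the robust SD (1.4826 x
#'   MAD) of the smallest-scale coefficients.
#' @param add integer indices to append to the result (curation).
#' @param remove indices to drop; a removal matches the nearest detected
#'   peak within 2 frames.
#' @return sorted integer vector of peak indices.
#' @export
find_peaks_wavelet <- function(y, widths = c(1, 2, 3, 4, 6, 8), min_snr = 3,
                               noise = NULL, add = NULL, remove = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (n == 0) return(integer(0))
  widths <- widths[widths * 2 + 1 <= n]
  if (!length(widths)) return(sort(unique(as.integer(add))))
  C <- cwt_ricker(y, widths)
  cmax <- apply(C, 1, max)
  noise <- noise %||% mad(C[, 1])
  if (noise <= 0) noise <- sd(C[, 1])
  peaks <- integer(0)
  if (!is.null(noise) && noise > 0 && n >= 3) {
    w <- max(1L, as.integer(round(min(widths))))
    is_max <- vapply(seq_len(n), function(i) {
      lo <- max(1, i - w); hi <- min(n, i + w)
      cmax[i] == max(cmax[lo:hi]) && cmax[i] > 0
    }, TRUE)
    # ridge requirement: the threshold must hold on at least half of the
    # scales, which suppresses single-scale noise excursions
    ridge_ok <- rowSums(C >= min_snr * noise) >= ceiling(ncol(C) / 2)
    snr_ok <- cmax / noise >= min_snr
    peaks <- which(is_max & ridge_ok & snr_ok)
    # collapse plateaus of equal coefficients
    if (length(peaks) > 1) {
      keep <- c(TRUE, diff(peaks) > w)
      peaks <- peaks[keep]
    }
    # the coefficient maximum of an asymmetric transient trails its true
    # maximum; localise each detection at the series maximum nearby
    if (length(peaks)) {
      peaks <- unique(vapply(peaks, function(i) {
        lo <- max(1L, i - 2L); hi <- min(n, i + 2L)
        lo + which.max(y[lo:hi]) - 1L
      }, integer(1)))
    }
  }
  if (!is.null(remove)) {
    for (r in remove) {
      if (!length(peaks)) break
      d <- abs(peaks - r)
      if (min(d) <= 2) peaks <- peaks[-which.min(d)]
    }
  }
  if (!is.null(add)) peaks <- c(peaks, as.integer(add))
  sort(unique(as.integer(peaks)))
}

#' Template peak locations for a trace set
#'
#' Runs ALS baseline subtraction on the across-ROI mean trace, finds its
#' peaks by wavelet transform, and maps every stimulus to the nearest
#' detected peak. Because the symmetric ricker kernel centres on the mass
#' of an instant-rise/exponential-decay transient rather than on its
#' maximum, the matched locations are then snapped to a consensus lag: the
#' stimulus-triggered average of the mean corrected trace determines the
#' offset of the true peak from the stimulus frame, and every template
#' location becomes stimulus frame plus that lag.
#'
#' @param ts a [trace_set()].
#' @param widths,min_snr passed to [find_peaks_wavelet()].
#' @param max_lag maximum frames a template peak may trail its stimulus.
#' @param als_smoothness,als_asymmetry ALS parameters.
#' @return integer vector of template frame indices, one per stimulus row.
#' @export
template_locations <- function(ts, widths = c(1, 2, 3, 4, 6, 8),
                               min_snr = 3, max_lag = 4,
                               als_smoothness = 1e4, als_asymmetry = 0.01) {
  stopifnot(inherits(ts, "trace_set"))
  keep <- ts$valid & colSums(is.na(ts$dff)) == 0
  m <- rowMeans(ts$dff[, keep, drop = FALSE])
  corrected <- m - als_baseline(m, als_smoothness, als_asymmetry)
  pk <- find_peaks_wavelet(corrected, widths, min_snr)
  sf <- ts$stim_table$frame
  loc <- rep(NA_integer_, length(sf))
  for (i in seq_along(sf)) {
    d <- pk - sf[i]
    ok <- which(d >= 0 & d <= max_lag)
    if (length(ok)) loc[i] <- pk[ok[which.min(d[ok])]]
  }
  # consensus peak lag from the stimulus-triggered average waveform
  nf <- length(corrected)
  trig <- vapply(0:max_lag, function(tau) {
    idx <- sf + tau
    mean(corrected[idx[idx <= nf]])
  }, 1)
  lag <- which.max(trig) - 1L
  loc[] <- sf + lag
  pmin(loc, nf)
}

# Per-frame decay factor of the response transient, estimated from the
# tail after the last stimulus of each train of a baseline-corrected trace.
estimate_decay_per_frame <- function(corrected, stim_table, tail_frames = 6) {
  last <- stim_table[stim_table$stimulus_index ==
                       max(stim_table$stimulus_index), , drop = FALSE]
  nf <- length(corrected)
  segs <- lapply(last$frame, function(s) {
    idx <- (s + 1):(s + tail_frames)
    idx <- idx[idx <= nf]
    corrected[idx]
  })
  len <- min(vapply(segs, length, 1L))
  if (len < 3) return(NA_real_)
  m <- colMeans(do.call(rbind, lapply(segs, function(x) x[seq_len(len)])))
  if (any(m <= 0)) return(NA_real_)
  fit <- stats::lm(log(m) ~ seq_along(m))
  rho <- exp(unname(coef(fit)[2]))
  if (!is.finite(rho) || rho <= 0 || rho >= 1) NA_real_ else rho
}

#' Extract per-stimulus peak amplitudes at template locations
#'
#' For every ROI and template location, the response amplitude is the
#' ALS-baseline-corrected trace at the template frame (default) or the
#' maximum within `search_halfwidth` frames of it, minus the
#' decay-extrapolated level immediately before the stimulus: responses
#' within a summating 5 Hz train measure the per-stimulus increment, with
#' the residual of earlier transients projected forward by the per-frame
#' decay factor estimated from the across-ROI mean waveform. Evaluating at
#' the template frame keeps the amplitude unbiased (a windowed maximum
#' adds the expected extreme of the window noise, about one noise SD, to
#' every response and distorts the quantal spacing); use
#' `amplitude_at = "window_max"` when per-ROI timing jitter is expected.
#' Responses below `failure_k` times the ROI's noise SD are failures and
#' recorded as exactly 0.
#'
#' @param ts a [trace_set()].
#' @param template integer template frame indices (one per stimulus row),
#'   e.g. from [template_locations()]; must be non-empty.
#' @param search_halfwidth frames searched either side of the template
#'   (used with `amplitude_at = "window_max"`).
#' @param amplitude_at `"template"` (unbiased, default) or `"window_max"`.
#' @param failure_k failure threshold in units of the per-ROI noise SD.
#' @param local_baseline subtract the immediately pre-stimulus level
#'   (default); `FALSE` uses the raw windowed maximum.
#' @param als_smoothness,als_asymmetry ALS parameters.
#' @param ignore_first_high_ca if `TRUE`, flag the very first response of
#'   the `high_ca_condition` block as ignored (it is often
#'   disproportionately large).
#' @param high_ca_condition condition label for that flag.
#' @return a `peak_table` data frame: one row per (ROI, stimulus) with
#'   `roi_id`, `condition`, `train`, `stimulus_index`, `frame`,
#'   `amplitude`, `is_failure`, `snr`, `ignored`, `excluded`, `reason`;
#'   per-ROI noise SDs in attribute `roi_stats`.
#' @export
extract_peaks_at_template <- function(ts, template = NULL,
                                      search_halfwidth = 2, failure_k = 2,
                                      amplitude_at = c("template",
                                                       "window_max"),
                                      local_baseline = TRUE,
                                      als_smoothness = 1e4,
                                      als_asymmetry = 0.01,
                                      ignore_first_high_ca = FALSE,
                                      high_ca_condition = "4") {
  stopifnot(inherits(ts, "trace_set"))
  amplitude_at <- match.arg(amplitude_at)
  st <- ts$stim_table
  if (is.null(st) || !nrow(st)) stop("trace set has no stimulus annotation")
  if (is.null(template)) {
    template <- template_locations(ts, als_smoothness = als_smoothness,
                                   als_asymmetry = als_asymmetry)
  }
  if (!length(template)) stop("template is empty")
  stopifnot(length(template) == nrow(st))
  nf <- nrow(ts$dff)
  n_roi <- ncol(ts$dff)
  # per-frame transient decay, from the across-ROI mean corrected trace
  rho <- 1
  if (local_baseline) {
    keep <- ts$valid & colSums(is.na(ts$dff)) == 0
    if (any(keep)) {
      m <- rowMeans(ts$dff[, keep, drop = FALSE])
      mc <- m - als_baseline(m, als_smoothness, als_asymmetry)
      rho_hat <- estimate_decay_per_frame(mc, st)
      if (!is.na(rho_hat)) rho <- rho_hat
    }
  }
  # quiet frames for the noise estimate: outside post-stimulus decay windows
  resp <- ceiling(0.6 * ts$frame_rate_hz)
  quiet <- rep(TRUE, nf)
  for (s in st$frame) {
    quiet[max(1, s - 2):min(nf, s + resp)] <- FALSE
  }
  if (sum(quiet) < 30) quiet <- rep(TRUE, nf)
  rows <- vector("list", n_roi)
  noise_sd <- numeric(n_roi)
  for (r in seq_len(n_roi)) {
    yr <- ts$dff[, r]
    if (!ts$valid[r] || anyNA(yr)) {
      noise_sd[r] <- NA_real_
      rows[[r]] <- data.frame(roi_id = ts$roi_ids[r],
                              condition = st$condition, train = st$train,
                              stimulus_index = st$stimulus_index,
                              frame = template, amplitude = NA_real_,
                              is_failure = NA, snr = NA_real_,
                              ignored = FALSE, stringsAsFactors = FALSE)
      next
    }
    corrected <- yr - als_baseline(yr, als_smoothness, als_asymmetry)
    noise <- mad(corrected[quiet])
    if (noise == 0) noise <- sd(corrected[quiet])
    amp <- numeric(nrow(st))
    for (i in seq_len(nrow(st))) {
      loc <- template[i]
      if (amplitude_at == "window_max") {
        win <- max(1, loc - search_halfwidth):min(nf, loc + search_halfwidth)
        ipk <- win[which.max(corrected[win])]
      } else {
        ipk <- loc
      }
      # with a known decay factor the peak frame and the next frame are both
      # unbiased peak estimates; averaging them reduces noise
      peak <- if (rho < 1 && ipk + 1 <= nf) {
        (corrected[ipk] + corrected[ipk + 1] / rho) / 2
      } else {
        corrected[ipk]
      }
      if (local_baseline) {
        s <- st$frame[i]
        pf <- (s - 2):(s - 1)
        pf <- pf[pf >= 1]
        if (length(pf)) {
          # residual of earlier transients at the peak frame, estimated from
          # each pre-stimulus frame projected forward by the decay
          res_est <- mean(corrected[pf] * rho^(ipk - pf))
          amp[i] <- peak - res_est
        } else {
          amp[i] <- peak
        }
      } else {
        amp[i] <- peak
      }
    }
    fail <- amp < failure_k * noise
    amp[fail] <- 0
    noise_sd[r] <- noise
    rows[[r]] <- data.frame(roi_id = ts$roi_ids[r], condition = st$condition,
                            train = st$train,
                            stimulus_index = st$stimulus_index,
                            frame = template, amplitude = amp,
                            is_failure = fail, snr = amp / noise,
                            ignored = FALSE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (ignore_first_high_ca) {
    first <- out$condition == high_ca_condition & out$train == 1 &
      out$stimulus_index == 1
    out$ignored[first] <- TRUE
  }
  out$excluded <- !rep(ts$valid, each = nrow(st))
  out$reason <- ifelse(out$excluded, "invalid F0", "")
  attr(out, "roi_stats") <- data.frame(roi_id = ts$roi_ids,
                                       noise_sd = noise_sd,
                                       stringsAsFactors = FALSE)
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Apply SNR and rundown exclusions to a peak table
#'
#' Flags whole ROIs: excluded with reason `"low SNR"` when the median event
#' SNR of non-failure responses is below `min_snr` (or there are no
#' events), and with reason `"rundown"` when the last-decile/first-decile
#' amplitude ratio falls below `rundown_cut`.
#'
#' @param peaks a `peak_table` from [extract_peaks_at_template()].
#' @param min_snr median event SNR threshold.
#' @param rundown_cut rundown-ratio threshold (strictly below excludes).
#' @return the peak table with updated `excluded`/`reason` columns and a
#'   per-ROI summary in attribute `roi_stats`.
#' @export
snr_and_exclusion <- function(peaks, min_snr = 3, rundown_cut = 0.5) {
  stopifnot(inherits(peaks, "peak_table"))
  stats <- attr(peaks, "roi_stats")
  stats$median_snr <- NA_real_
  stats$rundown <- NA_real_
  for (i in seq_len(nrow(stats))) {
    rid <- stats$roi_id[i]
    rows <- peaks$roi_id == rid
    if (any(peaks$excluded[rows])) next
    ev <- peaks$snr[rows & !peaks$is_failure & !peaks$ignored]
    med <- if (length(ev)) median(ev) else 0
    stats$median_snr[i] <- med
    amps <- peaks$amplitude[rows & !peaks$ignored]
    # an all-failure first decile leaves the ratio undefined: the NA in
    # the per-ROI stats is the flag, no exclusion
    rd <- if (length(amps) >= 10) {
      suppressWarnings(rundown_ratio(amps))
    } else NA_real_
    stats$rundown[i] <- rd
    if (med < min_snr) {
      peaks$excluded[rows] <- TRUE
      peaks$reason[rows] <- "low SNR"
    } else if (!is.na(rd) && rd < rundown_cut) {
      peaks$excluded[rows] <- TRUE
      peaks$reason[rows] <- "rundown"
    }
  }
  attr(peaks, "roi_stats") <- stats
  peaks
}

#' Write a peak table to CSV
#' @param peaks a `peak_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks_csv <- function(peaks, path) {
  write.csv(as.data.frame(peaks)[, c("roi_id", "condition", "train",
                                     "stimulus_index", "amplitude",
                                     "is_failure", "ignored", "excluded",
                                     "reason")],
            path, row.names = FALSE)
  invisible(path)
}
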