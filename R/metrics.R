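#' Rundown ratio of an ordered response sequence
#'
#' Mean of the last decile of responses divided by the mean of the first
#' decile (decile size `ceiling(0.1 * n)`). ROIs with ratio strictly below
#' 0.5 are conventionally classified as showing rundown.
#'
#' @param amplitudes ordered response amplitudes (>= 10 values).
#' @return the ratio, with attribute `rundown_gt_50` (logical); `NA` with a
#'   warning when the first-decile mean is 0.
#' @export
rundown_ratio <- function(amplitudes) {
  n <- length(amplitudes)
  if (n < 10) stop("rundown_ratio needs at least 10 responses")
  k <- ceiling(0.1 * n)
  first <- mean(amplitudes[seq_len(k)])
  last <- mean(amplitudes[(n - k + 1):n])
  if (first == 0) {
    warning("first-decile mean is 0; rundown ratio undefined")
    return(structure(NA_real_, rundown_gt_50 = NA))
  }
  r <- last / first
  structure(r, rundown_gt_50 = r < 0.5)
}

#' Short-term depression ratio of one train
#'
#' Last amplitude divided by the first amplitude of a stimulus train.
#'
#' @param train_amplitudes ordered amplitudes of one train (>= 2).
#' @return the ratio; `NA` with a warning when the first amplitude is 0.
#' @export
depression_ratio <- function(train_amplitudes) {
  if (length(train_amplitudes) < 2) {
    stop("depression_ratio needs at least 2 amplitudes")
  }
  if (train_amplitudes[1] == 0) {
    warning("first amplitude is 0; depression ratio undefined for this train")
    return(NA_real_)
  }
  train_amplitudes[length(train_amplitudes)] / train_amplitudes[1]
}

#' Per-cell depression from a peak table
#'
#' Computes the per-train last/first amplitude ratio for every (ROI, train)
#' of one condition and averages: first within ROI over its trains, then
#' across ROIs. Trains whose first amplitude is 0 are dropped.
#'
#' @param peaks a `peak_table`.
#' @param condition condition label.
#' @param per_roi if `TRUE` return the per-ROI means instead of the cell
#'   mean.
#' @return mean depression ratio (or named per-ROI vector).
#' @export
depression_by_train <- function(peaks, condition, per_roi = FALSE) {
  sub <- peaks[peaks$condition == condition & !peaks$excluded &
                 !peaks$ignored, , drop = FALSE]
  if (!nrow(sub)) stop("no usable responses in condition ", condition)
  rois <- unique(sub$roi_id)
  per <- vapply(rois, function(r) {
    s <- sub[sub$roi_id == r, , drop = FALSE]
    ratios <- vapply(unique(s$train), function(tr) {
      a <- s$amplitude[s$train == tr][order(s$stimulus_index[s$train == tr])]
      if (length(a) < 2 || a[1] == 0) return(NA_real_)
      a[length(a)] / a[1]
    }, 1)
    mean(ratios, na.rm = TRUE)
  }, 1)
  names(per) <- rois
  if (per_roi) per else mean(per, na.rm = TRUE)
}

#' Pearson correlation between two dF/F traces
#'
#' @param trace_a,trace_b equal-length numeric series (>= 3 samples).
#' @return Pearson r in `[-1, 1]`; `NA` when either trace has zero
#'   variance.
#' @export
neighbour_correlation <- function(trace_a, trace_b) {
  stopifnot(length(trace_a) == length(trace_b), length(trace_a) >= 3)
  if (sd(trace_a) == 0 || sd(trace_b) == 0) return(NA_real_)
  cor(trace_a, trace_b)
}

#' Gaussian fit of a 1-D intensity line profile
#'
#' Least-squares fit of `amplitude * exp(-(x - x0)^2 / (2 sigma^2)) +
#' offset`. Both the Gaussian sigma and the full width at half maximum
#' (`2.3548 * sigma`) are reported, since "width" conventions differ.
#'
#' @param position_um positions along the profile (micrometres, >= 5
#'   samples).
#' @param intensity intensities at those positions; must show a single
#'   dominant maximum.
#' @return list with `sigma_um`, `fwhm_um`, `centre_um`, `amplitude`,
#'   `offset` and `converged`; fit failure gives `converged = FALSE` with
#'   a diagnostic message attribute.
#' @export
gaussian_profile_width <- function(position_um, intensity) {
  stopifnot(length(position_um) == length(intensity))
  if (length(intensity) < 5) stop("profile needs at least 5 samples")
  rng <- diff(range(intensity))
  if (rng == 0) stop("flat profile: no dominant maximum")
  med <- median(intensity)
  if (max(intensity) - med < 0.2 * rng) {
    stop("profile has no dominant maximum")
  }
  off0 <- min(intensity)
  amp0 <- max(intensity) - off0
  x0 <- position_um[which.max(intensity)]
  wgt <- pmax(intensity - off0, 0)
  sig0 <- sqrt(sum(wgt * (position_um - x0)^2) / sum(wgt))
  if (!is.finite(sig0) || sig0 <= 0) sig0 <- diff(range(position_um)) / 6
  x <- position_um; y <- intensity
  sse <- function(par) {
    mu <- par[2]; s <- exp(par[3])
    sum((y - (par[1] * exp(-(x - mu)^2 / (2 * s^2)) + par[4]))^2)
  }
  fit <- tryCatch(
    stats::optim(c(amp0, x0, log(sig0), off0), sse,
                 method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12)),
    error = function(e) e)
  bad <- inherits(fit, "error") || !is.finite(fit$value) ||
    fit$convergence != 0
  if (bad) {
    msg <- if (inherits(fit, "error")) conditionMessage(fit) else
      "optimiser did not converge"
    return(structure(list(sigma_um = NA_real_, fwhm_um = NA_real_,
                          centre_um = NA_real_, amplitude = NA_real_,
                          offset = NA_real_, converged = FALSE),
                     diagnostic = msg))
  }
  s <- exp(fit$par[3])
  list(sigma_um = s, fwhm_um = 2 * sqrt(2 * log(2)) * s,
       centre_um = fit$par[2], amplitude = fit$par[1],
       offset = fit$par[4], converged = TRUE)
}

#' NBQX-based correction of miniature event statistics
#'
#' Spontaneous (miniature) event frequency is corrected by subtracting the
#' false-positive rate measured in the AMPA-receptor blocker NBQX; the
#' amplitude is the frequency-weighted difference
#' `(f_ctrl * a_ctrl - f_nbqx * a_nbqx) / (f_ctrl - f_nbqx)`. The record is
#' discarded when the two frequencies differ by less than 0.1 Hz, when the
#' NBQX amplitude is not smaller than control, or when the NBQX frequency
#' exceeds control.
#'
#' @param freq_ctrl,freq_nbqx event frequencies (Hz, >= 0).
#' @param amp_ctrl,amp_nbqx mean event amplitudes (pA, >= 0).
#' @return list with `discarded` (logical), `reason`, and (when kept)
#'   `frequency_hz` and `amplitude_pa`.
#' @export
correct_minis <- function(freq_ctrl, freq_nbqx, amp_ctrl, amp_nbqx) {
  vals <- c(freq_ctrl, freq_nbqx, amp_ctrl, amp_nbqx)
  if (any(vals < 0)) stop("all inputs must be >= 0")
  if (abs(freq_ctrl - freq_nbqx) < 0.1) {
    return(list(discarded = TRUE, reason = "frequency difference < 0.1 Hz"))
  }
  if (freq_nbqx > freq_ctrl) {
    return(list(discarded = TRUE, reason = "higher frequency in NBQX"))
  }
  if (amp_nbqx >= amp_ctrl) {
    return(list(discarded = TRUE, reason = "NBQX amplitude not below control"))
  }
  f <- freq_ctrl - freq_nbqx
  a <- (freq_ctrl * amp_ctrl - freq_nbqx * amp_nbqx) / f
  list(discarded = FALSE, reason = "", frequency_hz = f, amplitude_pa = a)
}
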