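#' Select a background region of a movie
#'
#' Finds the circular region of the given diameter with the smallest mean
#' intensity whose time series shows no stimulus-locked change; its
#' frame-wise mean is the background signal. Candidate centres are ranked by
#' mean intensity; a candidate is rejected when any stimulus-locked
#' amplitude of its trace exceeds 3 robust SDs. When every candidate is
#' stimulus-modulated the dimmest region is used with a warning.
#'
#' @param movie a [fluor_movie()].
#' @param diameter_um diameter of the background region (micrometres);
#'   at least one pixel.
#' @param max_candidates number of dimmest candidate regions to test.
#' @return list with `centre` (row, col), `pixels` (indices), `series`
#'   (frame-wise mean), `mean` intensity, and `stimulus_modulated` flag.
#' @export
select_background_roi <- function(movie, diameter_um = 1,
                                  max_candidates = 25) {
  stopifnot(inherits(movie, "fluor_movie"))
  r_px <- max(1, diameter_um / 2 / movie$pixel_size_um)
  nr <- movie$nrow; nc <- movie$ncol
  mean_img <- matrix(colMeans(movie$data), nr, nc)
  step <- max(1L, as.integer(floor(r_px)))
  cr <- seq(ceiling(r_px) + 1L, nr - ceiling(r_px), by = step)
  cc <- seq(ceiling(r_px) + 1L, nc - ceiling(r_px), by = step)
  cand <- expand.grid(row = cr, col = cc)
  disk <- function(r0, c0) {
    rr <- max(1, floor(r0 - r_px)):min(nr, ceiling(r0 + r_px))
    cc2 <- max(1, floor(c0 - r_px)):min(nc, ceiling(c0 + r_px))
    g <- expand.grid(row = rr, col = cc2)
    g <- g[(g$row - r0)^2 + (g$col - c0)^2 <= r_px^2, , drop = FALSE]
    (g$col - 1L) * nr + g$row
  }
  cand$mean <- vapply(seq_len(nrow(cand)), function(i) {
    mean(mean_img[disk(cand$row[i], cand$col[i])])
  }, 1)
  cand <- cand[order(cand$mean), , drop = FALSE]
  sf <- movie$stimulus_frames
  check <- function(series) {
    if (!length(sf)) return(FALSE)
    noise <- mad(series)
    if (noise == 0) return(FALSE)
    amps <- stim_event_amplitudes(matrix(series, ncol = 1), sf)
    max(abs(amps)) > 3 * noise
  }
  n_try <- min(max_candidates, nrow(cand))
  for (i in seq_len(n_try)) {
    px <- disk(cand$row[i], cand$col[i])
    series <- rowMeans(movie$data[, px, drop = FALSE])
    if (!check(series)) {
      return(list(centre = c(cand$row[i], cand$col[i]), pixels = px,
                  series = series, mean = cand$mean[i],
                  stimulus_modulated = FALSE))
    }
  }
  warning("all candidate background regions are stimulus-modulated; ",
          "falling back to the dimmest region")
  px <- disk(cand$row[1], cand$col[1])
  list(centre = c(cand$row[1], cand$col[1]), pixels = px,
       series = rowMeans(movie$data[, px, drop = FALSE]),
       mean = cand$mean[1], stimulus_modulated = TRUE)
}

#' Mean raw intensity traces of composite ROIs
#' @param movie a [fluor_movie()].
#' @param rois a [merge_contiguous()] result.
#' @return frames x ROIs matrix of mean intensities.
#' @export
extract_roi_traces <- function(movie, rois) {
  out <- matrix(0, nrow(movie$data), nrow(rois))
  for (i in seq_len(nrow(rois))) {
    out[, i] <- rowMeans(movie$data[, roi_pixels(rois, i), drop = FALSE])
  }
  colnames(out) <- rois$roi_id
  out
}

#' Convert raw traces to dF/F
#'
#' Frame-wise background subtraction followed by normalisation to the
#' baseline median: `F_j = raw_j - background_j`, `F0 = median(F[baseline])`,
#' `dff_j = (F_j - F0) / F0`. Series whose F0 is not positive are flagged
#' invalid and returned as `NA`.
#'
#' @param raw numeric vector or frames x ROIs matrix of raw intensities.
#' @param background background series (same length as the traces), or a
#'   scalar.
#' @param baseline_window frame indices used for F0 (must precede the first
#'   stimulus).
#' @return list with `dff` (same shape as `raw`), `f0` (per series) and
#'   `valid` (logical per series).
#' @export
compute_dff <- function(raw, background, baseline_window) {
  raw <- as.matrix(raw)
  if (length(background) == 1) background <- rep(background, nrow(raw))
  stopifnot(length(background) == nrow(raw), length(baseline_window) >= 1)
  f <- raw - background
  f0 <- apply(f[baseline_window, , drop = FALSE], 2, median)
  valid <- f0 > 0
  dff <- sweep(f, 2, ifelse(valid, f0, 1), "/") - 1
  dff[, !valid] <- NA_real_
  list(dff = dff, f0 = f0, valid = valid)
}

#' Build a trace set from a movie and a ROI set
#'
#' Runs [select_background_roi()], [extract_roi_traces()] and
#' [compute_dff()]; the baseline window defaults to every frame before the
#' first stimulus.
#'
#' @param movie a [fluor_movie()] with stimulus frames.
#' @param rois a [merge_contiguous()] result.
#' @param background optional precomputed [select_background_roi()] result.
#' @param baseline_window optional frame indices for F0.
#' @param protocol optional [stim_protocol()] annotation.
#' @return a [trace_set()]; ROIs with invalid F0 carry `NA` traces and are
#'   flagged in `$valid`.
#' @export
movie_to_traceset <- function(movie, rois, background = NULL,
                              baseline_window = NULL, protocol = NULL) {
  sf <- movie$stimulus_frames
  if (!length(sf)) stop("movie has no stimulus frames")
  baseline_window <- baseline_window %||% seq_len(max(2L, sf[1] - 1L))
  background <- background %||% select_background_roi(movie)
  raw <- extract_roi_traces(movie, rois)
  d <- compute_dff(raw, background$series, baseline_window)
  st <- movie$stim_table
  if (is.null(st)) {
    st <- data.frame(condition = "all", train = 1L,
                     stimulus_index = seq_along(sf), global_train = 1L,
                     time_s = (sf - 1) / movie$frame_rate_hz, frame = sf)
  }
  ts <- trace_set(d$dff, movie$frame_rate_hz, st, protocol = protocol,
                  f0 = d$f0, raw = raw - background$series,
                  roi_ids = rois$roi_id, valid = d$valid)
  ts$background <- background
  ts
}

#' Per-train baseline stability
#'
#' Recomputes F0 for every stimulus train from the frames immediately
#' preceding it and summarises drift as
#' `(last train F0 - first train F0) / first train F0` per ROI. Requires
#' raw (background-subtracted) intensities, i.e. a trace set built from a
#' movie, or a raw matrix passed directly.
#'
#' @param x a [trace_set()] with `$raw`, or a frames x ROIs raw matrix.
#' @param stim_table required when `x` is a matrix.
#' @param pre_frames number of frames before each train used for F0.
#' @return list with `f0_per_train` (trains x ROIs) and `drift_fraction`
#'   (per ROI).
#' @export
f0_stability <- function(x, stim_table = NULL, pre_frames = 10) {
  if (inherits(x, "trace_set")) {
    if (is.null(x$raw)) {
      stop("trace set carries no raw intensities; build it from a movie")
    }
    stim_table <- stim_table %||% x$stim_table
    x <- x$raw
  }
  stopifnot(is.matrix(x), !is.null(stim_table))
  starts <- stim_table$frame[stim_table$stimulus_index == 1]
  if (length(starts) < 2) stop("f0_stability needs at least 2 trains")
  f0 <- matrix(0, length(starts), ncol(x))
  for (i in seq_along(starts)) {
    win <- max(1, starts[i] - pre_frames):max(1, starts[i] - 1)
    f0[i, ] <- apply(x[win, , drop = FALSE], 2, median)
  }
  drift <- (f0[nrow(f0), ] - f0[1, ]) / f0[1, ]
  list(f0_per_train = f0, drift_fraction = drift)
}
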