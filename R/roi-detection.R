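#' Tile acceptance criteria for responsive-ROI detection
#'
#' A movie is scanned in non-overlapping square tiles; a tile is accepted
#' when its mean-intensity time series shows more than `min_peaks`
#' stimulus-locked transients, each with dF/F at least `min_event_dff` and
#' event SNR at least `min_snr`.
#'
#' @param tile_size_px tile edge length in pixels.
#' @param min_event_dff minimum per-event dF/F (fraction).
#' @param min_snr minimum per-event signal-to-noise ratio; the noise
#'   estimate is the robust SD (1.4826 x MAD) of the tile's dF/F trace.
#' @param min_peaks qualifying-event count threshold; acceptance requires
#'   strictly more than this many events.
#' @return an object of class `tile_criteria`.
#' @export
tile_criteria <- function(tile_size_px = 4, min_event_dff = 0.10,
                          min_snr = 3, min_peaks = 20) {
  stopifnot(tile_size_px >= 1, min_event_dff > 0, min_snr > 0, min_peaks > 0)
  structure(list(tile_size_px = as.integer(tile_size_px),
                 min_event_dff = min_event_dff, min_snr = min_snr,
                 min_peaks = as.integer(min_peaks)),
            class = "tile_criteria")
}

# Mean-intensity time series of every complete tile: frames x tiles matrix.
tile_mean_traces <- function(movie, ts) {
  nr <- movie$nrow; nc <- movie$ncol
  ntr <- nr %/% ts; ntc <- nc %/% ts
  tr0 <- rep(seq_len(ntr), times = ntc)
  tc0 <- rep(seq_len(ntc), each = ntr)
  acc <- matrix(0, nrow(movie$data), ntr * ntc)
  for (dr in seq_len(ts)) {
    for (dc in seq_len(ts)) {
      row <- (tr0 - 1L) * ts + dr
      col <- (tc0 - 1L) * ts + dc
      acc <- acc + movie$data[, (col - 1L) * nr + row]
    }
  }
  list(traces = acc / (ts * ts), tile_row = tr0, tile_col = tc0,
       n_tile_rows = ntr, n_tile_cols = ntc)
}

# Stimulus-locked event amplitudes on a dff matrix (frames x series):
# windowed max after the stimulus minus the immediately pre-stimulus level.
stim_event_amplitudes <- function(dff, stimulus_frames, halfwidth = 2) {
  nf <- nrow(dff)
  amps <- matrix(0, length(stimulus_frames), ncol(dff))
  for (i in seq_along(stimulus_frames)) {
    s <- stimulus_frames[i]
    win <- s:min(nf, s + halfwidth)
    pre <- max(1, s - 2):max(1, s - 1)
    peak <- do.call(pmax, lapply(win, function(j) dff[j, ]))
    base <- colMeans(dff[pre, , drop = FALSE])
    amps[i, ] <- peak - base
  }
  amps
}

#' Scan a movie for responsive tiles
#'
#' Evaluates every complete `tile_size_px` x `tile_size_px` tile (edge
#' remainders are dropped) on its raw mean-intensity trace: dF/F is computed
#' against the median of the pre-stimulus window, stimulus-locked transient
#' amplitudes are measured as the post-stimulus windowed maximum minus the
#' immediately pre-stimulus level, and the tile is accepted when more than
#' `min_peaks` transients pass both the amplitude and the SNR threshold.
#' Tiles with non-positive baseline or zero variance are rejected (not an
#' error).
#'
#' @param movie a [fluor_movie()] with stimulus frames; must cover at least
#'   one stimulus train.
#' @param criteria a [tile_criteria()].
#' @param search_halfwidth frames after each stimulus searched for the peak.
#' @return data frame with one row per tile (`tile_row`, `tile_col`,
#'   `n_events`, `f0`, `noise`, `accepted`) and attributes `tile_size_px`,
#'   `grid_dim`, `pixel_size_um`, `image_dim`.
#' @export
scan_tiles <- function(movie, criteria = tile_criteria(),
                       search_halfwidth = 2) {
  stopifnot(inherits(movie, "fluor_movie"), inherits(criteria, "tile_criteria"))
  if (nrow(movie$data) < 2) stop("movie must have at least 2 frames")
  sf <- movie$stimulus_frames
  if (!length(sf)) stop("movie has no stimulus frames")
  if (max(sf) > nrow(movie$data)) {
    stop("movie shorter than one stimulus train")
  }
  tm <- tile_mean_traces(movie, criteria$tile_size_px)
  baseline_win <- seq_len(max(2L, sf[1] - 1L))
  f0 <- apply(tm$traces[baseline_win, , drop = FALSE], 2, median)
  ok <- f0 > 0
  dff <- sweep(tm$traces, 2, ifelse(ok, f0, 1), "/") - 1
  noise <- apply(dff, 2, mad)
  # noise-free responsive tiles have zero MAD: fall back to an epsilon so
  # their events pass on amplitude alone; constant tiles still yield no
  # qualifying events and are rejected
  den <- pmax(noise, .Machine$double.eps)
  amps <- stim_event_amplitudes(dff, sf, search_halfwidth)
  snr <- sweep(amps, 2, den, "/")
  qual <- amps >= criteria$min_event_dff & snr >= criteria$min_snr
  n_events <- colSums(qual)
  accepted <- ok & n_events > criteria$min_peaks
  out <- data.frame(tile_row = tm$tile_row, tile_col = tm$tile_col,
                    n_events = as.integer(n_events), f0 = f0, noise = noise,
                    accepted = accepted)
  attr(out, "tile_size_px") <- criteria$tile_size_px
  attr(out, "grid_dim") <- c(tm$n_tile_rows, tm$n_tile_cols)
  attr(out, "pixel_size_um") <- movie$pixel_size_um
  attr(out, "image_dim") <- c(movie$nrow, movie$ncol)
  out
}

#' Merge contiguous accepted tiles into composite ROIs
#'
#' 4-connected components of the accepted tile grid become one composite ROI
#' each; composite area equals `tile_count * tile_size_px^2 *
#' pixel_size_um^2` and ROIs are disjoint by construction.
#'
#' @param tiles output of [scan_tiles()] (or a data frame with `tile_row`,
#'   `tile_col`, `accepted`, plus the same attributes).
#' @param pixel_size_um pixel size; defaults to the attribute carried by
#'   `tiles`.
#' @return an object of class `roi_set`: a data frame with one row per ROI
#'   (`roi_id`, `tile_count`, `pixel_count`, `area_um2`, centroid in pixels)
#'   and an attribute `tiles` listing each ROI's member tiles.
#' @export
merge_contiguous <- function(tiles, pixel_size_um = NULL) {
  ts <- attr(tiles, "tile_size_px")
  gd <- attr(tiles, "grid_dim")
  pixel_size_um <- pixel_size_um %||% attr(tiles, "pixel_size_um")
  stopifnot(!is.null(ts), !is.null(gd), !is.null(pixel_size_um))
  acc <- tiles[tiles$accepted, , drop = FALSE]
  lab <- matrix(0L, gd[1], gd[2])
  lab[cbind(acc$tile_row, acc$tile_col)] <- -1L
  nxt <- 0L
  comp_tiles <- list()
  for (i in seq_len(nrow(acc))) {
    r <- acc$tile_row[i]; c <- acc$tile_col[i]
    if (lab[r, c] != -1L) next
    nxt <- nxt + 1L
    queue <- matrix(c(r, c), 1)
    lab[r, c] <- nxt
    members <- queue
    while (nrow(queue)) {
      cur <- queue[1, , drop = FALSE]
      queue <- queue[-1, , drop = FALSE]
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- cur[1] + d[1]; cc <- cur[2] + d[2]
        if (rr >= 1 && rr <= gd[1] && cc >= 1 && cc <= gd[2] &&
            lab[rr, cc] == -1L) {
          lab[rr, cc] <- nxt
          queue <- rbind(queue, c(rr, cc))
          members <- rbind(members, c(rr, cc))
        }
      }
    }
    comp_tiles[[nxt]] <- members
  }
  n <- length(comp_tiles)
  out <- data.frame(
    roi_id = if (n) paste0("roi_", seq_len(n)) else character(),
    tile_count = if (n) vapply(comp_tiles, nrow, 1L) else integer(),
    stringsAsFactors = FALSE)
  out$pixel_count <- out$tile_count * ts^2
  out$area_um2 <- out$pixel_count * pixel_size_um^2
  out$centroid_row <- if (n) vapply(comp_tiles, function(m) {
    mean((m[, 1] - 0.5) * ts + 0.5)
  }, 1) else numeric()
  out$centroid_col <- if (n) vapply(comp_tiles, function(m) {
    mean((m[, 2] - 0.5) * ts + 0.5)
  }, 1) else numeric()
  attr(out, "tiles") <- comp_tiles
  attr(out, "tile_size_px") <- ts
  attr(out, "grid_dim") <- gd
  attr(out, "image_dim") <- attr(tiles, "image_dim")
  attr(out, "pixel_size_um") <- pixel_size_um
  class(out) <- c("roi_set", "data.frame")
  out
}

#' Pixel indices of one composite ROI
#' @param rois a [merge_contiguous()] result.
#' @param i ROI row index.
#' @return integer pixel indices (column-major over the image).
#' @export
roi_pixels <- function(rois, i) {
  ts <- attr(rois, "tile_size_px")
  id <- attr(rois, "image_dim")
  m <- attr(rois, "tiles")[[i]]
  px <- integer(0)
  for (j in seq_len(nrow(m))) {
    rows <- (m[j, 1] - 1L) * ts + seq_len(ts)
    cols <- (m[j, 2] - 1L) * ts + seq_len(ts)
    px <- c(px, as.vector(outer(rows, (cols - 1L) * id[1], `+`)))
  }
  sort(px)
}

#' Count and size summary of a ROI set
#'
#' @param rois a [merge_contiguous()] result (or data frame with
#'   `area_um2`).
#' @return list with `count`, `areas` (um^2) and `mean_area` (um^2; `NA`
#'   for an empty set).
#' @export
roi_count_and_sizes <- function(rois) {
  n <- nrow(rois)
  list(count = n, areas = rois$area_um2,
       mean_area = if (n) mean(rois$area_um2) else NA_real_)
}

#' Write ROI masks as a labelled 16-bit TIFF plus a CSV summary
#'
#' @param rois a [merge_contiguous()] result.
#' @param tiff_path output path for the label mask (ROI i has value i).
#' @param csv_path output path for the per-ROI summary table.
#' @return `tiff_path`, invisibly.
#' @export
write_roi_masks <- function(rois, tiff_path, csv_path) {
  id <- attr(rois, "image_dim")
  mask <- matrix(0L, id[1], id[2])
  for (i in seq_len(nrow(rois))) mask[roi_pixels(rois, i)] <- i
  tiff::writeTIFF(mask / 65535, tiff_path, bits.per.sample = 16L)
  write.csv(as.data.frame(rois)[, c("roi_id", "tile_count", "pixel_count",
                                    "area_um2", "centroid_row",
                                    "centroid_col")],
            csv_path, row.names = FALSE)
  invisible(tiff_path)
}
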