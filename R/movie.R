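#' Construct a fluorescence movie object
#'
#' Frames are stored as rows of a frames x pixels matrix; pixel index is
#' column-major over the image (`(col - 1) * nrow + row`), matching R's
#' matrix layout.
#'
#' @param data frames x pixels numeric matrix of intensities (camera counts).
#' @param nrow,ncol image dimensions in pixels.
#' @param frame_rate_hz frames per second.
#' @param pixel_size_um pixel size in micrometres.
#' @param stimulus_frames integer frame indices of stimuli (strictly
#'   increasing, within range).
#' @param stim_table optional per-stimulus annotation ([stimulus_table()]).
#' @return an object of class `fluor_movie`.
#' @export
fluor_movie <- function(data, nrow, ncol, frame_rate_hz, pixel_size_um,
                        stimulus_frames = integer(), stim_table = NULL) {
  stopifnot(is.matrix(data), ncol(data) == nrow * ncol, pixel_size_um > 0)
  if (any(data < 0)) stop("intensities must be >= 0")
  if (length(stimulus_frames)) {
    if (is.unsorted(stimulus_frames, strictly = TRUE)) {
      stop("stimulus_frames must be strictly increasing")
    }
    if (min(stimulus_frames) < 1 || max(stimulus_frames) > base::nrow(data)) {
      stop("stimulus_frames outside the movie")
    }
  }
  structure(list(data = data, nrow = as.integer(nrow),
                 ncol = as.integer(ncol), frame_rate_hz = frame_rate_hz,
                 pixel_size_um = pixel_size_um,
                 stimulus_frames = as.integer(stimulus_frames),
                 stim_table = stim_table),
            class = "fluor_movie")
}

#' @export
print.fluor_movie <- function(x, ...) {
  cat("<fluor_movie> ", nrow(x$data), " frames of ", x$nrow, "x", x$ncol,
      " px @ ", x$frame_rate_hz, " Hz (", x$pixel_size_um, " um/px), ",
      length(x$stimulus_frames), " stimuli\n", sep = "")
  invisible(x)
}

#' Extract one frame of a movie as an image matrix
#' @param movie a [fluor_movie()].
#' @param i frame index.
#' @return nrow x ncol matrix.
#' @export
movie_frame <- function(movie, i) {
  matrix(movie$data[i, ], movie$nrow, movie$ncol)
}

#' Render dF/F traces into a synthetic fluorescence movie
#'
#' Places one Gaussian spot per ROI on a constant background. Each spot has a
#' static brightness `spot_f0 * k(x)` and a response `gain * dff_t * k(x)`,
#' where `k(x) = exp(-d^2 / (2 * sigma_px^2))` is the unit-peak footprint.
#' With `gain = spot_f0` the spot fluorescence is `spot_f0 * k(x) *
#' (1 + dff_t)`, so the trace's dF/F is recovered exactly by
#' background-subtracted trace extraction. Optional Gaussian camera noise
#' and Poisson shot noise can be added.
#'
#' @param traces a [trace_set()] or a frames x ROIs dF/F matrix.
#' @param centres ROIs x 2 matrix of spot centres (row, col), in pixels;
#'   fractional positions allowed. Must lie inside the frame.
#' @param dim image dimensions `c(nrow, ncol)` in pixels.
#' @param spot_sigma_um Gaussian footprint standard deviation(s), recycled
#'   across spots (micrometres).
#' @param pixel_size_um pixel size (micrometres).
#' @param background constant background level (counts).
#' @param spot_f0 static peak brightness of each spot above background
#'   (counts), recycled.
#' @param gain peak response amplitude per unit dF/F (counts), recycled;
#'   defaults to `spot_f0`.
#' @param noise_sd Gaussian camera noise SD (counts; 0 disables).
#' @param shot_noise if `TRUE`, replace intensities by Poisson draws.
#' @param frame_rate_hz,stimulus_frames movie metadata; taken from `traces`
#'   when it is a `trace_set`.
#' @param seed seed for the noise draws.
#' @return a [fluor_movie()].
#' @export
simulate_movie <- function(traces, centres, dim = c(64, 64),
                           spot_sigma_um = 0.3, pixel_size_um = 0.5,
                           background = 100, spot_f0 = 0, gain = NULL,
                           noise_sd = 0, shot_noise = FALSE,
                           frame_rate_hz = NULL, stimulus_frames = NULL,
                           seed = 1L) {
  stim_table <- NULL
  if (inherits(traces, "trace_set")) {
    frame_rate_hz <- frame_rate_hz %||% traces$frame_rate_hz
    if (is.null(stimulus_frames) && !is.null(traces$stim_table)) {
      stimulus_frames <- sort(unique(traces$stim_table$frame))
      stim_table <- traces$stim_table
    }
    traces <- traces$dff
  }
  traces <- as.matrix(traces)
  centres <- matrix(centres, ncol = 2)
  ns <- nrow(centres)
  stopifnot(ncol(traces) == ns, pixel_size_um > 0)
  nr <- dim[1]; nc <- dim[2]
  if (any(centres[, 1] < 1 | centres[, 1] > nr |
          centres[, 2] < 1 | centres[, 2] > nc)) {
    stop("spot centres must lie inside the frame")
  }
  if (anyDuplicated(round(centres, 6))) {
    message("simulate_movie: overlapping spot centres")
  }
  spot_sigma_um <- rep_len(spot_sigma_um, ns)
  spot_f0 <- rep_len(spot_f0, ns)
  gain <- rep_len(gain %||% spot_f0, ns)
  nf <- nrow(traces)
  dat <- matrix(background, nf, nr * nc)
  for (s in seq_len(ns)) {
    sig <- spot_sigma_um[s] / pixel_size_um
    rad <- max(1L, as.integer(ceiling(4 * sig)))
    r0 <- max(1L, as.integer(floor(centres[s, 1] - rad)))
    r1 <- min(nr, as.integer(ceiling(centres[s, 1] + rad)))
    c0 <- max(1L, as.integer(floor(centres[s, 2] - rad)))
    c1 <- min(nc, as.integer(ceiling(centres[s, 2] + rad)))
    rr <- r0:r1; cc <- c0:c1
    kr <- exp(-(rr - centres[s, 1])^2 / (2 * sig^2))
    kc <- exp(-(cc - centres[s, 2])^2 / (2 * sig^2))
    k <- as.vector(outer(kr, kc))
    px <- as.vector(outer(rr, (cc - 1L) * nr, `+`))
    amp <- spot_f0[s] + gain[s] * traces[, s]
    dat[, px] <- dat[, px] + amp %o% k
  }
  if (noise_sd > 0 || shot_noise) {
    dat <- with_seed(seed, {
      if (shot_noise) dat[] <- rpois(length(dat), pmax(dat, 0))
      if (noise_sd > 0) dat <- dat + rnorm(length(dat), 0, noise_sd)
      dat
    })
  }
  dat[dat < 0] <- 0
  fluor_movie(dat, nr, nc, frame_rate_hz %||% 25, pixel_size_um,
              stimulus_frames %||% integer(), stim_table)
}

#' Write a movie as a multi-frame 16-bit TIFF
#'
#' Counts are rounded and clipped to the 16-bit range. Frame rate, pixel size
#' and stimulus frames go into a JSON sidecar next to the TIFF.
#'
#' @param movie a [fluor_movie()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  frames <- lapply(seq_len(nrow(movie$data)), function(i) {
    m <- movie_frame(movie, i)
    m[m > 65535] <- 65535
    round(m) / 65535
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  meta <- list(frame_rate_hz = movie$frame_rate_hz,
               pixel_size_um = movie$pixel_size_um,
               stimulus_frames = movie$stimulus_frames)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-frame TIFF movie
#'
#' Reads intensities back to camera counts (16-bit scale) and restores
#' metadata from the JSON sidecar when present.
#'
#' @param path TIFF path.
#' @param frame_rate_hz,pixel_size_um,stimulus_frames metadata overrides;
#'   required when no sidecar exists.
#' @return a [fluor_movie()].
#' @export
read_movie_tiff <- function(path, frame_rate_hz = NULL, pixel_size_um = NULL,
                            stimulus_frames = NULL) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  meta <- list()
  side <- paste0(path, ".json")
  if (file.exists(side)) meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  nr <- nrow(frames[[1]]); nc <- ncol(frames[[1]])
  dat <- t(vapply(frames, function(m) as.vector(m) * 65535,
                  numeric(nr * nc)))
  fluor_movie(dat, nr, nc,
              frame_rate_hz %||% meta$frame_rate_hz %||% 25,
              pixel_size_um %||% meta$pixel_size_um %||% 0.5,
              as.integer(stimulus_frames %||% meta$stimulus_frames %||%
                           integer()))
}
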