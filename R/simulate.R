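#' Simulate per-stimulus vesicle release counts
#'
#' Draws the number of vesicles released at each stimulus of a protocol under
#' either the binomial model (each of `n_sites` sites releases independently
#' with probability `p_release[condition]`) or the Poisson model (rate
#' `lambda = p_release[condition] * n_sites`).
#'
#' @param gt a [ground_truth()].
#' @param protocol a [stim_protocol()]; every protocol condition must have an
#'   entry in `gt$p_release`.
#' @param model `"binomial"` or `"poisson"`.
#' @param seed seed for the draw; defaults to `gt$seed`.
#' @return the [stimulus_table()] of the protocol with an added integer
#'   `count` column.
#' @export
simulate_release_counts <- function(gt, protocol, model = "binomial",
                                    seed = gt$seed) {
  stopifnot(inherits(gt, "ground_truth"), inherits(protocol, "stim_protocol"))
  if (!model %in% c("binomial", "poisson")) {
    stop("unknown release model '", model,
         "'; allowed models are \"binomial\" and \"poisson\"")
  }
  missing_cond <- setdiff(protocol$conditions, names(gt$p_release))
  if (length(missing_cond)) {
    stop("no p_release entry for condition(s): ",
         paste(missing_cond, collapse = ", "))
  }
  st <- stimulus_table(protocol)
  p <- unname(gt$p_release[st$condition])
  st$count <- with_seed(seed, {
    if (model == "binomial") {
      rbinom(nrow(st), size = gt$n_sites, prob = p)
    } else {
      rpois(nrow(st), lambda = p * gt$n_sites)
    }
  })
  st
}

#' Simulate a single-ROI dF/F time series
#'
#' Forward model for a fluorescence trace: each stimulus adds an
#' instantaneous-rise, single-exponential-decay transient with peak increment
#' `count * q * rundown_factor^(global_train - 1)`, so that responses within a
#' 5 Hz train summate; slow drift (linear plus one exponential component) and
#' additive Gaussian noise are superimposed.
#'
#' @param counts data frame from [simulate_release_counts()] (needs columns
#'   `frame`, `count`, `global_train`).
#' @param gt a [ground_truth()].
#' @param protocol the [stim_protocol()] the counts were generated under.
#' @param seed seed for the noise draw; defaults to `gt$seed`.
#' @param n_frames optional total trace length in frames (>= protocol span);
#'   extra frames extend the quiet tail.
#' @return numeric dF/F vector with attribute `clean` (the noise- and
#'   drift-free trace).
#' @export
simulate_trace <- function(counts, gt, protocol, seed = gt$seed,
                           n_frames = NULL) {
  stopifnot(inherits(gt, "ground_truth"), inherits(protocol, "stim_protocol"))
  need <- c("frame", "count", "global_train")
  if (!all(need %in% names(counts))) {
    stop("counts must contain columns: ", paste(need, collapse = ", "))
  }
  nf <- protocol_frames(protocol)
  if (!is.null(n_frames)) {
    if (n_frames < nf) stop("n_frames shorter than the protocol span")
    nf <- as.integer(n_frames)
  }
  if (nrow(counts) &&
      nrow(counts) != protocol$trains_per_condition *
        protocol$stimuli_per_train * length(protocol$conditions)) {
    stop("counts length does not match the protocol")
  }
  fr <- protocol$frame_rate_hz
  decay <- exp(-1 / (fr * gt$decay_tau_s))
  amp <- counts$count * gt$q * gt$rundown_factor^(counts$global_train - 1)
  clean <- numeric(nf)
  # recursive exponential decay with impulse injection at stimulus frames
  imp <- numeric(nf)
  imp[counts$frame] <- imp[counts$frame] + amp
  acc <- 0
  for (j in seq_len(nf)) {
    acc <- acc * decay + imp[j]
    clean[j] <- acc
  }
  t_s <- (seq_len(nf) - 1) / fr
  drift <- gt$drift_linear * t_s +
    gt$drift_amplitude * exp(-t_s / gt$drift_tau_s)
  noise <- if (gt$noise_sd > 0) {
    with_seed(seed, rnorm(nf, 0, gt$noise_sd))
  } else numeric(nf)
  out <- clean + drift + noise
  attr(out, "clean") <- clean
  out
}

#' Construct a trace set
#'
#' Container for per-ROI dF/F time series with protocol annotation; produced
#' by the simulator and by [movie_to_traceset()].
#'
#' @param dff numeric matrix, frames x ROIs, in dF/F units.
#' @param frame_rate_hz frames per second.
#' @param stim_table per-stimulus annotation ([stimulus_table()] layout).
#' @param protocol optional [stim_protocol()].
#' @param f0 optional per-ROI baseline fluorescence (camera counts).
#' @param raw optional frames x ROIs matrix of background-subtracted raw
#'   intensities (needed by [f0_stability()]).
#' @param roi_ids optional ROI identifiers (default `roi_1 ... roi_k`).
#' @param valid optional logical vector flagging ROIs with usable baselines.
#' @return an object of class `trace_set`.
#' @export
trace_set <- function(dff, frame_rate_hz, stim_table, protocol = NULL,
                      f0 = NULL, raw = NULL, roi_ids = NULL, valid = NULL) {
  dff <- as.matrix(dff)
  n <- ncol(dff)
  roi_ids <- roi_ids %||% paste0("roi_", seq_len(n))
  stopifnot(length(roi_ids) == n)
  if (!is.null(stim_table) && nrow(stim_table) &&
      max(stim_table$frame) > nrow(dff)) {
    stop("stimulus frames exceed trace length")
  }
  colnames(dff) <- roi_ids
  structure(list(dff = dff, frame_rate_hz = frame_rate_hz,
                 stim_table = stim_table, protocol = protocol, f0 = f0,
                 raw = raw, roi_ids = roi_ids,
                 valid = valid %||% rep(TRUE, n)),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat("<trace_set> ", ncol(x$dff), " ROIs x ", nrow(x$dff), " frames @ ",
      x$frame_rate_hz, " Hz, ",
      if (is.null(x$stim_table)) 0 else nrow(x$stim_table), " stimuli\n",
      sep = "")
  invisible(x)
}

#' Simulate a multi-ROI experiment with known ground truth
#'
#' Generates `n_roi` independent ROIs under a common protocol and ground
#' truth. One master seed governs everything; each ROI draws from a
#' deterministically derived sub-stream, so the same seed reproduces the same
#' experiment bit for bit.
#'
#' @param n_roi number of ROIs.
#' @param gt a [ground_truth()].
#' @param protocol a [stim_protocol()].
#' @param model release model, `"binomial"` or `"poisson"`.
#' @param seed master seed; defaults to `gt$seed`.
#' @param n_frames optional trace length override (see [simulate_trace()]).
#' @return a [trace_set()] with extra fields `counts` (long data frame of
#'   ground-truth vesicle counts per ROI and stimulus) and `gt`.
#' @export
simulate_experiment <- function(n_roi, gt, protocol, model = "binomial",
                                seed = gt$seed, n_frames = NULL) {
  stopifnot(n_roi >= 1)
  counts_all <- vector("list", n_roi)
  dff <- NULL
  for (i in seq_len(n_roi)) {
    s_counts <- derive_seed(seed, 2L * i)
    s_noise <- derive_seed(seed, 2L * i + 1L)
    ct <- simulate_release_counts(gt, protocol, model, seed = s_counts)
    tr <- simulate_trace(ct, gt, protocol, seed = s_noise,
                         n_frames = n_frames)
    if (is.null(dff)) dff <- matrix(0, length(tr), n_roi)
    dff[, i] <- tr
    ct$roi_id <- paste0("roi_", i)
    counts_all[[i]] <- ct
  }
  ts <- trace_set(dff, protocol$frame_rate_hz, stimulus_table(protocol),
                  protocol = protocol)
  ts$counts <- do.call(rbind, counts_all)
  ts$gt <- gt
  ts
}

#' Simulate paired EPSC amplitude trains
#'
#' Produces the electrophysiological counterpart of the optical record: the
#' EPSC amplitude at stimulus s of a train is proportional to the total
#' number of quanta released at that stimulus times
#' `depression_per_stimulus^(s - 1)` (presynaptic short-term depression).
#'
#' @param gt a [ground_truth()].
#' @param protocol a [stim_protocol()].
#' @param depression_per_stimulus multiplicative depression per stimulus,
#'   in (0, 1].
#' @param counts optional count table from [simulate_release_counts()];
#'   simulated if missing.
#' @param unit_pa EPSC amplitude per released vesicle (pA).
#' @param seed seed used when counts are simulated.
#' @return count table with an added `epsc_pa` column.
#' @export
simulate_epsc_trains <- function(gt, protocol, depression_per_stimulus = 1,
                                 counts = NULL, unit_pa = 20,
                                 seed = gt$seed) {
  if (depression_per_stimulus <= 0 || depression_per_stimulus > 1) {
    stop("depression_per_stimulus must lie in (0, 1]")
  }
  if (is.null(counts)) {
    counts <- simulate_release_counts(gt, protocol, seed = seed)
  }
  counts$epsc_pa <- counts$count * unit_pa *
    depression_per_stimulus^(counts$stimulus_index - 1)
  counts
}

#' Write a trace set to CSV
#'
#' Long format with columns `time_s`, `roi_id`, `dff`, and, for stimulus
#' frames, `condition`, `train`, `stimulus_index`.
#'
#' @param ts a [trace_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(ts, path) {
  stopifnot(inherits(ts, "trace_set"))
  nf <- nrow(ts$dff)
  t_s <- (seq_len(nf) - 1) / ts$frame_rate_hz
  long <- data.frame(
    time_s = rep(t_s, times = ncol(ts$dff)),
    roi_id = rep(ts$roi_ids, each = nf),
    dff = as.vector(ts$dff),
    condition = NA_character_, train = NA_integer_,
    stimulus_index = NA_integer_, stringsAsFactors = FALSE)
  if (!is.null(ts$stim_table) && nrow(ts$stim_table)) {
    st <- ts$stim_table
    idx <- rep((seq_len(ncol(ts$dff)) - 1) * nf, each = nrow(st)) +
      rep(st$frame, times = ncol(ts$dff))
    long$condition[idx] <- rep(st$condition, times = ncol(ts$dff))
    long$train[idx] <- rep(st$train, times = ncol(ts$dff))
    long$stimulus_index[idx] <- rep(st$stimulus_index, times = ncol(ts$dff))
  }
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read a trace set from CSV
#'
#' Inverse of [write_traces_csv()].
#'
#' @param path CSV path.
#' @param frame_rate_hz frame rate of the recording; inferred from the time
#'   column when `NULL`.
#' @return a [trace_set()].
#' @export
read_traces_csv <- function(path, frame_rate_hz = NULL) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  rois <- unique(long$roi_id)
  nf <- sum(long$roi_id == rois[1])
  dff <- matrix(long$dff, nrow = nf,
                dimnames = list(NULL, rois))
  if (is.null(frame_rate_hz)) {
    dt <- diff(long$time_s[seq_len(min(nf, 2))])
    frame_rate_hz <- round(1 / dt)
  }
  sub <- long[long$roi_id == rois[1] & !is.na(long$condition), , drop = FALSE]
  st <- NULL
  if (nrow(sub)) {
    st <- data.frame(condition = as.character(sub$condition),
                     train = sub$train, stimulus_index = sub$stimulus_index,
                     time_s = sub$time_s,
                     frame = floor(sub$time_s * frame_rate_hz) + 1L,
                     stringsAsFactors = FALSE)
    st <- st[order(st$frame), ]
    st$global_train <- cumsum(st$stimulus_index == 1)
    rownames(st) <- NULL
  }
  trace_set(dff, frame_rate_hz, st, roi_ids = rois)
}

#' Write ground truth as a JSON sidecar
#' @param gt a [ground_truth()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(gt, path) {
  jsonlite::write_json(unclass(gt), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
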