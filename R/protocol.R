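#' Stimulation protocol
#'
#' Describes the stimulus structure of a recording: an ordered set of calcium
#' conditions, each delivered as repeated trains of stimuli at fixed
#' inter-stimulus interval. The default mirrors the common design of 10 trains
#' of 5 stimuli at 5 Hz per condition, in 0.5, 2 and 4 mM external calcium,
#' imaged at 25 Hz.
#'
#' @param conditions character vector of calcium-condition labels, in the
#'   order they are recorded (mM as strings, e.g. `"0.5"`).
#' @param trains_per_condition number of stimulus trains per condition.
#' @param stimuli_per_train number of stimuli within one train.
#' @param stimulus_interval_s inter-stimulus interval within a train (s);
#'   0.2 s corresponds to 5 Hz stimulation.
#' @param frame_rate_hz imaging frame rate (frames per second).
#' @param pre_train_gap_s quiet period preceding each train (s), used for
#'   per-train baseline estimation.
#' @param tail_s quiet period appended after the last train of each
#'   condition (s), letting the final transient decay.
#' @return an object of class `stim_protocol`.
#' @export
stim_protocol <- function(conditions = c("0.5", "2", "4"),
                          trains_per_condition = 10,
                          stimuli_per_train = 5,
                          stimulus_interval_s = 0.2,
                          frame_rate_hz = 25,
                          pre_train_gap_s = 2,
                          tail_s = 1) {
  stopifnot(length(conditions) >= 1, trains_per_condition >= 1,
            stimuli_per_train >= 1, stimulus_interval_s > 0,
            frame_rate_hz > 0, pre_train_gap_s > 0, tail_s >= 0)
  structure(list(conditions = as.character(conditions),
                 trains_per_condition = as.integer(trains_per_condition),
                 stimuli_per_train = as.integer(stimuli_per_train),
                 stimulus_interval_s = stimulus_interval_s,
                 frame_rate_hz = frame_rate_hz,
                 pre_train_gap_s = pre_train_gap_s,
                 tail_s = tail_s),
            class = "stim_protocol")
}

#' Per-stimulus annotation table for a protocol
#'
#' Expands a [stim_protocol()] into one row per stimulus with its condition,
#' train number, within-train stimulus index, global train counter, time and
#' frame index.
#'
#' @param protocol a [stim_protocol()].
#' @return data frame with columns `condition`, `train`, `stimulus_index`,
#'   `global_train`, `time_s`, `frame`.
#' @export
stimulus_table <- function(protocol) {
  stopifnot(inherits(protocol, "stim_protocol"))
  p <- protocol
  train_dur <- p$pre_train_gap_s + p$stimuli_per_train * p$stimulus_interval_s
  block_dur <- p$trains_per_condition * train_dur + p$tail_s
  rows <- list()
  g <- 0L
  for (ci in seq_along(p$conditions)) {
    for (tr in seq_len(p$trains_per_condition)) {
      g <- g + 1L
      t0 <- (ci - 1) * block_dur + (tr - 1) * train_dur + p$pre_train_gap_s
      st <- t0 + (seq_len(p$stimuli_per_train) - 1) * p$stimulus_interval_s
      rows[[g]] <- data.frame(condition = p$conditions[ci], train = tr,
                              stimulus_index = seq_len(p$stimuli_per_train),
                              global_train = g, time_s = st,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$frame <- floor(out$time_s * p$frame_rate_hz) + 1L
  rownames(out) <- NULL
  out
}

#' Total number of frames spanned by a protocol
#' @param protocol a [stim_protocol()].
#' @return integer frame count.
#' @export
protocol_frames <- function(protocol) {
  p <- protocol
  train_dur <- p$pre_train_gap_s + p$stimuli_per_train * p$stimulus_interval_s
  block_dur <- p$trains_per_condition * train_dur + p$tail_s
  as.integer(ceiling(length(p$conditions) * block_dur * p$frame_rate_hz))
}
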