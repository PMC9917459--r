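#' Build a pipeline run configuration
#'
#' Exactly one input source is used: `"simulate"` (ground truth + protocol),
#' a movie TIFF path, or a trace CSV path. All analysis thresholds are
#' carried in the config so a run is fully described by (config, seed).
#'
#' @param mode `"simulate"`, `"movie"` or `"traces"`.
#' @param seed integer seed governing all stochastic steps.
#' @param outdir output directory.
#' @param n_roi ROIs to simulate (simulate mode).
#' @param model release model for simulation.
#' @param gt list of [ground_truth()] arguments (simulate mode).
#' @param protocol list of [stim_protocol()] arguments.
#' @param movie_path,trace_path input file for the respective modes.
#' @param tile list of [tile_criteria()] arguments.
#' @param als list with `smoothness` and `asymmetry`.
#' @param min_snr,rundown_cut exclusion thresholds.
#' @param p_cut low-calcium probability cut for [select_min_n()].
#' @param n_range candidate site counts for [select_best_n()].
#' @param bin_width histogram bin width (`NULL` = automatic).
#' @param max_fit_rois cap on the number of ROIs taken to histogram
#'   fitting (`Inf` = all).
#' @param low_ca_condition label of the low-calcium condition.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "movie", "traces"), seed = 1L,
                       outdir = tempfile("qfrun"), n_roi = 12,
                       model = "binomial", gt = list(), protocol = list(),
                       movie_path = NULL, trace_path = NULL, tile = list(),
                       als = list(smoothness = 1e4, asymmetry = 0.01),
                       min_snr = 3, rundown_cut = 0.5, p_cut = 0.5,
                       n_range = 1:12, bin_width = NULL,
                       max_fit_rois = Inf, low_ca_condition = "0.5") {
  mode <- match.arg(mode)
  if (mode == "movie" && is.null(movie_path)) stop("movie_path required")
  if (mode == "traces" && is.null(trace_path)) stop("trace_path required")
  cfg <- list(mode = mode, seed = as.integer(seed), outdir = outdir,
              n_roi = n_roi, model = model, gt = gt, protocol = protocol,
              movie_path = movie_path, trace_path = trace_path,
              tile = tile, als = als, min_snr = min_snr,
              rundown_cut = rundown_cut, p_cut = p_cut,
              n_range = n_range, bin_width = bin_width,
              max_fit_rois = max_fit_rois,
              low_ca_condition = low_ca_condition)
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as YAML
#' @param path YAML path.
#' @param config a [run_config()].
#' @return `read_config` returns a `run_config`; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$outdir <- raw$outdir %||% tempfile("qfrun")
  do.call(run_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

log_line <- function(state, ...) {
  msg <- paste0(...)
  state$log <- c(state$log, msg)
  if (state$verbose) message(msg)
  state
}

#' Run the full analysis pipeline
#'
#' Executes the applicable stages in order — simulate/load, responsive-ROI
#' detection, trace extraction, peak extraction with exclusions, CV
#' analysis and per-ROI quantal histogram fitting — and writes every
#' result with a manifest (config hash, seed, package version, file list).
#' Identical config and seed give identical numerical outputs. A failing
#' stage leaves earlier results in place and is recorded in the report.
#'
#' @param config a [run_config()].
#' @param verbose print progress messages.
#' @return a run report: list with `stages` (status per stage), `files`,
#'   `config_hash`, and the in-memory results (`traceset`, `peaks`,
#'   `cv`, `fits`, ...).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  # re-running into the same directory cleans the previous run's outputs
  old_manifest <- file.path(config$outdir, "manifest.json")
  if (file.exists(old_manifest)) {
    prev <- jsonlite::read_json(old_manifest, simplifyVector = TRUE)
    unlink(file.path(config$outdir,
                     c(prev$files, "manifest.json", "run.log")))
  }
  state <- list(log = character(), verbose = verbose, files = character())
  stages <- c("input", "roi_detection", "trace_extraction", "peaks",
              "quantal", "report")
  status <- stats::setNames(rep("pending", length(stages)), stages)
  res <- list()
  t0 <- proc.time()[["elapsed"]]
  run_stage <- function(name, fun) {
    st <- proc.time()[["elapsed"]]
    out <- tryCatch(fun(), error = function(e) e)
    el <- round(proc.time()[["elapsed"]] - st, 3)
    if (inherits(out, "error")) {
      status[name] <<- paste0("failed: ", conditionMessage(out))
      state <<- log_line(state, "[", name, "] FAILED (", el, "s): ",
                         conditionMessage(out))
      NULL
    } else {
      status[name] <<- "ok"
      state <<- log_line(state, "[", name, "] ok (", el, "s)")
      out
    }
  }
  emit <- function(obj, file, writer) {
    path <- file.path(config$outdir, file)
    writer(obj, path)
    state$files <<- c(state$files, file)
    path
  }

  # --- input -------------------------------------------------------------
  ts <- run_stage("input", function() {
    if (config$mode == "simulate") {
      gt <- do.call(ground_truth, c(config$gt, list(seed = config$seed)))
      pr <- do.call(stim_protocol, config$protocol)
      sim <- simulate_experiment(config$n_roi, gt, pr, config$model,
                                 seed = config$seed)
      emit(gt, "ground_truth.json", write_ground_truth_json)
      sim
    } else if (config$mode == "traces") {
      read_traces_csv(config$trace_path)
    } else {
      read_movie_tiff(config$movie_path)
    }
  })
  movie <- if (inherits(ts, "fluor_movie")) ts else NULL

  # --- movie stages ------------------------------------------------------
  if (!is.null(movie)) {
    rois <- run_stage("roi_detection", function() {
      tiles <- scan_tiles(movie, do.call(tile_criteria, config$tile))
      merge_contiguous(tiles)
    })
    if (!is.null(rois)) {
      res$rois <- rois
      emit(rois, "rois.csv", function(r, p) {
        write_roi_masks(r, sub("\\.csv$", "_mask.tiff", p), p)
        state$files <<- c(state$files, "rois_mask.tiff")
      })
      ts <- run_stage("trace_extraction", function() {
        movie_to_traceset(movie, rois)
      })
    } else {
      ts <- NULL
      status["trace_extraction"] <- "skipped"
    }
  } else {
    status["roi_detection"] <- "skipped"
    status["trace_extraction"] <- "skipped"
  }

  peaks <- NULL
  if (!is.null(ts) && inherits(ts, "trace_set")) {
    res$traceset <- ts
    emit(ts, "traces.csv", write_traces_csv)
    # --- peaks -----------------------------------------------------------
    peaks <- run_stage("peaks", function() {
      pk <- extract_peaks_at_template(
        ts, als_smoothness = config$als$smoothness,
        als_asymmetry = config$als$asymmetry)
      snr_and_exclusion(pk, config$min_snr, config$rundown_cut)
    })
  } else {
    status["peaks"] <- "skipped"
  }

  if (!is.null(peaks)) {
    res$peaks <- peaks
    emit(peaks, "peaks.csv", write_peaks_csv)
    # --- quantal ---------------------------------------------------------
    q <- run_stage("quantal", function() {
      conds <- unique(peaks$condition)
      cvs <- vapply(conds, function(cd) {
        tryCatch(cv_slope(peaks, cd)$cv, error = function(e) NA_real_)
      }, 1)
      names(cvs) <- conds
      cv_fits <- if (all(is.finite(cvs))) {
        cv_global_fit(cvs, config$n_range)
      } else NULL
      cv_n <- if (!is.null(cv_fits) &&
                  config$low_ca_condition %in% conds) {
        select_min_n(cv_fits, config$low_ca_condition, config$p_cut)
      } else NA_integer_
      ok_rois <- unique(peaks$roi_id[!peaks$excluded])
      if (is.finite(config$max_fit_rois)) {
        ok_rois <- head(ok_rois, config$max_fit_rois)
      }
      fits <- list()
      for (r in ok_rois) {
        h <- tryCatch(build_histograms(peaks, r,
                                       bin_width = config$bin_width),
                      error = function(e) NULL)
        if (is.null(h)) next
        sel <- select_best_n(h, config$n_range,
                             seed = derive_seed(config$seed, match(
                               r, unique(peaks$roi_id))))
        fits[[r]] <- sel
      }
      list(cv = cvs, cv_fits = cv_fits, cv_selected_n = cv_n, fits = fits)
    })
    if (!is.null(q)) {
      res$cv <- q$cv
      res$cv_fits <- q$cv_fits
      res$cv_selected_n <- q$cv_selected_n
      res$fits <- q$fits
      emit(q, "quantal.json", function(obj, p) {
        tidy <- list(
          cv = as.list(obj$cv),
          cv_selected_n = obj$cv_selected_n,
          fits = lapply(obj$fits, function(s) {
            f <- s$best
            if (is.null(f)) return(list(converged = FALSE))
            list(model = f$model, n_sites = f$n_sites, q = f$q,
                 sigma = f$sigma, scale = f$scale,
                 p_release = as.list(f$p_release),
                 min_ks_p = f$min_ks_p)
          }))
        jsonlite::write_json(tidy, p, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
      })
    }
  } else {
    status["quantal"] <- "skipped"
  }

  # --- report ------------------------------------------------------------
  # the hash covers the analysis parameters, not the output location
  cfg_hash <- rlang::hash(unclass(config)[setdiff(names(config), "outdir")])
  manifest <- list(package = "quantalfluor",
                   version = as.character(utils::packageVersion(
                     "quantalfluor")),
                   seed = config$seed, config_hash = cfg_hash,
                   stages = as.list(status[setdiff(stages, "report")]),
                   files = sort(unique(state$files)))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  status["report"] <- "ok"
  state <- log_line(state, "run complete in ",
                    round(proc.time()[["elapsed"]] - t0, 2), "s")
  writeLines(state$log, file.path(config$outdir, "run.log"))
  c(list(stages = status, files = sort(unique(c(state$files,
                                                "manifest.json"))),
         config_hash = cfg_hash, outdir = config$outdir), res)
}

#' Correlate fluorescence and EPSC short-term depression across cells
#'
#' @param depression_fluor,depression_epsc named per-cell depression
#'   ratios; entries are paired by name and unpaired entries are dropped
#'   with a warning.
#' @return list with Pearson `r` and the paired `table`.
#' @export
correlate_fluor_vs_epsc <- function(depression_fluor, depression_epsc) {
  if (is.null(names(depression_fluor)) || is.null(names(depression_epsc))) {
    stop("inputs must be named by cell")
  }
  common <- intersect(names(depression_fluor), names(depression_epsc))
  dropped <- length(depression_fluor) + length(depression_epsc) -
    2 * length(common)
  if (dropped > 0) warning(dropped, " unpaired entries dropped")
  if (length(common) < 3) stop("need at least 3 paired cells")
  tab <- data.frame(cell = common,
                    fluor = unname(depression_fluor[common]),
                    epsc = unname(depression_epsc[common]),
                    stringsAsFactors = FALSE)
  list(r = cor(tab$fluor, tab$epsc), table = tab)
}
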