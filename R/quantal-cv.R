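#' Population CV from SD-vs-mean of train responses
#'
#' For every included ROI of the condition, the mean and SD of the response
#' amplitudes within each train are computed and averaged over trains into
#' one (mean, SD) point per ROI. The coefficient of variation is the slope
#' of the least-squares line through the origin fitted to SD against mean
#' over ROIs (CV = sigma/mu implies proportionality); an unconstrained fit
#' is also reported for comparison.
#'
#' @param peaks a `peak_table`.
#' @param condition condition label.
#' @param min_rois,min_trains minimum data requirements.
#' @return list with `cv`, `r_squared`, `slope_unconstrained`, and the
#'   per-ROI `points` data frame.
#' @export
cv_slope <- function(peaks, condition, min_rois = 3, min_trains = 2) {
  sub <- peaks[peaks$condition == condition & !peaks$excluded &
                 !peaks$ignored & !is.na(peaks$amplitude), , drop = FALSE]
  rois <- unique(sub$roi_id)
  pts <- do.call(rbind, lapply(rois, function(r) {
    s <- sub[sub$roi_id == r, , drop = FALSE]
    trains <- unique(s$train)
    if (length(trains) < min_trains) return(NULL)
    m <- vapply(trains, function(tr) mean(s$amplitude[s$train == tr]), 1)
    sdv <- vapply(trains, function(tr) sd(s$amplitude[s$train == tr]), 1)
    data.frame(roi_id = r, mean = mean(m), sd = mean(sdv),
               stringsAsFactors = FALSE)
  }))
  if (is.null(pts) || nrow(pts) < min_rois) {
    stop("cv_slope needs at least ", min_rois, " ROIs with >= ", min_trains,
         " trains in condition ", condition)
  }
  cv <- if (sum(pts$mean^2) > 0) {
    sum(pts$mean * pts$sd) / sum(pts$mean^2)
  } else 0
  ss_res <- sum((pts$sd - cv * pts$mean)^2)
  ss_tot <- sum((pts$sd - mean(pts$sd))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  slope_u <- if (nrow(pts) >= 2 && sd(pts$mean) > 0 &&
                 sd(pts$sd) > 0) {
    unname(cor(pts$mean, pts$sd) * sd(pts$sd) / sd(pts$mean))
  } else NA_real_
  list(cv = cv, r_squared = r2, slope_unconstrained = slope_u, points = pts)
}

#' Release probabilities from CVs for a range of site counts
#'
#' For binomial release `CV^2 = (1 - P_R) / (N * P_R)`, so for every
#' candidate integer N the per-condition release probability follows
#' exactly as `P_R = 1 / (1 + N * CV^2)`; `CV = 0` gives `P_R = 1`. With
#' one free release probability per condition the inversion fits every
#' condition's CV exactly, so goodness of fit cannot distinguish the
#' candidate N values; selection needs the external plausibility rule of
#' [select_min_n()].
#'
#' @param cv_per_condition named numeric vector of CVs (condition ->
#'   CV >= 0).
#' @param n_range integer candidate site counts.
#' @return data frame with columns `n_sites`, `condition`, `cv`,
#'   `p_release`.
#' @export
cv_global_fit <- function(cv_per_condition, n_range = 1:8) {
  stopifnot(length(cv_per_condition) >= 1, length(n_range) >= 1,
            all(cv_per_condition >= 0), all(n_range == round(n_range)))
  if (is.null(names(cv_per_condition))) {
    stop("cv_per_condition must be named by condition")
  }
  out <- expand.grid(n_sites = as.integer(n_range),
                     condition = names(cv_per_condition),
                     stringsAsFactors = FALSE)
  cv <- cv_per_condition[out$condition]
  out$cv <- unname(cv)
  out$p_release <- 1 / (1 + out$n_sites * out$cv^2)
  out
}

#' Select the smallest plausible number of release sites
#'
#' The conservative selection rule: the minimal candidate N whose release
#' probability in the low-calcium condition falls below `p_cut` (default
#' 50%).
#'
#' @param fits data frame from [cv_global_fit()].
#' @param low_ca_condition label of the low-calcium condition.
#' @param p_cut probability cut-off.
#' @return the selected integer N, or `NA` (with attribute `diagnostic`)
#'   when no candidate satisfies the rule.
#' @export
select_min_n <- function(fits, low_ca_condition = "0.5", p_cut = 0.5) {
  sub <- fits[fits$condition == low_ca_condition, , drop = FALSE]
  if (!nrow(sub)) stop("condition ", low_ca_condition, " not in fits")
  ok <- sub$n_sites[sub$p_release < p_cut]
  if (!length(ok)) {
    return(structure(NA_integer_,
                     diagnostic = paste0("no candidate N gives P_R < ",
                                         p_cut, " at ", low_ca_condition,
                                         " mM")))
  }
  min(ok)
}
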