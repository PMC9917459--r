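#' Asymmetric least squares baseline
#'
#' Eilers-style iteratively reweighted penalised least squares: the baseline
#' z minimises `sum(w * (y - z)^2) + smoothness * sum(diff(z, 2)^2)` with
#' asymmetric weights `w = asymmetry` for points above the current baseline
#' and `1 - asymmetry` below, so positive-going transients are ignored while
#' slow drift is tracked. Defaults keep 5 Hz synaptic transients out of the
#' baseline at a 25 Hz frame rate.
#'
#' @param y numeric series (length >= 10).
#' @param smoothness second-difference penalty weight (squared frames);
#'   larger values give a stiffer baseline.
#' @param asymmetry weight for points above the baseline, in (0, 1).
#' @param maxit maximum reweighting iterations; when the weights have not
#'   settled by then the last iterate is returned with a warning.
#' @return numeric baseline of the same length, with attributes `converged`
#'   and `iterations`.
#' @export
als_baseline <- function(y, smoothness = 1e4, asymmetry = 0.01, maxit = 10) {
  stopifnot(length(y) >= 10, asymmetry > 0, asymmetry < 1, smoothness > 0)
  res <- als_baseline_cpp(as.numeric(y), smoothness, asymmetry,
                          as.integer(maxit))
  if (!res$converged) {
    warning("ALS baseline did not converge in ", maxit,
            " iterations; returning last iterate")
  }
  structure(res$baseline, converged = res$converged,
            iterations = res$iterations)
}
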