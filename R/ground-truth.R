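#' Ground-truth release parameters for simulation
#'
#' Collects the quantal parameters that the synthetic-data generator draws
#' from: the number of release sites per ROI (N), the quantal fluorescence
#' increment (q, in dF/F units), the per-site release probability for each
#' calcium condition (P_R), additive Gaussian amplitude noise, per-train
#' multiplicative rundown, slow baseline drift, the spatial footprint of a
#' release site, and the sensor decay time constant. Under the Poisson release
#' model the rate is `lambda = p_release * n_sites`.
#'
#' Defaults are the study conditions used throughout the package's tests:
#' N = 5 sites, q = 0.09 dF/F, P_R = 0.1 / 0.4 / 0.7 at 0.5 / 2 / 4 mM
#' calcium, additive noise 0.03 dF/F.
#'
#' @param n_sites integer number of release sites (N >= 1).
#' @param q quantal dF/F increment per vesicle (> 0).
#' @param p_release named numeric vector mapping condition label to per-site
#'   release probability in `[0, 1]`.
#' @param noise_sd additive Gaussian noise of the dF/F trace (>= 0).
#' @param rundown_factor per-train multiplicative amplitude decay in (0, 1].
#' @param drift_linear linear baseline drift slope (dF/F per second).
#' @param drift_amplitude amplitude of a slow exponential drift component
#'   (dF/F units).
#' @param drift_tau_s time constant of the exponential drift component (s).
#' @param spot_sigma_um standard deviation of the Gaussian spatial footprint
#'   of a release site (micrometres).
#' @param decay_tau_s single-exponential decay time constant of the response
#'   kernel (s).
#' @param seed integer master seed for all stochastic draws.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(n_sites = 5,
                         q = 0.09,
                         p_release = c("0.5" = 0.1, "2" = 0.4, "4" = 0.7),
                         noise_sd = 0.03,
                         rundown_factor = 1,
                         drift_linear = 0,
                         drift_amplitude = 0,
                         drift_tau_s = 30,
                         spot_sigma_um = 0.3,
                         decay_tau_s = 0.4,
                         seed = 1L) {
  if (n_sites < 1 || n_sites != round(n_sites)) {
    stop("n_sites must be an integer >= 1")
  }
  if (q <= 0) stop("q must be > 0")
  if (is.null(names(p_release)) || any(!nzchar(names(p_release)))) {
    stop("p_release must be a named vector (condition label -> probability)")
  }
  if (any(p_release < 0 | p_release > 1)) {
    stop("p_release values must lie in [0, 1]")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (rundown_factor <= 0 || rundown_factor > 1) {
    stop("rundown_factor must lie in (0, 1]")
  }
  stopifnot(drift_tau_s > 0, spot_sigma_um > 0, decay_tau_s > 0)
  structure(list(n_sites = as.integer(n_sites), q = q,
                 p_release = p_release, noise_sd = noise_sd,
                 rundown_factor = rundown_factor,
                 drift_linear = drift_linear,
                 drift_amplitude = drift_amplitude,
                 drift_tau_s = drift_tau_s,
                 spot_sigma_um = spot_sigma_um,
                 decay_tau_s = decay_tau_s,
                 seed = as.integer(seed)),
            class = "ground_truth")
}
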