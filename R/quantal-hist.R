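#' Per-condition response histograms for one ROI
#'
#' Bins the response amplitudes of one ROI separately per condition on a
#' common grid from 0, plus the pooled histogram (the element-wise sum).
#' Failures carry amplitude exactly 0 and land in the first bin.
#'
#' @param peaks a `peak_table`.
#' @param roi ROI identifier; the ROI must not be excluded.
#' @param bin_width bin width in dF/F; when `NULL` it defaults to one third
#'   of the pooled quantal-size estimate from
#'   [fit_pooled_gaussian_mixture()], floored at 0.01.
#' @param q_init optional quantal-size initial value forwarded to the
#'   pooled estimate.
#' @return an object of class `quantal_histograms`: list with `edges`,
#'   `counts` (bins x conditions), `pooled`, `amplitudes` (per condition),
#'   `bin_width`, `q_init`, `n`.
#' @export
build_histograms <- function(peaks, roi, bin_width = NULL, q_init = NULL) {
  rows <- peaks$roi_id == roi & !peaks$ignored & !is.na(peaks$amplitude)
  if (!any(rows)) stop("no responses for ROI ", roi)
  if (any(peaks$excluded[rows])) {
    stop("ROI ", roi, " is excluded (", peaks$reason[rows][1], ")")
  }
  sub <- peaks[rows, , drop = FALSE]
  conds <- unique(sub$condition)
  amps <- lapply(conds, function(cd) sub$amplitude[sub$condition == cd])
  names(amps) <- conds
  quantal_histograms(amps, bin_width = bin_width, q_init = q_init)
}

#' Construct quantal histograms from per-condition amplitude vectors
#'
#' The binning backbone of [build_histograms()], usable directly on
#' amplitude samples (e.g. from [simulate_quantal_amplitudes()]).
#'
#' @param amplitudes named list of per-condition amplitude vectors
#'   (failures as exactly 0).
#' @param bin_width,q_init as in [build_histograms()].
#' @return a `quantal_histograms` object.
#' @export
quantal_histograms <- function(amplitudes, bin_width = NULL, q_init = NULL) {
  stopifnot(is.list(amplitudes), !is.null(names(amplitudes)))
  amps <- amplitudes
  if (is.null(bin_width)) {
    est <- fit_pooled_gaussian_mixture(unlist(amps), fallback_q = q_init)
    bin_width <- max(est$q / 3, 0.01)
    q_init <- q_init %||% est$q
  }
  stopifnot(bin_width > 0)
  top <- max(unlist(amps), bin_width)
  edges <- seq(0, bin_width * ceiling(top / bin_width + 1), by = bin_width)
  counts <- vapply(amps, function(a) {
    as.numeric(table(cut(a, edges, right = FALSE, include.lowest = TRUE)))
  }, numeric(length(edges) - 1))
  counts <- matrix(counts, ncol = length(amps),
                   dimnames = list(NULL, names(amps)))
  structure(list(edges = edges, counts = counts,
                 pooled = rowSums(counts), amplitudes = amps,
                 bin_width = bin_width, q_init = q_init,
                 n = length(unlist(amps))),
            class = "quantal_histograms")
}

#' Sample response amplitudes from a quantal release model
#'
#' Draws per-stimulus quantal counts from the binomial or Poisson model
#' and turns them into amplitudes under that model's own component
#' structure: failures are exactly 0, a count of k gives
#' `k * q + N(0, sigma_k)` with `sigma_k = sigma` (binomial, common
#' width) or `sigma * sqrt(k)` (Poisson, proportional widths). Negative
#' draws are truncated at 0. This is the model-faithful sampler used for
#' model-recovery and classification tests.
#'
#' @param n_per_condition stimuli per condition.
#' @param q quantal amplitude.
#' @param sigma component width (binomial) or first-component width
#'   (Poisson).
#' @param model `"binomial"` or `"poisson"`.
#' @param n_sites number of sites (binomial).
#' @param p_release named per-condition release probabilities (binomial).
#' @param lambda named per-condition release rates (Poisson).
#' @param seed random seed.
#' @return named list of per-condition amplitude vectors.
#' @export
simulate_quantal_amplitudes <- function(n_per_condition, q, sigma,
                                        model = c("binomial", "poisson"),
                                        n_sites = NULL, p_release = NULL,
                                        lambda = NULL, seed = 1L) {
  model <- match.arg(model)
  pars <- if (model == "binomial") p_release else lambda
  stopifnot(!is.null(pars), !is.null(names(pars)))
  with_seed(seed, {
    out <- lapply(pars, function(th) {
      k <- if (model == "binomial") {
        rbinom(n_per_condition, n_sites, th)
      } else {
        rpois(n_per_condition, th)
      }
      sg <- if (model == "poisson") sigma * sqrt(pmax(k, 1)) else sigma
      a <- ifelse(k == 0, 0, k * q + rnorm(n_per_condition, 0, sg))
      pmax(a, 0)
    })
    names(out) <- names(pars)
    out
  })
}

#' Initial quantal-size estimate from the pooled amplitude distribution
#'
#' Finds the modes of a kernel density estimate of the positive (non-
#' failure) amplitudes; with at least two discernible modes, the quantal
#' size is refined by least squares against an equally spaced multi-
#' Gaussian model (component amplitudes solved linearly at each candidate
#' spacing). With fewer than two modes the estimate falls back to
#' `fallback_q` (or, failing that, the 15th percentile of the positive
#' amplitudes, which approximates the single-quantum level when
#' multi-quantal responses dominate) with a warning.
#'
#' @param amplitudes pooled response amplitudes (failures as 0 allowed).
#' @param fallback_q quantal size used when no multi-modal structure is
#'   discernible.
#' @param min_mode_frac minimum mode height relative to the tallest mode.
#' @return list with `q`, `sigma`, `modes`, `used_fallback`.
#' @export
fit_pooled_gaussian_mixture <- function(amplitudes, fallback_q = NULL,
                                        min_mode_frac = 0.05) {
  x <- amplitudes[amplitudes > 0]
  fallback <- function(msg) {
    q <- fallback_q %||%
      if (length(x)) unname(stats::quantile(x, 0.15)) else NA_real_
    warning("pooled mixture: ", msg, "; falling back to q = ",
            signif(q, 3))
    list(q = q, sigma = NA_real_, modes = numeric(), used_fallback = TRUE)
  }
  if (length(x) < 10) return(fallback("too few positive responses"))
  d <- density(x, bw = max(0.008, stats::bw.nrd0(x) / 2), n = 512,
               from = 0, to = max(x) * 1.1)
  ym <- d$y
  is_mode <- which(diff(sign(diff(ym))) == -2) + 1
  is_mode <- is_mode[ym[is_mode] >= min_mode_frac * max(ym)]
  modes <- d$x[is_mode]
  if (length(modes) < 2) return(fallback("fewer than 2 modes"))
  q0 <- median(diff(modes))
  if (!is.finite(q0) || q0 <= 0) return(fallback("degenerate mode spacing"))
  # refine by projecting a fine histogram onto equally spaced Gaussians
  bw <- max(0.005, q0 / 10)
  edges <- seq(0, max(x) + 2 * bw, by = bw)
  counts <- as.numeric(table(cut(x, edges, right = FALSE)))
  mids <- edges[-1] - bw / 2
  score <- function(par) {
    q <- exp(par[1]); s <- exp(par[2])
    K <- max(1, round(max(x) / q))
    B <- vapply(seq_len(K), function(k) exp(-(mids - k * q)^2 / (2 * s^2)),
                numeric(length(mids)))
    fit <- tryCatch({
      cf <- qr.coef(qr(B), counts)
      cf[!is.finite(cf) | cf < 0] <- 0
      sum((counts - B %*% cf)^2)
    }, error = function(e) Inf)
    fit
  }
  s0 <- max(bw, q0 / 4)
  opt <- stats::optim(c(log(q0), log(s0)), score, method = "Nelder-Mead")
  q <- exp(opt$par[1]); s <- exp(opt$par[2])
  if (!is.finite(q) || q <= 0 || abs(log(q / q0)) > log(2)) {
    return(fallback("refinement diverged"))
  }
  list(q = q, sigma = s, modes = modes, used_fallback = FALSE)
}

# shared optimiser for the global quantal fits
qfit_optimise <- function(hists, model, n_sites, init, restarts, seed,
                          pois_mass = 0.999) {
  counts <- hists$counts
  edges <- hists$edges
  nc <- ncol(counts)
  conds <- colnames(counts)
  n_per_cond <- colSums(counts)
  q0 <- init$q
  s0 <- init$sigma
  if (!is.finite(s0) || is.na(s0) || s0 <= 0) s0 <- max(q0 / 3, 0.01)
  scale0 <- mean(n_per_cond)
  # moment-based starts for the release parameter per condition
  theta0 <- vapply(seq_len(nc), function(c) {
    a <- hists$amplitudes[[conds[c]]]
    fail_frac <- mean(a < hists$bin_width)
    fail_frac <- min(max(fail_frac, 1e-3), 1 - 1e-3)
    if (model == 0L) {
      p <- 1 - fail_frac^(1 / n_sites)
      qlogis(min(max(p, 0.02), 0.98))
    } else {
      log(max(-log(fail_frac), 0.05))
    }
  }, 1)
  par0 <- c(log(q0), log(s0), log(scale0), theta0)
  obj <- function(par) {
    qmix_objective_cpp(par, model, as.integer(n_sites), edges, counts,
                       pois_mass)
  }
  # a component narrower than a bin is numerically indistinguishable from a
  # point mass; keep sigma at least a third of the bin width
  s_floor <- min(s0, max(s0 / 10, hists$bin_width / 3))
  lower <- c(log(q0) - log(3), log(s_floor), log(scale0) - log(10),
             rep(if (model == 0L) qlogis(1e-3) else log(1e-3), nc))
  upper <- c(log(q0) + log(3), log(s0) + log(10), log(scale0) + log(10),
             rep(if (model == 0L) qlogis(1 - 1e-3) else log(20), nc))
  best <- NULL
  jit <- with_seed(seed, matrix(rnorm(restarts * length(par0), 0, 0.15),
                                restarts))
  jit[1, ] <- 0
  for (r in seq_len(restarts)) {
    par_r <- pmin(pmax(par0 + jit[r, ], lower), upper)
    fit <- tryCatch(nlminb(par_r, obj, lower = lower, upper = upper,
                           control = list(iter.max = 300, eval.max = 600)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (!is.null(best) &&
        abs(fit$objective - best$objective) <=
          1e-3 * max(1, abs(best$objective))) {
      # two initialisations agree on the optimum: stop early
      if (fit$objective < best$objective) best <- fit
      break
    }
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  best
}

quantal_fit_obj <- function(model_name, n_sites, par, conds, hists,
                            converged) {
  q <- exp(par[1]); sigma <- exp(par[2]); scale <- exp(par[3])
  theta <- par[-(1:3)]
  out <- list(model = model_name, q = q, sigma = sigma, scale = scale,
              conditions = conds, converged = converged,
              bin_width = hists$bin_width)
  if (model_name == "binomial") {
    out$n_sites <- as.integer(n_sites)
    out$p_release <- stats::setNames(plogis(theta), conds)
  } else {
    out$lambda <- stats::setNames(exp(theta), conds)
  }
  class(out) <- "quantal_fit"
  out
}

#' Mixture weights of a quantal fit for one condition
#'
#' Binomial: `dbinom(0:N, N, P_R)`. Poisson: the Poisson pmf truncated
#' where its cumulative mass exceeds 0.999 and renormalised. Weights sum
#' to 1.
#'
#' @param fit a `quantal_fit`.
#' @param condition condition label.
#' @return numeric vector of weights for components k = 0, 1, ...
#' @export
mixture_weights <- function(fit, condition) {
  if (fit$model == "binomial") {
    dbinom(0:fit$n_sites, fit$n_sites, fit$p_release[[condition]])
  } else {
    lam <- fit$lambda[[condition]]
    K <- 1
    while (ppois(K, lam) < 0.999 && K < 50) K <- K + 1
    w <- dpois(0:K, lam)
    w / sum(w)
  }
}

# per-component widths of a fit
component_sigmas <- function(fit, n_comp) {
  k <- seq_len(n_comp)
  if (fit$model == "poisson") fit$sigma * sqrt(k) else rep(fit$sigma, n_comp)
}

#' Expected bin counts under a quantal fit
#' @param fit a `quantal_fit`.
#' @param edges histogram bin edges.
#' @param condition condition label.
#' @return expected counts per bin.
#' @export
expected_counts <- function(fit, edges, condition) {
  w <- mixture_weights(fit, condition)
  qmix_expected_cpp(edges, w, fit$q, fit$sigma, fit$scale,
                    fit$model == "poisson")
}

#' Global binomial fit of per-condition quantal histograms
#'
#' Weighted least squares (Poisson-variance weights, floor 1) on the
#' concatenated per-condition bin counts. Free parameters: quantal size q,
#' a common Gaussian component width, a common scale factor, and one
#' release probability per condition. Component k (k = 0..N) is centred at
#' `k * q` with weight `dbinom(k, N, P_R)`; the k = 0 failure component is
#' a point mass assigned to the first bin, not a symmetric Gaussian.
#' Optimisation restarts from jittered initialisations and keeps the best
#' objective; the run is deterministic given `seed`.
#'
#' @param hists a [build_histograms()] result.
#' @param n_sites fixed integer number of release sites (N >= 1).
#' @param init list with starting `q` (and optionally `sigma`); defaults
#'   to the pooled-mixture estimate carried by `hists`.
#' @param restarts number of jittered initialisations.
#' @param seed seed for the jitter.
#' @return a `quantal_fit` with fields `q`, `sigma`, `scale`, `n_sites`,
#'   `p_release`, `objective`, `converged`, plus `ks` once
#'   [add_ks_goodness()] has run.
#' @export
fit_binomial_global <- function(hists, n_sites, init = NULL, restarts = 5,
                                seed = 1L) {
  stopifnot(inherits(hists, "quantal_histograms"), n_sites >= 1)
  init <- init %||% list(q = hists$q_init %||% median(
    unlist(hists$amplitudes)[unlist(hists$amplitudes) > 0]))
  if (is.null(init$sigma)) init$sigma <- NA_real_
  best <- qfit_optimise(hists, 0L, n_sites, init, restarts, seed)
  if (is.null(best)) {
    return(structure(list(model = "binomial", n_sites = n_sites,
                          converged = FALSE),
                     class = "quantal_fit"))
  }
  fit <- quantal_fit_obj("binomial", n_sites, best$par,
                         colnames(hists$counts), hists,
                         best$convergence == 0)
  fit$objective <- best$objective
  pinned <- fit$p_release <= plogis(qlogis(1e-3) + 1e-6) |
    fit$p_release >= plogis(qlogis(1 - 1e-3) - 1e-6)
  fit$p_pinned <- pinned
  fit
}

#' Global Poisson fit of per-condition quantal histograms
#'
#' As [fit_binomial_global()], but component k is weighted by the Poisson
#' pmf with one free rate lambda per condition (components truncated where
#' the cumulative Poisson mass exceeds 0.999) and the Gaussian component
#' widths grow in proportion, `sigma_k = sigma_1 * sqrt(k)`.
#'
#' @inheritParams fit_binomial_global
#' @return a `quantal_fit` with `lambda` per condition.
#' @export
fit_poisson_global <- function(hists, init = NULL, restarts = 5, seed = 1L) {
  stopifnot(inherits(hists, "quantal_histograms"))
  init <- init %||% list(q = hists$q_init %||% median(
    unlist(hists$amplitudes)[unlist(hists$amplitudes) > 0]))
  if (is.null(init$sigma)) init$sigma <- NA_real_
  best <- qfit_optimise(hists, 1L, 0L, init, restarts, seed)
  if (is.null(best)) {
    return(structure(list(model = "poisson", converged = FALSE),
                     class = "quantal_fit"))
  }
  fit <- quantal_fit_obj("poisson", 0L, best$par, colnames(hists$counts),
                         hists, best$convergence == 0)
  fit$objective <- best$objective
  fit
}

#' @export
print.quantal_fit <- function(x, ...) {
  cat("<quantal_fit> ", x$model, sep = "")
  if (!isTRUE(x$converged)) cat(" (not converged)")
  cat("\n")
  if (!is.null(x$q)) {
    cat("  q =", signif(x$q, 4), " sigma =", signif(x$sigma, 4),
        " scale =", signif(x$scale, 4), "\n")
    if (x$model == "binomial") {
      cat("  N =", x$n_sites, " P_R:",
          paste(names(x$p_release), signif(x$p_release, 3), sep = "=",
                collapse = " "), "\n")
    } else {
      cat("  lambda:", paste(names(x$lambda), signif(x$lambda, 3),
                             sep = "=", collapse = " "), "\n")
    }
  }
  invisible(x)
}

kolmogorov_p <- function(t) {
  if (t < 1e-3) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(max(p, 0), 1)
}

model_cdf <- function(fit, condition, x) {
  w <- mixture_weights(fit, condition)
  K <- length(w) - 1
  out <- w[1] * as.numeric(x >= 0)
  if (K >= 1) {
    sg <- component_sigmas(fit, K)
    for (k in seq_len(K)) {
      out <- out + w[k + 1] * pnorm(x, k * fit$q, sg[k])
    }
  }
  out
}

#' Kolmogorov-Smirnov goodness of fit for one condition
#'
#' Compares the empirical CDF of the observed amplitudes with the model
#' CDF (failure point mass at 0 plus weighted Gaussian CDFs). D is the
#' supremum distance evaluated at the sample points (both sides of each
#' empirical step); the p value comes from the asymptotic Kolmogorov
#' distribution and is approximate in the presence of the point mass and
#' of fitted parameters.
#'
#' @param amplitudes observed amplitudes of the condition (non-empty).
#' @param fit a converged `quantal_fit`.
#' @param condition condition label.
#' @return list with `statistic` (D) and `p_value`.
#' @export
ks_goodness <- function(amplitudes, fit, condition) {
  if (!length(amplitudes)) stop("empty amplitude sample")
  if (!isTRUE(fit$converged) && is.null(fit$q)) stop("fit did not converge")
  x <- sort(amplitudes)
  n <- length(x)
  u <- unique(x)
  ecdf_hi <- vapply(u, function(v) mean(x <= v), 1)
  ecdf_lo <- vapply(u, function(v) mean(x < v), 1)
  m_hi <- model_cdf(fit, condition, u)
  # left limit of the model CDF: drop the failure point mass at 0
  w0 <- mixture_weights(fit, condition)[1]
  m_lo <- m_hi - w0 * as.numeric(u == 0)
  D <- max(abs(ecdf_hi - m_hi), abs(ecdf_lo - m_lo))
  list(statistic = D, p_value = kolmogorov_p(sqrt(n) * D))
}

#' Attach per-condition K-S results to a fit
#' @param fit a `quantal_fit`.
#' @param hists the [build_histograms()] result it was fitted to.
#' @return the fit with a `ks` data frame (`condition`, `statistic`,
#'   `p_value`) and `min_ks_p`.
#' @export
add_ks_goodness <- function(fit, hists) {
  if (is.null(fit$q)) {
    fit$ks <- NULL
    fit$min_ks_p <- NA_real_
    return(fit)
  }
  ks <- do.call(rbind, lapply(fit$conditions, function(cd) {
    r <- ks_goodness(hists$amplitudes[[cd]], fit, cd)
    data.frame(condition = cd, statistic = r$statistic,
               p_value = r$p_value, stringsAsFactors = FALSE)
  }))
  fit$ks <- ks
  fit$min_ks_p <- min(ks$p_value)
  fit
}

#' Brute-force selection of the number of release sites
#'
#' Fits the binomial model for every candidate N, scores each fit by the
#' minimum per-condition K-S p value, and returns the fit with the highest
#' score; ties (within numerical tolerance) break toward smaller N.
#' Candidates clearly unable to reach the largest observed quantal level
#' (more than two quanta short of the maximum amplitude at the initial q)
#' are skipped. The full per-N table is retained in place of the original
#' manual check.
#'
#' @param hists a [build_histograms()] result.
#' @param n_range candidate integer N values.
#' @param init,restarts,seed forwarded to [fit_binomial_global()].
#' @return list with `best` (a `quantal_fit` with K-S results),
#'   `selected_n`, and `table` (one row per fitted N); `best` is `NULL`
#'   with a diagnostic when every fit fails.
#' @export
select_best_n <- function(hists, n_range = 1:12, init = NULL, restarts = 5,
                          seed = 1L) {
  stopifnot(inherits(hists, "quantal_histograms"), length(n_range) >= 1)
  q0 <- (init$q %||% hists$q_init) %||% median(
    unlist(hists$amplitudes)[unlist(hists$amplitudes) > 0])
  max_amp <- max(unlist(hists$amplitudes))
  # prune only clearly infeasible N: allow the pooled q estimate to be off
  # by up to a factor of two (it can lock onto a subharmonic spacing)
  n_min <- max(1, ceiling(max_amp / (2 * q0)) - 1)
  cand <- n_range[n_range >= n_min]
  if (!length(cand)) cand <- max(n_range)
  fits <- list()
  rows <- list()
  for (n in sort(cand)) {
    f <- fit_binomial_global(hists, n, init = init, restarts = restarts,
                             seed = derive_seed(seed, n))
    f <- add_ks_goodness(f, hists)
    # a fit whose N quanta cannot reach the largest observed response is
    # infeasible (n_sites must cover the maximum quantal level)
    if (!is.null(f$q) && n * f$q + 3 * f$sigma < max_amp) {
      f$min_ks_p <- NA_real_
    }
    fits[[as.character(n)]] <- f
    rows[[as.character(n)]] <- data.frame(
      n_sites = n, q = f$q %||% NA_real_, sigma = f$sigma %||% NA_real_,
      objective = f$objective %||% NA_real_,
      min_ks_p = f$min_ks_p %||% NA_real_,
      converged = isTRUE(f$converged))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ok <- which(!is.na(tab$min_ks_p))
  if (!length(ok)) {
    return(list(best = NULL, selected_n = NA_integer_, table = tab,
                diagnostic = "all fits failed"))
  }
  best_p <- max(tab$min_ks_p[ok])
  sel <- tab$n_sites[ok][which(tab$min_ks_p[ok] >= best_p - 1e-9)[1]]
  list(best = fits[[as.character(sel)]], selected_n = as.integer(sel),
       table = tab)
}

#' Prefer the binomial or Poisson model for one ROI
#'
#' The model with the larger minimum per-condition K-S p value wins; exact
#' ties are flagged. When one fit is absent the other wins by default,
#' flagged.
#'
#' @param binomial_fit,poisson_fit `quantal_fit`s with K-S results (see
#'   [add_ks_goodness()]); either may be `NULL`.
#' @return list with `preferred` (`"binomial"`/`"poisson"`), `margin`
#'   (difference of the two minimum p values) and `flagged`.
#' @export
classify_model <- function(binomial_fit, poisson_fit) {
  bp <- if (!is.null(binomial_fit)) binomial_fit$min_ks_p else NA_real_
  pp <- if (!is.null(poisson_fit)) poisson_fit$min_ks_p else NA_real_
  if (is.na(bp) && is.na(pp)) {
    return(list(preferred = NA_character_, margin = NA_real_,
                flagged = TRUE))
  }
  if (is.na(bp)) {
    return(list(preferred = "poisson", margin = NA_real_, flagged = TRUE))
  }
  if (is.na(pp)) {
    return(list(preferred = "binomial", margin = NA_real_, flagged = TRUE))
  }
  if (bp == pp) {
    return(list(preferred = "tie", margin = 0, flagged = TRUE))
  }
  list(preferred = if (bp > pp) "binomial" else "poisson",
       margin = bp - pp, flagged = FALSE)
}

#' Fraction of responsive ROIs usable for histogram fitting
#'
#' @param peaks a `peak_table` (after [snr_and_exclusion()]).
#' @param fits named list of per-ROI fit results (elements may be `NULL`
#'   or carry `converged`); ROIs without an entry count as unusable.
#' @return fraction in `[0, 1]`, or `NA` when there are no responsive
#'   ROIs.
#' @export
usable_roi_fraction <- function(peaks, fits) {
  rois <- unique(peaks$roi_id)
  if (!length(rois)) return(NA_real_)
  ok <- vapply(rois, function(r) {
    if (any(peaks$excluded[peaks$roi_id == r])) return(FALSE)
    f <- fits[[r]]
    !is.null(f) && isTRUE(f$converged %||% FALSE)
  }, TRUE)
  mean(ok)
}
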