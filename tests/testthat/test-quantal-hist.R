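study_p <- c("0.5" = 0.1, "2" = 0.4, "4" = 0.7)

test_that("binomial mixture weights equal brute-force site enumeration", {
  for (n in 1:6) {
    for (p in c(0.1, 0.4, 0.9)) {
      fit <- structure(list(model = "binomial", n_sites = n,
                            p_release = stats::setNames(p, "2"),
                            q = 0.09, sigma = 0.03, scale = 1,
                            converged = TRUE), class = "quantal_fit")
      expect_equal(mixture_weights(fit, "2"), enum_binom_weights(n, p),
                   tolerance = 1e-12)
    }
  }
})

test_that("histograms conserve counts and pin failures to the first bin", {
  amps <- simulate_quantal_amplitudes(50, 0.09, 0.02, "binomial",
                                      n_sites = 5, p_release = study_p,
                                      seed = 5)
  h <- quantal_histograms(amps)
  expect_equal(sum(h$counts), 150)
  expect_equal(h$pooled, rowSums(h$counts))

  # all failures: everything in the first bin
  h0 <- quantal_histograms(list("2" = rep(0, 40)), bin_width = 0.05)
  expect_equal(unname(h0$counts[1, 1]), 40)
  expect_true(all(h0$counts[-1, 1] == 0))

  # binning arithmetic for {0, 0.09, 0.18} at width 0.05
  h1 <- quantal_histograms(list("2" = c(0, 0.09, 0.18)), bin_width = 0.05)
  expect_equal(unname(h1$counts[1:4, 1]), c(1, 1, 0, 1))

  pk <- make_peak_table(list(r = c(0, 0.09, 0.18)))
  h2 <- build_histograms(pk, "r", bin_width = 0.05)
  expect_equal(unname(h2$counts[1:4, 1]), c(1, 1, 0, 1))
  pk$excluded <- TRUE
  pk$reason <- "rundown"
  expect_error(build_histograms(pk, "r"), "excluded")
  expect_error(build_histograms(pk, "missing"), "no responses")
})

test_that("pooled mixture estimates the quantal spacing", {
  amps <- unlist(simulate_quantal_amplitudes(
    200, 0.09, 0.015, "binomial", n_sites = 5,
    p_release = c("2" = 0.3, "4" = 0.6), seed = 8))
  est <- fit_pooled_gaussian_mixture(amps)
  expect_false(est$used_fallback)
  expect_equal(est$q, 0.09, tolerance = 0.15)

  # doubling the spacing doubles the estimate
  est2 <- fit_pooled_gaussian_mixture(2 * amps)
  expect_equal(est2$q / est$q, 2, tolerance = 0.15)

  # single-mode input takes the fallback path
  set.seed(9)
  single <- abs(rnorm(200, 0.1, 0.01))
  expect_warning(estf <- fit_pooled_gaussian_mixture(single), "falling back")
  expect_true(estf$used_fallback)
})

test_that("global binomial fit recovers parameters at low noise", {
  amps <- simulate_quantal_amplitudes(120, 0.09, 0.01, "binomial",
                                      n_sites = 7,
                                      p_release = study_p, seed = 14)
  h <- suppressWarnings(quantal_histograms(amps))
  f <- fit_binomial_global(h, 7, seed = 2)
  expect_true(f$converged)
  expect_equal(f$q, 0.09, tolerance = 0.05)
  for (cd in names(study_p)) {
    expect_lt(abs(unname(f$p_release[cd]) - unname(study_p[cd])), 0.05)
  }
  # mixture weights are a probability distribution
  for (cd in names(study_p)) {
    expect_equal(sum(mixture_weights(f, cd)), 1, tolerance = 1e-12)
  }
  # the generating N scores at least as well as its neighbours
  f <- add_ks_goodness(f, h)
  f6 <- add_ks_goodness(fit_binomial_global(h, 6, seed = 2), h)
  f8 <- add_ks_goodness(fit_binomial_global(h, 8, seed = 2), h)
  expect_gte(f$min_ks_p, f6$min_ks_p)
})

test_that("global Poisson fit recovers lambda and q", {
  lam <- q <- conv <- numeric(0)
  for (s in 1:3) {
    amps <- simulate_quantal_amplitudes(150, 0.09, 0.02, "poisson",
                                        lambda = c("2" = 2), seed = 21 + s)
    h <- suppressWarnings(quantal_histograms(amps))
    f <- fit_poisson_global(h, seed = 3)
    conv <- c(conv, f$converged)
    lam <- c(lam, unname(f$lambda[["2"]]))
    q <- c(q, f$q)
  }
  expect_true(all(conv == 1))
  expect_equal(median(q), 0.09, tolerance = 0.10)
  expect_equal(median(lam), 2, tolerance = 0.10)

  # lambda -> 0 puts all model mass in the failure bin
  f0 <- structure(list(model = "poisson", q = 0.09, sigma = 0.02,
                       scale = 100, lambda = c("2" = 1e-8),
                       conditions = "2", converged = TRUE),
                  class = "quantal_fit")
  e <- expected_counts(f0, h$edges, "2")
  expect_equal(e[1], 100, tolerance = 1e-4)
  expect_lt(sum(e[-1]), 1e-4)
})

test_that("K-S goodness separates matching from shifted samples", {
  fit <- structure(list(model = "binomial", n_sites = 5, q = 0.09,
                        sigma = 0.03, scale = 1,
                        p_release = c("2" = 0.4), conditions = "2",
                        converged = TRUE), class = "quantal_fit")
  big <- simulate_quantal_amplitudes(4000, 0.09, 0.03, "binomial",
                                     n_sites = 5,
                                     p_release = c("2" = 0.4), seed = 4)
  ks <- ks_goodness(big[["2"]], fit, "2")
  expect_lt(ks$statistic, 0.05)
  expect_gt(ks$p_value, 0.1)

  a150 <- simulate_quantal_amplitudes(150, 0.09, 0.03, "binomial",
                                      n_sites = 5,
                                      p_release = c("2" = 0.4), seed = 5)
  shifted <- ifelse(a150[["2"]] == 0, 0, a150[["2"]] + 0.09)
  ks2 <- ks_goodness(shifted, fit, "2")
  expect_lt(ks2$p_value, 0.01)
  expect_true(ks$statistic >= 0 && ks$statistic <= 1)
  expect_true(ks2$statistic >= 0 && ks2$statistic <= 1)
  expect_error(ks_goodness(numeric(0), fit, "2"), "empty")
})

test_that("brute-force N selection recovers the generating site count", {
  # quantal-resolvable data (component width well below the spacing)
  hits <- 0
  for (rep in 1:50) {
    amps <- simulate_quantal_amplitudes(50, 0.09, 0.01, "binomial",
                                        n_sites = 3, p_release = study_p,
                                        seed = 40 + rep)
    h <- suppressWarnings(quantal_histograms(amps))
    sel <- select_best_n(h, n_range = 1:8, seed = rep)
    if (identical(sel$selected_n, 3L)) hits <- hits + 1
  }
  expect_gte(hits, 40)

  # singleton range returns that N
  amps <- simulate_quantal_amplitudes(50, 0.09, 0.02, "binomial",
                                      n_sites = 3, p_release = study_p,
                                      seed = 60)
  h <- suppressWarnings(quantal_histograms(amps))
  s1 <- select_best_n(h, n_range = 5, seed = 1)
  expect_equal(s1$selected_n, 5L)

  # exact plateau ties break toward smaller N
  tab_dup <- select_best_n(h, n_range = 3:6, seed = 1)
  expect_true(tab_dup$selected_n ==
                tab_dup$table$n_sites[which.max(tab_dup$table$min_ks_p)] ||
              tab_dup$selected_n <
                max(tab_dup$table$n_sites[tab_dup$table$min_ks_p >=
                                            max(tab_dup$table$min_ks_p,
                                                na.rm = TRUE) - 1e-9]))
})

test_that("model classification prefers the generating model class", {
  amps_b <- simulate_quantal_amplitudes(50, 0.09, 0.03, "binomial",
                                        n_sites = 5, p_release = study_p,
                                        seed = 71)
  hb <- suppressWarnings(quantal_histograms(amps_b))
  bb <- select_best_n(hb, seed = 1)
  pb <- add_ks_goodness(fit_poisson_global(hb, seed = 1), hb)
  expect_equal(classify_model(bb$best, pb)$preferred, "binomial")

  # ties and missing fits are flagged
  expect_true(classify_model(bb$best, bb$best)$flagged)
  expect_equal(classify_model(NULL, pb)$preferred, "poisson")
  expect_equal(classify_model(bb$best, NULL)$preferred, "binomial")
})

test_that("usable ROI fraction counts converged, included ROIs", {
  pk <- make_peak_table(list(a = rep(0.1, 10), b = rep(0.1, 10),
                             c = rep(0.1, 10), d = rep(0.1, 10)))
  fits <- list(a = list(converged = TRUE), b = list(converged = TRUE),
               c = list(converged = FALSE), d = NULL)
  expect_equal(usable_roi_fraction(pk, fits), 0.5)
  pk$excluded[pk$roi_id %in% c("a", "b")] <- TRUE
  expect_equal(usable_roi_fraction(pk, fits), 0)
  fits_all <- list(a = list(converged = TRUE), b = list(converged = TRUE),
                   c = list(converged = TRUE), d = list(converged = TRUE))
  pk$excluded <- FALSE
  expect_equal(usable_roi_fraction(pk, fits_all), 1)
})
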