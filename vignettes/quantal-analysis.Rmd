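---
title: "Optical quantal analysis with quantalfluor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optical quantal analysis with quantalfluor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantalfluor)
```

## The problem and the model

Genetically encoded glutamate sensors report neurotransmitter release as
fractional fluorescence changes (dF/F) at individual synaptic sites. When a
presynaptic terminal is driven by single action potentials, the peak dF/F
response at a region of interest (ROI) takes approximately discrete values:
multiples of a *quantal size* q, the fluorescence increment produced by one
released vesicle. quantalfluor extracts these per-stimulus response
amplitudes from movies or trace tables and estimates the quantal parameters
of each ROI under the classical binomial release model:

* N — the number of release sites in the ROI, each releasing at most one
  vesicle per stimulus;
* P_R — the per-site release probability, which varies with external
  calcium; and
* q — the quantal dF/F increment, constant across calcium conditions.

The number of vesicles released at one stimulus is Binomial(N, P_R); an
alternative Poisson model with rate lambda (mean quanta per stimulus) is
fitted for comparison. Two independent routes to P_R are implemented:

1. **CV route (population).** For each ROI the mean and SD of the five
   responses within a train are averaged over trains into one (mean, SD)
   point; the slope of the through-origin line fitted to SD against mean
   over ROIs estimates the coefficient of variation. For binomial release
   CV^2 = (1 − P_R)/(N · P_R), so for any candidate integer N the
   per-condition P_R follows exactly as P_R = 1/(1 + N·CV^2). Because one
   free P_R per condition fits each condition's CV exactly, N itself is not
   identified by goodness of fit; the conservative rule picks the smallest
   N whose low-calcium P_R falls below 50% (`select_min_n()`). This route
   gives a rank order of release probabilities across conditions rather
   than a precise N.
2. **Histogram route (per ROI).** Per-condition histograms of response
   amplitudes (failures recorded as exactly 0 and collected in the first
   bin) are fitted globally with a quantal Gaussian mixture: component k is
   centred at k·q with weight Binomial(k; N, P_R) (or Poisson(k; lambda)),
   a common width, a common scale, and one release parameter per condition;
   q and N are shared across conditions. The number of sites is selected by
   brute force over N = 1…12, scoring each fit by the minimum per-condition
   Kolmogorov–Smirnov p value and breaking ties toward smaller N.

## The analysis pipeline

For movies, responsive ROIs are found by scanning the image in 4 × 4-pixel
tiles: a tile is accepted when its raw mean-intensity trace shows more than
20 stimulus-locked transients with per-event dF/F ≥ 10% and SNR ≥ 3 (robust
SD, 1.4826 × MAD, of the tile dF/F trace). Four-connected accepted tiles
merge into composite ROIs. Background is the frame-wise mean of the dimmest
circular region (1 µm) without stimulus-locked modulation; dF/F is
(F − F0)/F0 with F the background-subtracted trace and F0 the median over
the pre-stimulus window.

Each ROI trace is baseline-corrected by asymmetric least squares (ALS): the
baseline minimises a weighted squared error with a second-difference
penalty, with weight `asymmetry` (default 0.01) for points above the
baseline and 1 − asymmetry below, so positive transients are ignored while
slow drift is tracked. The default smoothness 1e4 (units of squared frames,
effective scale ≈ 10 frames at 25 Hz) keeps 5 Hz transients out of the
baseline; both parameters are exposed.

Peaks on the across-ROI mean waveform are detected with a ricker
(Mexican-hat) continuous wavelet transform over widths of 1–8 frames, with
an SNR threshold that must hold on at least half of the scales (a ridge
requirement that suppresses single-scale noise excursions). A headless
curation hook (`add`/`remove` indices) replaces the interactive step of a
GUI. Because the symmetric wavelet centres on the mass of an
instant-rise/exponential-decay transient rather than on its maximum, the
per-stimulus template locations are snapped to the consensus
stimulus-triggered lag of the mean waveform.

**Amplitude definition.** At 5 Hz stimulation the sensor decay (default
time constant 0.4 s) makes responses within a train summate, so the raw
trace value at a peak contains the residual of earlier transients. The
extracted amplitude is therefore the *increment*: the corrected trace at
the template frame minus the pre-stimulus level projected forward by the
per-frame decay factor (estimated once per recording from the mean
waveform's post-train tail). Two design choices here deserve a note,
because simpler alternatives are subtly biased:

* Evaluating at the template frame (default), rather than taking the
  maximum within ±2 frames of it, avoids adding the expected extreme of
  the window noise (≈ +1 noise SD) to every amplitude — an offset that
  breaks the equal spacing k·q that the mixture model relies on. The
  windowed maximum remains available (`amplitude_at = "window_max"`) for
  data with per-ROI timing jitter.
* The peak estimate averages the template frame with the next frame scaled
  by 1/decay, and the residual estimate averages the two pre-stimulus
  frames projected forward — each an unbiased estimate under the
  exponential kernel — reducing amplitude noise by roughly 25%. With
  noise-free input the extracted amplitude equals count × q exactly.

Responses below 2 × the ROI's noise SD are failures, recorded as exactly 0
(the failure cut-off is configurable; the value 0 is part of the method).
ROIs are excluded with a recorded reason when the median event SNR falls
below 3, when the rundown ratio (mean of the last decile of responses over
the first decile) falls below 0.5, or when F0 is not positive.

## The synthetic-data generator

Every stage is validated against `simulate_experiment()`, which draws
per-stimulus vesicle counts (binomial or Poisson; for Poisson the rate is
P_R·N by convention), renders each ROI's dF/F trace with an
instantaneous-rise single-exponential-decay kernel (default tau 0.4 s, of
the order of the slow sensor decay), additive Gaussian noise, optional
linear-plus-exponential baseline drift, and optional per-train
multiplicative rundown, and can render movies by modulating Gaussian spots
(targeted ≈ 0.3 µm or diffuse ≈ 1.5 µm footprints) on a constant background
with camera and shot noise. Defaults are the study conditions used by the
validation suite: N = 5, q = 0.09 dF/F, P_R = 0.1/0.4/0.7 at 0.5/2/4 mM
calcium, noise SD 0.03, three conditions of 10 trains × 5 stimuli at 5 Hz,
imaged at 25 Hz. One master seed drives everything; per-ROI streams are
derived deterministically, so equal seeds give bit-identical data.

What the generator deliberately does **not** emulate: sensor binding
kinetics and saturation, per-vesicle quantal variability (the quantal
amplitude is fixed; amplitude noise is additive and constant), motion,
bleaching beyond slow drift, and spontaneous release. Passing tests on this
generator therefore demonstrate correctness of the estimators under the
stated model, not robustness to every artefact of real recordings.

## Numerical choices

* Histogram bin width defaults to one third of the pooled quantal-size
  estimate, floored at 0.01 dF/F. The pooled estimate finds KDE modes of
  the positive amplitudes and refines their spacing by projecting a fine
  histogram onto equally spaced Gaussians; with fewer than two discernible
  modes it falls back to the 15th percentile of positive amplitudes (an
  approximation to the single-quantum level when multi-quantal responses
  dominate).
* The global fits minimise weighted least squares on binned counts with
  Poisson-variance weights floored at 1, over (log q, log sigma,
  log scale, one transformed release parameter per condition), using
  `nlminb` with moment-based starts (failure fraction inverted through the
  model) and up to five jittered restarts, stopping early when two
  initialisations agree to 0.1%. q is constrained to within 3× its initial
  estimate and sigma to at least a third of the bin width (a narrower
  component is numerically indistinguishable from a point mass).
* The k = 0 failure component is a point mass in the first bin for both
  models — no symmetric peak around zero is created from failures. The
  binomial model uses a common component width; the Poisson model grows
  widths as sigma·sqrt(k) and truncates components at 99.9% cumulative
  mass.
* The K–S statistic compares the empirical CDF with the mixture CDF
  (failure step at 0 plus weighted Gaussian CDFs), evaluating both one-sided
  gaps at the sample points with the model's left limit at the shared point
  mass; p values use the asymptotic Kolmogorov series and are approximate
  in the presence of fitted parameters and the point mass.
* Brute-force N selection skips candidates that are clearly unable to reach
  the largest observed amplitude (allowing the initial q to be off by up to
  2×), and disqualifies a fitted candidate whose N quanta plus 3 sigma fall
  short of the observed maximum — the fitted site count must cover the
  largest observed quantal level. Exact score ties break toward smaller N.

## Validation scale and known limitations

The packaged validation (see `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`) runs 20 synthetic experiments of 60 ROIs × 150
stimuli for parameter recovery, 50 replicates per side for model
classification, and one 256 × 256 × 1500-frame movie with 10 narrow and 10
broad planted spots for ROI detection — sizes chosen to give stable
statistics at desktop cost.

Two limitations are worth stating plainly. First, at realistic noise
(sigma/q ≈ 0.3–0.45) the K–S p value at 50 events per condition cannot
sharply distinguish adjacent N; selection is modal rather than certain, and
the per-N table is retained for inspection. Second, model classification is
asymmetric: binomial-generated data reject the Poisson fit easily
(sub-Poisson variance), but on Poisson-generated data the binomial family
with brute-forced N ≤ 12 nearly nests the Poisson count distribution, and
its best-of-N selection biases its K–S p upward, so the Poisson model is
preferred on its own data only moderately more often than not at 150
events. This is a property of the model pair at this sample size, not of
the optimiser: the fitted Poisson model scores as well as the true
generating parameters.

## A minimal run

```{r example, eval = FALSE}
gt <- ground_truth(seed = 42)          # N = 5, q = 0.09, study P_R map
sim <- simulate_experiment(20, gt, stim_protocol())
peaks <- snr_and_exclusion(extract_peaks_at_template(sim))

# CV route
cvs <- vapply(c("0.5", "2", "4"), function(cd) cv_slope(peaks, cd)$cv, 1)
select_min_n(cv_global_fit(cvs, 1:8))

# histogram route for one ROI
h <- build_histograms(peaks, "roi_1")
sel <- select_best_n(h)
sel$best
```

The same stages run end to end, with every output file and a manifest
written to disk, via `run_pipeline(run_config(mode = "simulate", ...))`.
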