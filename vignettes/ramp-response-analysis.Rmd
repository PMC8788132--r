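---
title: "Analysing luminance-ramp responses with ramplux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing luminance-ramp responses with ramplux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramplux)
library(dplyr)
```

## The problem

Slow, naturalistic changes in illumination — dawn, dusk, cloud cover —
are encoded in the zebrafish tectum by classes of neurons that respond
within distinct luminance ranges. The experimental probe is a
whole-field *luminance ramp*: display brightness rises linearly from a
minimum (0.4 LUX) to a maximum (32 LUX) over one ramp leg and falls
back over the next, repeated for several cycles. With a 10 s leg one
cycle lasts 20 s; with a 30 s leg, 60 s. Responses recorded with
GCaMP6s fall into three classes — ON (peak near maximum luminance),
OFF (near minimum) and DUAL (one peak on each leg) — plus a
nonresponsive remainder. `ramplux` implements the full analysis chain
from fluorescence traces (or raw movies) to class assignments, peak
kinetics, segmentation statistics and binocular receptive-field maps,
together with a synthetic generator that provides ground truth for all
of it.

## Normalisation and gating

Each ROI's trace is z-scored with the mean and standard deviation of
the samples inside the stimulus window, `z = (x − μ)/σ`. The σ uses
the population (N) denominator — the plain reading of "standard
deviation of the fluorescence"; `denominator = "sample"` switches to
N−1, which changes z by under 1% for the trace lengths involved.
Because μ and σ absorb gain and offset, the z trace is invariant to
affine rescaling of the raw fluorescence, so detector gain and
background-subtraction conventions do not reach any downstream stage.

ROIs whose z never leaves the band ±0.5 over the stimulus window are
gated out as nonresponsive (the bound is exclusive: a single sample at
|z| = 0.500001 counts as responsive). Two caveats are worth stating
plainly. First, a *constant* trace has σ = 0 and cannot be z-scored;
it is flagged (`flat`) and treated as nonresponsive without dividing.
Second, by construction a z-scored trace has unit variance, so a pure
noise trace will essentially always leave ±0.5 somewhere: on noisy
data the gate catches flat and near-dead ROIs, while genuinely
unresponsive-but-noisy ROIs are identified by the classifier's
nonresponsive class instead. Both routes are exercised in the tests.

Consecutive ramps are then folded with `cycle_fold()` and averaged
pointwise into one cycle response on a regular grid of
`2·ramp_s·rate_hz` bins (nearest-bin assignment, no interpolation).
Partial trailing cycles are discarded; the first cycle — which carries
the indicator onset transient — is kept by default because discarding
it costs averaging power at the trace lengths used here
(`drop_first_cycle = TRUE` reverses that). Averaging n cycles reduces
noise SD by ≈ 1/√n, which the test suite verifies by Monte Carlo.

## Peak kinetics

The response statistics are built on *significant peaks*: local maxima
of the cycle-averaged z trace with topographic prominence strictly
greater than 0.75 z-units. Methods-style texts describe this threshold
both as a prominence and as a "minimum Z-score"; we implement the
prominence reading, which subsumes the other for responses rising from
a ≈0 baseline. Prominence is the classic lowest-contour definition.
Because the cycle response is periodic, detection runs on the cyclic
domain: from each candidate peak we descend in both directions until
strictly higher ground (or a full wrap), and the key col is the higher
of the two path minima. OFF responses peak at minimum luminance — the
cycle seam — and are found exactly once this way. Plateaus of tied
samples count as a single peak at their centre; an exhaustive
comparison against an independent level-set oracle over all short
small-valued signals pins this behaviour down in the tests.

Two statistics follow, per ROI:

* **LUX-at-half-max.** The half-height level is
  `baseline + (height − baseline)/2` with the baseline taken as the
  minimum of the cycle response (the prominence-referenced alternative
  is available via `baseline = "prominence"`). The crossing *preceding*
  the peak — "reached 50%" reads as onset — is located by linear
  interpolation between samples and mapped through the triangular wave
  to a luminance. With several significant peaks (DUAL), the most
  prominent peak is used; in DUAL responses that is the OFF-phase peak
  by construction of the class. (Methods-style wording that averages
  LUX over peaks exists; we follow the dominant-peak rule, which is
  the one stated alongside the DUAL definition.)
* **Width-at-half-max.** `right crossing − left crossing`, averaged
  across significant peaks when there are several.

Both statistics converge to the analytic values of noiseless synthetic
traces as the sampling rate grows; at a given rate the error is
bounded by one sample of linear interpolation (0.5 s at 2 Hz, i.e.
1.6 LUX on a 10 s ramp). Because the synthetic firing kernels live in
the luminance domain, the same kernel played on a 30 s ramp produces
widths 3× those of the 10 s ramp — an invariance the acceptance suite
checks with a fast indicator, where the convolution does not add
appreciable width of its own. With the slow GCaMP6s kernel the
measured width includes indicator decay; the statistics describe the
calcium signal, not the underlying firing.

## Classification

Features are the phase-aligned cycle response resampled to L = 40
points by linear interpolation on the cyclic domain. The z scale from
preprocessing is deliberately kept (no per-vector renormalisation), so
amplitude remains available for separating weak from strong
responders.

The supervised route is a linear-kernel SVM (one-vs-one, cost 1),
evaluated by stratified 5-fold cross-validation with a seeded fold
assignment; fold accuracies, their mean and the pooled held-out
confusion matrix are reported, and the returned model is refit on all
data. Prediction applies the responsiveness gate first: a gated-out
ROI is nonresponsive regardless of the model. The SVM is trained with
the nonresponsive class included — traces enter classification
"binned altogether" — and the label-shuffle control in the tests
confirms the CV estimate sits at chance when the labels carry no
information.

The unsupervised route runs `stats::kmeans` for k = 2…8 with 1000
random restarts per k and scores each k with the Calinski–Harabasz
index, `(B/(k−1))/(W/(n−k))`. The optimum is taken at the criterion
maximum — for the CH index the elbow of the curve and its maximum
coincide for well-separated data, and the maximum is the standard,
parameter-free reading (a curvature-based elbow was considered and
rejected as less stable on short k ranges). Clusters are then binned
to classes from their centroids: no significant centroid peak →
nonresponsive; two or more → DUAL; one → ON or OFF according to the
stimulus luminance at the peak relative to mid-range. On separable
synthetic data the binning agrees with the ground-truth labels and
with the per-item kinetics.

## Synthetic data: what it emulates, and what not

`simulate_trace()` draws a firing rate as a Gaussian in *(luminance,
phase)* space — ON centred at 32 LUX, OFF at 0.4 LUX, DUAL with a
dominant falling-leg peak and a rising-leg peak scaled by
`dual_ratio = 0.6 < 1`, widths 6 LUX — evaluated along the ramp,
convolved with a causal unit-area double-exponential indicator
(`tau_rise` 0.2 s, `tau_decay` 1.8 s: slow GCaMP6s at the 1–2 Hz
acquisition rates used for ramp imaging) and topped with i.i.d.
Gaussian noise, default SD 0.2 of the kernel amplitude.
`simulate_dataset()` jitters tuning centres, widths and amplitudes
per unit and records ground truth (label, half-max luminance computed
on a dense 20 Hz grid by a direct global-max crossing search,
independent of the prominence machinery it later validates).
Defining kernels over luminance rather than time is what makes class
kinetics consistent across 10 s and 30 s ramps, mirroring the
biological observation the classes were defined by.

The generator reproduces the statistical structure the analysis
assumes — cycle-locked responses, slow-indicator kinetics, additive
noise — but not photon shot noise, bleaching drift, motion artifacts
or spike-level variability. Passing tests therefore demonstrate the
correctness of the analysis given those assumptions, not performance
on arbitrary raw recordings.

## Movie segmentation

`active_pixel_mask()` implements the multiplicative activity
threshold: a pixel is active when its temporal maximum reaches 175% of
its temporal mean, i.e. changes by at least 75% over that pixel's
average intensity — the reading that matches the "175%" phrasing; a
ΔF/F-style variant against a low-quantile baseline sits behind
`mode = "dff"`. Movies are assumed background-subtracted, and pixels
whose mean is non-positive (or below `min_mean`) are excluded with a
warning rather than divided by.

A raw temporal maximum is an extreme-value statistic: over ~120 frames
it sits several noise SDs above the true transient amplitude, which
makes the 175% rule noise-dominated on low-SNR movies. For that reason
the mask accepts `smooth_window` — a centred moving average (3 frames
is a good default at 1 Hz, roughly the indicator decay) applied before
the maximum, so the maximum estimates the transient amplitude. The
default is `smooth_window = 1` (the literal rule; the boundary
arithmetic at 1.75× mean is then exact), and the noisy-movie analyses
in the tests and acceptance script pass `smooth_window = 3`.

`group_rois()` labels 8-connected components of the mask and refines
them by trace coherence: pixels whose lightly smoothed trace
correlates below `corr_min = 0.7` with the component mean are removed
and regrouped among themselves (with a fall-back reference — the pixel
with the largest transient — for the degenerate case where
anticorrelated halves cancel in the mean). Components below
`min_size_px = 4` are discarded, which also suppresses isolated
false-positive pixels. `corr_min` is a free parameter of the method;
the coherence correlations use smoothed traces because at SNR ≈ 5 the
per-pixel correlation with the component mean is otherwise bounded
near 0.6 by noise alone, and a 0.7 threshold would shatter genuine
regions. The study-condition fixture (three 10×10 regions in a 64×64
field, baseline 70, amplitude 100, SNR 5, 30 s ramps, sparse OFF
kernels of width 4 LUX) was chosen by a detectability analysis of
exactly these trade-offs; at those settings region counts are
recovered exactly and areas within a few percent across seeds, which
the acceptance suite verifies at the ±15% level.

`active_area_fraction()` divides total ROI area by a reference mask
(for example thresholded anatomy of all labelled inputs), and
`layer_tally()` assigns ROIs to user-supplied integer layer masks by
centroid with a majority-pixel fallback — the package never infers
anatomical boundaries.

## Receptive-field mapping

Each hemifield is mapped with a 6×4 array of 15° squares presented one
at a time for 10 s with 10 s gaps in a seeded pseudorandom order
(`checkerboard_stimulus()` records the seed; `trial_schedule()` is a
permutation of all 24 positions). `rf_map()` z-scores each unit over
its *entire* recording — both hemifield sessions pooled, distinct from
the stimulus-window normalisation used for ramp traces — and takes per
trial the maximum z from square onset to `lag_s = 2` s past offset,
a window that catches the slow indicator peak; whether the gap should
count is ambiguous, and the lag parameter covers both readings.
Pooling the sessions is essential: normalising a silent hemifield on
its own would rescale its noise to unit variance and the windowed
maximum would then cross any fixed threshold spuriously.

RF size is the number of positions with z ≥ 1.5 (inclusive);
`binocular_summary()` adds the contra/ipsi size ratio (undefined for
monocular units, which are excluded from ratio summaries), the
binocularity call (both hemifields ≥ 1 position) and the number of
8-connected suprathreshold components per hemifield, a descriptor of
compound RFs. `tier_comparison()` reports mean size ± SEM per tier and
whether mean(PyrN) > mean(SMTL) ≥ mean(RGC).

`simulate_rf_scene()` builds the convergence ground truth: RGCs get
contiguous 1–3-position monocular footprints; each SMTL pools 3 RGCs
(hemifields may mix, which is what makes SMTLs binocular); each PyrN
pools 3 SMTLs plus one direct RGC; every downstream footprint is the
union of its sources'. `simulate_rf_responses()` gives each unit a 2 s
burst at square onset within its footprint, at noise SD 0.01 of the
response amplitude. That noise level reflects what the z ≥ 1.5
window-max rule presumes — mapping analyses operate on ROI-averaged,
signal-dominated traces; at noise SDs approaching the response
amplitude the windowed maximum of noise alone approaches the
threshold and the rule (any implementation of it) stops being
meaningful. Under these conditions noiseless footprints are recovered
exactly and the PyrN > SMTL ≥ RGC ordering holds in ≥ 95% of seeded
scenes.

## Numerical choices and limitations

* Phase tags at extrema: the cycle start is RISING, the apex FALLING
  (half-open legs), so every sample has an unambiguous phase.
* Ties: equal-prominence peak selection takes the earlier peak;
  plateau peaks report their centre sample.
* Half-max searches always terminate because the half level lies
  strictly above the cycle minimum; a search that would wrap a full
  cycle is truncated and flagged.
* Degenerate inputs: constant traces, empty masks, missing trials and
  sub-minimum class counts raise typed errors or flags rather than
  propagating NaNs.
* Problem sizes throughout the tests and acceptance script — 25–50
  traces per class, 64×64×120 movies, 10–50 seeded scenes — were
  chosen as the smallest sizes at which the verified statistics are
  stable.
* The kinetics describe the calcium signal, not firing: no
  deconvolution is attempted, and half-max statistics inherit the
  indicator's lag and decay. Supervised accuracies on synthetic data
  are upper bounds relative to manually labelled recordings, whose
  label noise and class imbalance the generator does not model.
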