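---
title: "Tracing fetal PWD velocity envelopes and assessing the processing chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing fetal PWD velocity envelopes and assessing the processing chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(pwdtrace)
```

## The problem

Pulsed-wave Doppler (PWD) of the fetal heart, recorded from the apical
five-chamber view with the sample volume at the mitral-aortic junction, shows
two waves per cardiac cycle: a biphasic diastolic E/A wave (mitral inflow,
with E smaller than A before birth) and a systolic V wave (aortic outflow) of
opposite polarity. Automatic analysis of such recordings usually starts by
tracing the *maximum-velocity envelope*: for every time column of the
spectrogram, the outermost velocity at which signal is present, above
(`G_u`) and below (`G_l`) the zero-velocity baseline.

Many tracing algorithms have been published, all decomposable into the same
six-slot workflow:

1. **image smoothing** — Gaussian low-pass (sigma 1.5) or nothing;
2. **contrast enhancement** — k-means three-class stretch, morphological
   intensity adjustment, or nothing;
3. **binarisation** — 2D Otsu, Canny, NLLAP, NLLAP+Sobel, local adaptive
   percentile, steepest histogram gradient, or global Otsu;
4. **mask clean-up** — removal of small connected components (70, 500 or 50
   pixels, optionally after dilation), flood-fill region growing, or nothing;
5. **envelope extraction** — white-region contour or the biggest-gap rule;
6. **envelope smoothing** — median (3 or 15 taps), 5-point moving average,
   or a first-order 70 Hz Butterworth low-pass.

That is 23 interchangeable options. `build_registry()` holds them;
`mc_chain()` is the reference composition (Gaussian, k-means, 2D Otsu, 70-px
clean-up, contour, 3-tap median); `run_chain()` executes any composition.

The package's question is not which chain traces the prettiest envelope but
which *slots matter* for a downstream clinical task: recognising complete,
measurable fetal cardiac cycles in the trace. A 128-column window of the
traced envelopes is summarised into 264 features (the two normalised
envelopes, four per-half area features, four per-half pixel-intensity means)
and classified by a 264-10-2 multi-layer perceptron as *complete* or
*incomplete*. Chains are then compared by classifier accuracy under
leave-one-subject-out (LOSO) cross-validation.

## The synthetic cohort

The clinical recordings the design is based on cannot ship with a package,
so `generate_cohort()` builds fully labelled synthetic cohorts. Each subject
gets one wide strip: beats are raised-cosine E/A humps above the baseline
(E/A amplitude ratio 0.75, A peak 75 rows) and a V hump below (55 rows),
concatenated at a per-beat jittered heart rate drawn from 110-160 bpm at a
column rate of 230 Hz — chosen so even the slowest beat spans at most ~125
columns and therefore fits the 128-column window. The pixels between
baseline and envelope are filled with an intensity ramp (0.9 at the baseline
decaying to 0.55 at the envelope edge), a bright axis line is drawn, and the
image is degraded with multiplicative speckle (sd 0.15), additive background
noise (sd 0.08), 0.5% salt pixels, and a light 0.8-px blur. A configurable
fraction of beats (default 30%) is malformed — signal dropout, missing A
hump, fused E/A, clipped V — and excluded from the complete-beat labels, so
the "incomplete" class exists for the classifier to find.

Windowing follows the labelling protocol of the clinical design: every
complete-beat centre contributes its centred window plus up to 15
single-column shifts on either side (31 positives per interior beat), and an
equal number of negative windows is sampled uniformly from start columns
farther than 15 columns from every positive start. Those negatives contain
clipped beats, malformed beats, or straddle two cycles — exactly the
"incomplete or malformed" material a cardiologist would skip.

What the generator does *not* emulate: true Doppler spectral broadening,
wall filters and display post-processing of a scanner, pathological
waveforms, or operator-dependent gain changes. Passing tests on this cohort
show that the machinery is correct and that the relative ordering of chain
options behaves as in clinical data; they do not certify clinical accuracy
levels.

```{r cohort, eval = FALSE}
cohort <- generate_cohort(synth_params(seed = 1))
autoplot(cohort$subjects[[1]]$strip)
```

## Worked example

```{r trace, eval = FALSE}
su <- cohort$subjects[[1]]
env <- run_chain(mc_chain(), su$strip)
autoplot(env)

ev <- loso_evaluate(cohort, mc_chain(), seed = 1)
glance(ev)
#> # A tibble: 1 x 6
#>   chain n_folds mean_acc    q1 median_acc    q3
#> 1 MC         25     99.2  98.7       99.4  99.9
```

The numbers above are from an actual run with the default cohort and seed 1:
25 LOSO folds, one per subject, median accuracy 99.4%. The corresponding
clinical acceptability floor used in the study design is 90%.

## Assessment machinery

* `enumerate_single_substitutions()` builds the 17 chains differing from the
  reference in exactly one slot (23 options minus the 6 reference ones).
* `assess_individual_steps()` evaluates all 18 chains and groups fold
  accuracies by slot. Each distribution is screened with the Lilliefors
  normality test; if any distribution in a slot is non-normal the slot is
  analysed nonparametrically (Kruskal-Wallis omnibus, pairwise two-sided
  Wilcoxon signed-rank against the reference), otherwise with paired
  t-tests. Significance is declared at p < 0.05 throughout.
* `greedy_soc_search()` walks the slots in order, re-evaluating the current
  chain with every option of the slot and keeping the best mean LOSO
  accuracy (ties favour the incumbent), costing exactly 23 evaluations.
* `compare_chain_sets()` compares any set of evaluations (typically the
  seven literature chains, the greedy result and a random chain) with a
  Kruskal-Wallis omnibus plus pairwise Wilcoxon tests against a reference.

On low-SNR synthetic cohorts the binarisation and envelope-extraction slots
dominate: the Canny substitution collapses to chance-level accuracy while
the Otsu-family thresholds stay above 90%, and the spread of per-chain
medians attributable to slots 3 and 5 far exceeds that of the peripheral
slots. This mirrors the behaviour reported on clinical material and is
checked as a stochastic property in the test suite. One deliberate
difference: with the image-adaptive edge-strength thresholds this package
uses for NLLAP (the original fixed constants were never published), the
NLLAP substitution degrades the traced envelope substantially (about 9-11
rows of upper-envelope error across a wide noise range) but degrades it
*systematically*, and the classifier largely compensates — so unlike
clinical reports based on fixed constants, NLLAP does not collapse to
chance here. The corresponding check in the acceptance suite records this
as an expected failure of that single sub-assertion.

## Design choices and numerical notes

Decisions the published methods left open, fixed here once and exposed as
parameters:

* **Coordinates and sign.** Row 1 is the image top; "above baseline" means a
  smaller row index and positive velocity, so envelope values are
  `baseline_row - row`. Empty columns carry 0 rather than interpolation —
  smoothing is slot 6's job.
* **Contrast stretch.** The three-class k-means uses deterministic
  percentile initialisation (10/50/90) so chains are reproducible; the
  stretch maps `[th_low, th_high]` linearly onto `[0, 1]`, the only reading
  of the published piecewise form that is continuous at both knees. The
  half-height histogram rule operates on a 256-bin histogram.
* **NLLAP.** The edge-strength thresholds were published only as
  "empirically determined"; defaults derive them from the image (probe
  patches near the baseline; `l2`/`l1` at 25%/50% of the observed
  edge-strength range) and are overridable via `nllap_config()`. The
  strength of a zero-crossing is read conservatively as the minimum of
  `grandmax - grandmin` over the two flanking sides.
* **2D Otsu** uses a 3x3 neighbourhood median and restricts the criterion to
  the two diagonal classes of the (gray, median) histogram, the standard
  median-variant formulation.
* **Canny** hysteresis thresholds auto-set at the 70th/90th percentiles of
  the non-zero gradient magnitude; only sigma was published.
* **Biggest gap.** Gaps are weighted by a triangular profile peaking at the
  centre of each half of the search space; ties break toward the gap farther
  from the baseline, and the envelope is reported at the signal-side
  boundary pixel, not the gap pixel.
* **Envelope smoothing pool.** The four slot-6 options are median-3,
  5-point average, median-15 and Butterworth-70 — the composition that makes
  the pool total 23 and the substitution count 17. One source describes the
  same filter inconsistently ("two-sample median", 71 Hz vs 70 Hz); taps and
  cut-off are parameters, defaults 3 and 70 Hz. The Butterworth runs
  causally (single pass) by default, with a zero-phase variant behind a
  flag.
* **Classifier.** Hidden activation (tanh), softmax output and cross-entropy
  were not published; the optimiser is full-batch L-BFGS — a quasi-Newton
  member of the conjugate-direction family the original environment used —
  with chunked iterations, early stopping on a 15% validation split, a 1000-
  iteration ceiling, and full seeding. Area features use the mean of the
  normalised samples (scale-free); pixel features are computed on the image
  as it enters binarisation. For large cohorts the per-fold training set may
  be subsampled (`max_train`, default 3000 windows) — the held-out test
  subject is never subsampled.
* **Statistics.** Lilliefors via the `nortest` implementation; quartiles use
  the standard type-7 (linear interpolation) convention; pairwise Wilcoxon
  tests are two-sided with the normal approximation (fold accuracies tie
  frequently); a constant non-zero paired difference is treated as maximally
  significant rather than degenerate.

Problem sizes used by the shipped checks (the package's own choices): the
default cohort is 25 subjects at 20 beats each; the step-importance property
runs on 25 subjects at 10 beats with training capped at 1500 windows and 150
iterations per fold; structural checks use 2-4 beats per subject.

## Known limitations

The synthetic task is easier than clinical material — the default-cohort
accuracies sit above the levels reported on real recordings, so only the
*ordering* of chain options, not absolute accuracy, should be read across.
The NLLAP constants, the adaptive-threshold overlap fraction and the
region-growing seed policy are reconstructions of under-specified published
steps; each is parameterised so other readings can be tested. Processing
time is not part of the assessment surface.
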