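---
title: "Multimodal gated-attention MIL for whole-slide outcome prediction: models and methods"
author: "milfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal gated-attention MIL: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milfuse)
```

## The problem

Treatment response after cytoreductive surgery and platinum-based
chemotherapy in advanced high-grade serous ovarian carcinoma is highly
heterogeneous: patients relapsing within six months of completing
chemotherapy (platinum-resistant) have a far worse prognosis than those
relapsing later (platinum-sensitive), and no routine biomarker predicts
which course a patient will take. Digitised H&E whole-slide images
(WSIs) encode morphology that correlates with both response and
progression-free survival (PFS), but a WSI is a gigapixel object with
only a single patient-level label — the canonical setting for weakly
supervised *multiple instance learning* (MIL), where a slide is a "bag"
of tile-level feature vectors and the label attaches to the bag.

`milfuse` implements a complete desk-scale version of this analysis:

1. **Tiling** — tissue segmentation on the HSV saturation channel and
   extraction of a filtered, non-overlapping 256-px tile grid;
2. **Encoding** — a pluggable encoder contract mapping preprocessed
   tiles to feature vectors (a deterministic synthetic encoder ships
   with the package; pretrained pathology foundation encoders plug into
   the same contract but no weights are shipped);
3. **Model** — dual surgery-routed gated-attention pooling over the tile
   features, gated fusion with encoded clinical covariates, and either a
   dual-output classification head or a single-output Cox risk head;
4. **Training** — slide-level optimisation with the combined
   bag/instance loss or the Cox partial likelihood, early stopping on a
   held-out metric, and patient-level aggregation only at evaluation;
5. **Evaluation** — ROC-AUC, Harrell's C, IPCW time-dependent AUC,
   Kaplan–Meier estimates, tertile risk stratification, chi-square and
   Kruskal–Wallis baseline tests, bootstrap model comparisons and
   multi-seed trial summaries;
6. **Synthetic cohorts** — a seeded generator producing feature bags
   with planted signal instances, clinical covariates with stated
   effects, Bernoulli response labels and censored exponential survival,
   with full ground truth for recovery testing.

## The model

For a slide with tile features $h_1,\dots,h_N$ ($h_i \in \mathbb R^D$),
the instances are first projected, $h_i' = \mathrm{ReLU}(W_p h_i + b_p)$.
A *gated attention* network — one per surgery route, primary (PDS) vs
interval (IDS) debulking, because post-chemotherapy morphology after
interval surgery differs systematically — scores each instance

$$a_i = w^\top\!\big(\tanh(V h_i') \odot \sigma(U h_i')\big) + b, \qquad
\alpha = \mathrm{softmax}(a),$$

and the slide embedding is the attention-weighted sum in the projected
space, $M_{WSI} = \sum_i \alpha_i h_i'$. Routing affects only the
attention parameters $(V, U, w, b)$; the projection, instance
classifier, fusion and heads are shared, so a PDS slide's gradient
never touches IDS attention weights (asserted by test).

Clinical covariates enter as a fixed-order encoded vector $C$
(z-scored continuous terms and one-hot categorical blocks). A
*gated fusion* computes a vector-valued gate from the concatenation,

$$g = \sigma\!\big(f_{gate}([M_{WSI}; C])\big), \qquad
M_{fused} = g \odot W_w M_{WSI} + (1 - g) \odot W_c C,$$

with $f_{gate}$ a single affine map into the fusion space. The convex
elementwise combination makes the endpoints testable: pinning
$g \equiv 1$ removes all dependence on $C$, and $g \equiv 0$ removes all
dependence on the image (both asserted by tests). The fused vector
feeds a dual-output softmax head (classification: class 1 =
treatment-sensitive) or an unsquashed single-output risk head
(survival).

### Losses

Classification uses the combined objective
$L_{total} = L_{bag} + \lambda\, L_{inst}$ with $\lambda = 0.9$:
$L_{bag}$ is the bag-level cross-entropy of the slide prediction, and
$L_{inst}$ is the CLAM-style instance clustering loss — instances are
ranked by attention, the top-$k$ receive the bag label as a
pseudo-label and the bottom-$k$ the complement ($k = 8$ per side,
shrunk to $\lfloor N/2\rfloor$ for small bags), and the mean
cross-entropy of a shared instance classifier over the $2k$ selected
instances is returned. The ranking is treated as fixed during
backpropagation (no gradient flows through the argsort), as in the CLAM
lineage. We use a single shared instance classifier (the "SB" variant)
rather than one per class; nothing in the architecture depends on that
choice and it halves the instance-branch parameters.

Survival training minimises the negative mean Cox partial
log-likelihood over a batch $B$,

$$L = -\frac{1}{B}\sum_{i=1}^{B} \delta_i\Big[\hat r_i -
\log\!\!\sum_{j:\,t_j \ge t_i}\!\! \exp(\hat r_j)\Big],$$

with risk sets formed within the batch and tied times included in each
other's risk sets (the Breslow convention that the $t_j \ge t_i$
condition literally implies; Efron weighting is out of scope). The
implementation is checked against a brute-force risk-set enumeration to
$10^{-9}$ on a thousand random batches, along with shift invariance in
the risks.

### Training procedure

Every slide is one optimisation example carrying its patient's label —
patient-level aggregation (mean or median of slide scores; the median
of an even count is the midpoint) is applied only when evaluating, so
training is never biased by per-patient slide counts. The two heads use
their own Adam hyperparameters: classification lr $5\times10^{-5}$,
weight decay $10^{-4}$, dropout 0.5; survival lr $2\times10^{-4}$,
weight decay $10^{-5}$, dropout 0.25 with a step scheduler. Both run at
most 50 epochs with early stopping (patience 5) on the patient-level
validation metric (AUC / Harrell C), with a floor of 10 epochs before
stopping is allowed so a lucky first epoch cannot freeze an untrained
model. Dropout (inverted scaling) is applied to the projected instances
feeding the attention networks and to the fused representation.
All randomness — initialisation (seeded uniform fan-in scaling),
shuffling, dropout masks — flows from one integer seed, and two runs
with the same seed are bit-identical.

**Cox batching.** The survival loss is a within-batch risk-set formula,
and we train it on minibatches of 16 slides by default (a full-cohort
option is available). One full-cohort Adam step per epoch at the
printed learning rate would allow at most ~50 optimiser steps in a
50-epoch budget — Adam's per-coordinate step is bounded by the learning
rate, so total parameter movement would be of order
$50 \times 2\times10^{-4} = 0.01$, far too small to leave the
initialisation. Minibatch risk sets trade a small bias in the partial
likelihood for two orders of magnitude more optimisation steps, which
is what the epoch/learning-rate budget requires; unpublished scheduler
constants default to a halving step every 10 epochs.

The multi-trial protocol (`runTrials()`) repeats training over seeds
0–9 and reports the mean metric with the normal-approximation 95% CI
($\bar x \pm 1.96\,s/\sqrt n$).

## WSI preprocessing

Tissue segmentation converts RGB to HSV and works on the saturation
channel: median filter (kernel 7), binarisation at the fixed threshold
8/255 (or Otsu on demand), morphological closing with a square $4\times
4$ structuring element, then artifact removal — white background
(saturation < 15 at brightness ≥ 200) and over-stained black regions
(mean RGB < 50) are zeroed. The white/black bounds are conventional
artifact thresholds exposed in `segParams()`; masks are computed at the
coarsest downsample whose longest side is ≤ 4096 px to bound memory.
The median filter, Otsu threshold and morphological closing are
delegated to EBImage.

Tiles are 256 × 256 px at level 0 with stride 256 (no overlap),
0-based half-open coordinates, enumerated row-major (y outer). A
candidate tile is kept by the *four-point rule*: the four probes at
$(c_x \pm s/4,\, c_y \pm s/4)$ around the tile centre are looked up in
the mask, and the tile survives if at least one (`four_pt_any`, the
permissive default) or all four (`four_pt_all`) lie in tissue. The rule
is configurable because "mostly inside tissue" admits either reading;
the default favours sensitivity at the tissue boundary. At the default
0.25 µm/px a tile covers 64 µm × 64 µm.

Kept tiles are resized to 224 px with separable bicubic interpolation
(Catmull–Rom kernel, $a=-0.5$, pixel-centre alignment, edge clamping),
scaled to $[0,1]$ and standardised per channel — in that order — with
the statistics of the encoder in use (ImageNet constants by default).
Catmull–Rom weights reproduce affine intensity ramps exactly away from
the clamped border, which the tests exploit as a closed-form oracle for
the resize step.

## The synthetic cohort generator

The generator defines the study conditions for every recovery test. Its
defaults emulate the cohort structure the method targets: 300 patients,
each with two primary-lesion slides and one metastatic slide, bags of
50–200 tiles in $D = 64$ dimensions, 38% of patients carrying a latent
high-risk (resistant-like) type, 35% PDS surgery, and ~30% independent
censoring.

* **Bags.** Background instances are standard normal; in the slides of
  high-risk patients a planted fraction $\pi = 0.2$ of instances
  (rounded to $\mathrm{round}(\pi N)$; $1.25\pi$ on the metastatic
  slide, mirroring the expectation that metastatic lesions carry more
  aggressive morphology) is shifted by $\mu = 2$ along a fixed seeded
  unit direction $u$. The "oracle score" — the projection of the mean
  bag feature onto $u$ — is the generator's own ceiling on image-based
  separability and is required to reach AUC ≥ 0.95 at the defaults.
* **Latent score and outcomes.** Each patient's latent score is
  $s = a f_{planted} + \gamma^\top (C - \mathbb E C) + \varepsilon$
  with $a = 25$, clinical effects $\gamma$ of realistic magnitude on a
  stage-like binary, a cytoreduction-like binary, a log-normal
  marker and a 3-level grading factor, and noise sd 0.4. The response
  label is $\mathrm{Bern}(\sigma(-3 (s - s_0)))$ (sensitive = low
  latent score; $s_0 = \mathbb E s$ so the null generator stays
  balanced), giving ~60% sensitive patients. Survival is exponential
  with hazard $\lambda_0 e^{\beta_s (s - s_0)}$, $\lambda_0 = 0.05$ per
  month and $\beta_s = 1$; censoring is an independent exponential
  whose rate is solved (by fixed Monte Carlo quadrature at the settings
  level) to hit the target censoring fraction. The constants were fixed
  once so that the generator meets its stated contracts — oracle AUC
  ≥ 0.95, prognostic latent score (C ≥ 0.75 on the truth), realized
  censoring within ±0.05 — while leaving label noise that no model can
  overcome, keeping the null and strong conditions honestly separated.
* **Reproducibility.** All draws flow through counter-based per-patient
  sub-seeds, so growing a cohort never perturbs earlier patients
  (asserted by test).

What the generator does *not* emulate: spatial correlation between
tiles, stain and scanner variation, batch effects, informative
censoring, or any real histologic texture (its "images" for the tiling
stage are saturated ellipses on white). Passing the recovery tests
therefore shows that the architecture, losses, optimisation and
evaluation machinery are correct and sensitive at realistic effect
sizes — not that the pipeline reaches any particular performance on
real slides.

With the hazard model above the simulated time scale is compressed
relative to clinical PFS (high-risk medians of a few months against
low-risk medians of years); the tertile ordering and rate contrasts are
the meaningful quantities, not the absolute month values.

## Evaluation statistics

* `rocAUC()` is the rank/trapezoid AUC (midranks = ties counted 1/2),
  exactly equal to the pairwise-probability definition; CIs by
  patient-level bootstrap.
* `harrellC()` counts all comparable pairs (shorter time must be an
  event; tied times with exactly one event are orderable), risk ties
  scoring 1/2; it matches an $O(n^2)$ enumeration exactly and
  `survival::concordance` on tie-free data.
* `timeDependentAUC()` is the IPCW cumulative/dynamic estimator at a
  horizon $\tau$: cases (events by $\tau$) weighted by $1/G(t^-)$,
  controls (at risk past $\tau$) by $1/G(\tau)$, with $G$ the censoring
  Kaplan–Meier curve; without censoring it collapses to the plain AUC
  of the event-by-$\tau$ indicator.
* `kmEstimate()` wraps `survival::survfit` (Greenwood variance,
  log-log CI); the median is the earliest time with
  $\hat S(t) \le 0.5$, its CI the same inversion of the confidence
  band, and "not reached" is reported as NA.
* `tertileStratify()` freezes the 1/3 and 2/3 training-score quantiles
  (linear interpolation, type 7 — the convention matters because group
  counts depend on it) with inclusive upper boundaries; frozen
  thresholds are applied unchanged to held-out scores.
* `chiSquareIndependence()` is the plain Pearson test without
  continuity correction; `kruskalWallis()` the tie-corrected rank test.
  Fisher's exact test is deliberately not offered: the package's single
  categorical test is the one whose values the baseline-table checks
  reproduce.
* `bootstrapCompare()` resamples patients with replacement, reporting
  the metric difference, its percentile CI, and the two-sided bootstrap
  p-value $2\min(P(\Delta^*\le 0), P(\Delta^*\ge 0))$, redrawing (at
  most 10%) resamples on which a metric is undefined.

## Numerical choices and degenerate inputs

* Probabilities are clamped at $10^{-12}$ inside cross-entropies (with
  a warning); the Cox loss uses the max-shift trick for the
  log-sum-exp; a batch without events contributes zero loss and no
  update.
* A singleton bag has $\alpha = 1$ exactly; empty bags are errors, an
  empty tissue mask yields an empty (not erroneous) tile grid.
* Softmax and sigmoid endpoints in the gate are strictly interior by
  construction; forcing the gate is available as a diagnostic mode only.
* Validation metrics that are undefined on a degenerate split (one
  class) count as "no improvement" rather than aborting training.
* The checkpoint sidecar stores an FNV-1a hash of the clinical schema
  so a model cannot be silently applied to reordered covariates.

## Problem sizes used by the test-suite

The recovery experiments run at the generator defaults (300 patients,
900 slides, $D = 64$) with attention/fusion widths 64/32 — widths are
architecture configuration, chosen so the full suite trains its dozen-plus
models in well under half an hour of single-CPU time while exercising
the identical code paths as the 256/256 defaults. Unit tests use smaller cohorts (10–40
patients, $D$ 8–16) generated on the fly; nothing is stored on disk.

## Known limitations

* No GPU path and no shipped pretrained encoder weights; real-WSI
  throughput is bounded by the pure-R forward/backward pass.
* Pyramidal slide formats are supported only through flat RGB images;
  a true OpenSlide-style backend would be needed for native WSIs.
* Only two surgery routes and binary response are supported.
* Minibatch Cox training uses within-batch risk sets; with very small
  batches the partial-likelihood gradient becomes noisy (the default of
  16 is a compromise, and `batch_scheme = full cohort` is available for
  inference-grade refits).
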