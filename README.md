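# milfuse

Multimodal gated-attention multiple instance learning (MIL) for
whole-slide histopathology, in R.

`milfuse` is for computational pathology and biostatistics groups who
want a fully testable, CPU-scale implementation of the
weakly-supervised pipeline used to predict **treatment response** (a
binary label, e.g. platinum-sensitive vs resistant ovarian carcinoma)
and **recurrence risk** (a continuous score trained against
progression-free survival) from whole-slide images (WSIs) fused with
clinical covariates. Everything from tissue segmentation to survival
statistics lives behind documented functions, and a seeded synthetic
cohort generator with known ground truth makes every stage verifiable
without access to clinical slide archives.

## The model

A slide is a *bag* of tile features $h_1,\dots,h_N$. Instances are
projected ($h_i' = \mathrm{ReLU}(W_p h_i)$) and pooled by **gated
attention** — one attention network per surgery route (PDS / IDS):

$$a_i = w^\top(\tanh(V h_i') \odot \sigma(U h_i')), \quad
\alpha = \mathrm{softmax}(a), \quad
M_{WSI} = \textstyle\sum_i \alpha_i h_i'.$$

Encoded clinical covariates $C$ are fused through a learned
vector-valued gate,

$$g = \sigma(f_{gate}([M_{WSI}; C])), \qquad
M_{fused} = g \odot W_w M_{WSI} + (1-g) \odot W_c C,$$

and $M_{fused}$ feeds either a dual-output softmax head trained with
$L_{total} = L_{bag} + 0.9\,L_{inst}$ (bag cross-entropy plus the
CLAM-style attention-guided instance clustering loss) or a single
risk head trained with the Cox partial likelihood
$L = -\frac1B\sum_i \delta_i[\hat r_i - \log\sum_{j:t_j\ge t_i}
e^{\hat r_j}]$. Slides are the training unit; patient-level predictions
are the mean or median of a patient's slide scores, taken only at
evaluation. The forward/backward passes are hand-written matrix algebra
(no deep-learning runtime), verified against finite differences.

Also included: HSV-saturation tissue segmentation with a four-point
tile-validity rule, bicubic tile preprocessing, a pluggable encoder
contract with a deterministic synthetic encoder, ROC-AUC / Harrell C /
IPCW time-dependent AUC / Kaplan–Meier / tertile risk stratification /
chi-square and Kruskal–Wallis baseline tests / bootstrap model
comparisons, and a `run`-everything pipeline plus a thin CLI
(`inst/cli/milfuse`).

## Worked example

```r
library(milfuse)

## 150-patient synthetic cohort: 2 primary + 1 metastatic slide each
cohort <- simulateCohort(simSettings(nPatients = 150, dim = 32,
                                     bagSizeRange = c(30, 60), seed = 1))
cohort <- splitCohort(cohort, seed = 1)
#> MILCohort: 150 patients, 450 slides (300 primary / 150 metastatic)
#>   split (patients): test=22, train=98, val=30

## platinum-response classifier (default printed hyperparameters)
cfg <- milConfig(32, 6, "classification", attentionHidden = 32,
                 fusionDim = 16)
fit <- trainModel(cohort, "classification", config = cfg, seed = 1)
evaluateCohort(fit, cohort, split = "test", nBoot = 500)
#> $auc        0.943        # held-out patient-level ROC-AUC
#> $aucCiLow   0.826        # 95% bootstrap CI
#> $aucCiHigh  1
#> $precision  0.789  $recall 1  $f1 0.882  $specificity 0.429

## recurrence-risk model and tertile stratification
cfgS <- milConfig(32, 6, "survival", attentionHidden = 32, fusionDim = 16)
fitS <- trainModel(cohort, "survival", config = cfgS, seed = 1)
evaluateCohort(fitS, cohort, split = "test")$cindex
#> [1] 0.838                # held-out Harrell C-index

thr <- tertileStratify(predictCohort(fitS, cohort, "train")$score)
held <- predictCohort(fitS, cohort, c("val", "test"))
grp <- assignRiskGroup(held$score, thr)
sapply(levels(grp), function(g)
  kmEstimate(held$time[grp == g], held$event[grp == g])$median)
#>          low intermediate         high
#>        84.26        32.26         0.46   # median PFS (months)
```

The classifier recovers the planted morphological signal (held-out AUC
0.94 against a generator oracle ceiling of ~0.95), the risk model
orders held-out survival (C = 0.84), and tertile thresholds frozen on
the training scores stratify held-out patients into clearly separated
Kaplan–Meier groups. On the null generator (no planted signal, no
clinical effect) the same pipeline stays at chance — see the test
suite.

The end-to-end pipeline is one call (or `inst/cli/milfuse run`):

```r
runPipeline(list(seed = 0, simulate = list(nPatients = 60),
                 heatmap = TRUE), "run_out/")
```

## Layout

```
R/                  implementation (tiling, encoding, model, losses,
                    training, evaluation, simulation, I/O, pipeline)
tests/testthat/     unit, property and acceptance suites
vignettes/          methods vignette (model, assumptions, choices)
scripts/acceptance.R  headline-quantity reproduction script
inst/cli/milfuse    command-line front end
```
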