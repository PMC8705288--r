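---
title: "Methods: sectional-plane volumetrics and survival-class prediction"
author: "ostvol authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sectional-plane volumetrics and survival-class prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ostvol)
```

# Overview

`ostvol` implements a three-class overall-survival (OST) prediction pipeline
for glioblastoma from segmented structural MRI. This vignette documents the
method, the assumptions behind it, the tunable parameters, the synthetic
data the package is validated on, and the numerical choices made where the
design was open.

# Survival classes

Survival in days is discretized as short-term (class 1, days 1–299),
mid-term (class 2, days 300–450) and long-term (class 3, day 451 up; the
generator caps at 1800 days, i.e. 60 months). The boundaries encode the
10- and 15-month cut-offs under a 30-day month: day 300 separates classes
1/2 and day 450 separates classes 2/3, so class 2 faces two decision
boundaries while classes 1 and 3 face one each (days 299 and 451). Day 450
belongs to mid-term: the long class begins strictly at 451. Censored
(alive) subjects carry no class and are excluded before binning; they are
never imputed.

```{r}
class_boundaries()
as.character(bin_survival_days(c(296, 300, 448, 450, 451, 453)))
```

# Volumetric features from sectional planes

Brain-lobe parcellation of MRI is not reliably automatable, so location
information is approximated by halving the brain with each of the three
anatomical sectional planes. For a volume of `N` voxels along the split
axis, the plane sits at `floor(N/2)`: the lower half covers indices
`1..floor(N/2)`, the upper half the rest, so for odd `N` the middle slice
belongs to the upper half. This single documented rule makes every
per-half count sum *exactly* to the whole-volume count — the conservation
invariant the test suite checks against brute-force voxel iteration.

Per half, five voxel counts are extracted — brain `Vb`, whole tumor `Vwt`,
enhancing tumor `Vet` (label 4), necrotic/non-enhancing core `Vncr`
(label 1), edema `Ved` (label 2) — plus whole-volume `Vb` and `Vwt`,
giving 12 features per approach in the fixed order
`lower_(Vb,Vwt,Vet,Vncr,Ved), upper_(...), whole_(Vb,Vwt)`. Because the
printed appendix order of the original feature tables is not available,
the schedule is explicit in the feature names and serialized into every
feature-table header, so any remapping is a one-line change. Counts are
raw voxels, not mm^3: BraTS volumes are resampled to uniform 1 mm spacing,
so counts are proportional to physical volume and the classifier z-scores
them anyway.

"Lower/upper" refer to array index order; their anatomical meaning
(left/right, anterior/posterior, superior/inferior) follows the volume's
`axis_roles`. When a file carries no usable orientation metadata the
default is the BraTS 240 x 240 x 155 layout: axis 1 sagittal, axis 2
coronal, axis 3 axial. The roles are data, never silently guessed from
image content.

## Brain extraction

`Vb` needs a brain/background separation. The intensity volume is
histogrammed into 256 equal-width bins over the observed range (all
voxels included — the exact-zero background of BraTS-style data forms its
own class), and the Otsu criterion selects the threshold maximizing the
between-class variance $\omega_0 \omega_1 (\mu_0 - \mu_1)^2$. Two
conventions are fixed and documented because the method leaves them open:
foreground voxels are *strictly greater* than the threshold, and exact
ties are broken toward the smallest threshold. A histogram with fewer than
two populated levels raises a named error rather than guessing.

Tumor-labeled voxels are unioned into the mask regardless of intensity:
necrotic cores can be darker than the global threshold, and excluding them
would break the containment `Vwt <= Vb` that the feature semantics assume.
Which modality to threshold is a configuration choice (the generator emits
one T1-like channel); nothing in the pipeline depends on it beyond the
mask.

## Clinical fusion

Age in years is appended directly as feature 13. Resection status is
encoded 1 for gross total resection (GTR) and 0 for both subtotal (STR)
and unknown, as feature 14 — the published encoding, which deliberately
collapses STR with missing. Roughly half of real cohorts have unknown
status, so the feature is weakly informative; the generator reproduces
that by drawing GTR with the per-class rates of the study cross-tabulation
(35/81, 27/55, 39/76) and leaving the rest unknown.

# The classifier

A single-hidden-layer network: tanh hidden layer, softmax output,
mean cross-entropy loss. The published description fixes exactly this
architecture and the hidden-size grid {40, 50, 100, 150, 200}, but no
optimizer, loss weighting, epochs, initialization or preprocessing; those
are declared configuration here, not inferred facts:

- **Optimizer**: full-batch gradient descent, fixed learning rate
  (default 0.05), default 500 epochs. The simplest deterministic choice;
  at n of a few hundred samples and at most 14 features, full-batch is
  also the fastest.
- **Initialization**: uniform on (-1, 1) scaled by 1/sqrt(fan-in), from a
  seeded RNG. Training is bit-reproducible under a fixed seed.
- **Standardization**: features are z-scored with training-set statistics
  stored in the model. Voxel counts are ~1e4–1e6 while age is ~1e1;
  without scaling, gradient descent on this mix is numerically degenerate.
  Constant features get unit scale. Predictions are invariant to any
  positive per-feature rescaling applied consistently at fit and predict
  time (property-tested).
- **Regularization**: L2 penalty on the weight matrices (not biases),
  default 1e-4, switchable off. With ~212 samples and 14 features the
  model is modest, but cross-validation alone does not regularize the
  final fit.
- **Early stopping**: optional, on validation loss with patience 50,
  restoring the best weights.
- **Prediction**: argmax of the softmax; exact ties break toward the
  lower class index (short before mid before long), a deterministic rule
  exercised in tests.

The analytic backprop gradient is the module's central oracle: the test
suite checks every component against central finite differences at
relative error below 1e-6.

The five comparison classifier families (SVM, k-NN, naive Bayes, linear
discriminant, decision trees) are exposed through a uniform fit/predict
adapter delegating to `e1071`, `MASS` and `rpart`; they are comparators,
not contributions, so they are deliberately not reimplemented.

# Evaluation protocol

The data are split stratified train/validation/test. The original split is
unstated; the default fractions 0.70/0.15/0.15 are a design choice exposed
as configuration, and on 212 subjects they give 148/32/32 — sizes under
which the published overall-accuracy row arithmetic (99 + 21 + 18 correct
= 138/212 = 65.1%) is self-consistent. That consistency motivates the
default but remains an inference about the original protocol, not a fact.

Subset totals are rounded by largest remainder; the per-class allocation
rounds the class-by-subset quota matrix to those row and column totals, so
every class is within one sample of its target proportion in every subset.
"Overall accuracy" is implemented as pooled correct/total across the three
subsets — equivalently the subset-size-weighted mean of subset accuracies,
an identity the tests verify on random partitions.

Hidden-size selection uses k-fold cross-validation (default k = 5) on the
training subset only, refitting the final model on the full training
subset with early stopping against the validation subset; both the CV fold
accuracies and the held-out validation accuracy are reported and labelled,
since the original text is ambiguous about which one its validation column
means.

Per-class ROC curves are one-vs-rest threshold sweeps over the class's
softmax score; AUC is the trapezoidal integral, which equals the
probability that a random positive outscores a random negative with ties
counted one half — the pairwise oracle the tests compare against.

# The synthetic cohort

The real survival cohort is access-gated, so the package generates one
with the same shape and a *stated* generative link between imaging and
outcome:

- **Geometry and topology.** Brain = an axis-aligned ellipsoid of bright
  intensity (100 ± 8) on exact-zero background, semi-axes ~0.45 of each
  dimension with ±8% jitter; tumor = three concentric ellipsoids scaled
  0.45/0.75/1.00, rasterized as NCR/NET core inside an ET shell inside an
  ED envelope, all clipped to the brain. The necrotic core is rendered
  dark (30 ± 5) to exercise the label-union rule in brain extraction. In
  brain-normalized coordinates the tumor is a ball, so the exact placement
  constraint is ‖center offset / brain semi-axes‖ ≤ 1 − s with
  s = fraction^(1/3); centers are sampled by rejection inside that ball,
  with a laterality parameter controlling the sagittal side (default 0.5,
  a nuisance covariate by design).
- **Composition.** Default 81/55/76 short/mid/long (212 subjects), with
  optional additional censored subjects (the study cohort had one alive
  patient). Survival days are uniform within each class interval
  (short [30, 299], mid [300, 450], long [451, 1800]; the 1800-day cap is
  the 60-month ceiling reported for long-term survivors).
- **Effect sizes.** No quantitative volume–survival effect size is
  published, so the defaults are the package's own: whole-tumor fraction
  ranges 0.10–0.18 / 0.05–0.10 / 0.01–0.05 of brain volume for
  short/mid/long (non-overlapping, monotone decreasing — the premise that
  tumor burden predicts survival, made recoverable), and mean ages
  65/58/52 years (SD 8, clamped to 18–90), encoding the younger-patients-
  survive-longer association. These are config parameters emulating a
  plausible signal, not claims about biology.
- **Ground truth.** Every subject records its true class, ellipsoid
  geometry, and all per-half subregion counts measured directly off the
  emitted grids, so feature extraction can be tested for exact recovery.

What the generator does **not** emulate: MRI texture, noise, bias fields,
multi-focal or irregular tumor shapes, the four separate modalities (one
intensity channel suffices since only the labels and one Otsu channel are
consumed), or realistic class overlap. Consequently, passing end-to-end
tests shows the pipeline is correct and the classes are recoverable when a
signal exists — it says nothing about accuracy on clinical data, where the
published models reach only ~53–65%.

# Problem sizes and runtimes

Tests and examples run the full 212-subject composition at the `tiny`
40 x 40 x 30 geometry preset (≈18,000 brain voxels), where a complete
simulate–extract–train–evaluate cycle takes well under a minute; the
full-pipeline property (mean test accuracy above the 0.384 majority-class
rate for all three planes) is checked over 5 master seeds. Full
240 x 240 x 155 geometry is supported by the same code paths (one ~9M-voxel
double array per modality) and is exercised in the examples only through
the shape-handling unit tests, to keep the default suite fast.

# Known limitations

- The feature order of the original appendix tables could not be
  confirmed; the named schedule makes any discrepancy a remap, not a bug.
- The reported month-histogram binning of the original figure is
  internally inconsistent (453 days appearing as 16 months); the package
  uses the 30-day convention throughout and does not reproduce that
  figure.
- Censoring-aware modelling and continuous survival regression are out of
  scope; censored subjects are simply excluded, matching the study.
- Accuracy on the synthetic cohort is far above the published clinical
  figures by construction; the acceptance machinery therefore targets the
  structural quantities (class boundaries, feature counts, conservation,
  arithmetic identities), never the printed accuracies.
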