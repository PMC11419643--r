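---
title: "Methods: the strokerisk pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the strokerisk pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokerisk)
```

## Overview

`strokerisk` implements a complete tabular stroke-risk modelling chain for
cohorts in the Kaggle stroke-prediction CSV dialect: cluster-based
imputation, ICA feature reduction, a correlation pre-filter followed by a
metaheuristic wrapper selector, trapezoidal fuzzy comorbidity coding, a
bidirectional LSTM classifier trained from first principles, a
confusion-matrix metric suite, and salted elliptic-curve ElGamal encryption
of the predicted records. One fitting function, `strokerisk()`, orchestrates
the stages and returns a classed model object with the usual `print`,
`summary`, `predict`, `coef`, `residuals` and `plot` methods.

This vignette records the model assumptions, the tunable parameters and the
design decisions that were genuinely open, so the package can be audited
without reading the sources.

## The input schema

The dialect has the fixed, case-sensitive 12-column header
`id,gender,age,...,smoking_status,stroke`. We count **11 input attributes**
besides the `stroke` target, following the dataset's own attribute list;
`id` is one of them but is an identifier, never a modelling predictor, so
models are built on the remaining 10 predictors. Some published descriptions
of this dataset name attributes (chest discomfort, blood pressure) that the
actual dialect does not carry; the package follows the dialect and documents
the discrepancy rather than resolving it.

Missing values: the literal `N/A` and empty cells are masked on read.
Categorical levels are encoded as integers in alphabetical level order, and
the codebook is stored with the table so encoding round-trips exactly.

## Synthetic cohorts

`generate_cohort()` emulates the dialect's statistical structure: ~5,000
records by default (5,110, the size of the real cohort), mixed
numeric/categorical predictors, a two-component glucose mixture
(normoglycemic mean 92 mg/dL, diabetic mean 175 mg/dL, sd 20), MCAR
missingness confined to `bmi` and `smoking_status` (default 4%, mirroring
which columns are incomplete in the real data), and a stroke label drawn
from a logistic model on age, hypertension, heart disease, glucose and BMI.
The intercept is solved numerically so the marginal prevalence matches the
requested value (default 5%).

The default log-odds effects (age 0.08/year, hypertension 1.2, heart
disease 1.0, glucose 0.02 per mg/dL, BMI 0.03) give a realistic,
moderately predictable cohort: a plain logistic oracle reaches AUC > 0.85
at n = 2000.

`preset = "separable"` defines a second, deliberately easy regime used to
demonstrate end-to-end signal recovery: balanced classes (prevalence 0.4),
a diabetic fraction matched to the prevalence, and a steep glucose effect
(0.3 per mg/dL) that makes the outcome essentially cluster-structured along
the bimodal glucose axis. This is the regime in which the pipeline is
expected to reach near-oracle accuracy; it does **not** emulate the class
imbalance, label noise or confounding of real clinical data, so passing
tests in this regime demonstrate mechanism recovery, not clinical
performance.

## Missing-data handling: hybrid k-means + GA (HKGA)

Plain Lloyd k-means can return empty clusters from unlucky initial centers.
The hybrid scheme runs Lloyd first (with the standard partial-distance rule
on masked cells: squared distance over observed coordinates rescaled by
`d/|observed|`), then evolves assignment chromosomes with a genetic
algorithm whose objective is the within-cluster sum of euclidean distances.
Selection is roulette-wheel on shifted goodness; because the objective is
minimized while the printed selection rule rewards larger values, selection
operates on the negated objective (all-equal goodness degenerates to 0/0
and is defined as uniform). Crossover is per-gene uniform; mutation
resamples two random gene positions; one elite individual is kept, so the
best objective never worsens. Degenerate chromosomes are repaired by giving
every empty cluster the farthest member of the largest cluster.

GA defaults (population 30, 50 generations, crossover 0.8, mutation 0.1,
elitism 1, k = 4) are conventional values; none are critical, and all are
configurable. Imputation fills a masked cell with its record's cluster mean
for that attribute (falling back to the global attribute mean when a
cluster never observed the attribute); a `drop` mode removes incomplete
records instead. Imputation is the pipeline default because it preserves
sample size.

## ICA reduction

After standardization the predictors are centered, whitened by
eigendecomposition (directions with negligible eigenvalues are dropped),
and unmixed by a fixed-point iteration with the tanh contrast and symmetric
orthogonalization (tolerance 1e-4, at most 200 iterations; non-convergence
returns the best iterate with a warning — on data whose sources are mostly
Gaussian this is expected, since such components are not identifiable).

Components are filtered by **mean absolute activation > 0.1**. Component
activations are zero-mean by construction, so a filter on the raw average
would discard everything; the absolute mean is the magnitude the threshold
can meaningfully act on. On standardized data activations have roughly unit
scale, so this filter is permissive — it exists to drop degenerate
components, and the real selection pressure comes from the wrapper stage.
Each retained component is mapped back to the original attribute with the
largest absolute unmixing loading, because the next stage operates on
attribute indices.

## Candidate filter and the UD-GSRBEHO wrapper

For each feature a pooled two-sample T statistic across the stroke classes
is computed, and summarized by the Spearman-style transform
`1 - 6*tau^2/(l(l^2-1))` over the `l` features (in the degenerate case of an
infinite statistic the summary is 0). Features with a non-zero summary are
unioned with the ICA-derived attributes to form the candidate set — in
practice a permissive filter; an `adjacent` mode comparing consecutive
feature columns is retained as a fidelity variant.

The wrapper encodes feature subsets as continuous positions in `[0,1]^d`
thresholded at 0.5 and searches with elephant herding optimization
hybridized with a gradient search rule:

* **Clan updating**: each non-matriarch elephant moves toward its clan's
  fittest member by `omega * (matriarch - x) * gamma`, `gamma ~ U(0,1)`;
  the matriarch moves to `delta * clan_center`. (A printed variant defining
  `gamma` as a reciprocal position difference contradicts its own
  description as a uniform draw and is not used.)
* **Clan separating**: each clan's worst member is replaced by
  `lower + (upper - lower + 1) * rand`, clamped.
* **GSR/DM step**: a Newton-inspired displacement built from the best and
  worst positions, a random step length, and an exploitation pull toward
  the best position; three candidate vectors X1/X2/X3 are blended with two
  uniform weights. The schedule `beta = 0.2 + (1.2 - 0.2)(1 - (m/M)^3)^2`
  decays from 1.2 to exactly 0.2 at the final iteration and drives the
  step-size coefficient `alpha`.
* **Local escape operator**: with probability `pr = 0.5` a jump mixing the
  best position, a random population member or a fresh uniform point, and
  the X1/X2 difference.

Elitist bookkeeping keeps the best-so-far per clan and globally, so the
reported best fitness is monotone. Defaults: 5 clans of 10 elephants,
`omega = 0.5`, `delta = 0.1`, 100 iterations at module level (the pipeline
caps it at 30, which is where the fitness curve flattens on cohorts of a
few thousand records).

Subset fitness is the **Rand index** between seeded k-means on the selected
columns (k = number of label classes) and the labels. Using the labels
(rather than an unsupervised reference) makes the wrapper supervised; this
is the reading under which "cluster analysis" yields a usable fitness. The
empty subset scores 0.

## Fuzzy comorbidity coding

Records are coded on a six-point comorbidity scale from two crisp classes —
diabetes (`avg_glucose_level` above a 125 mg/dL cut) and heart disease (the
schema column):

| dia | hea | comparison | code |
|----|----|-------------------------------|---|
| 0 | 0 | — | 1 |
| 1 | 0 | glucose above diabetic mean `xx` | 2 |
| 1 | 0 | glucose between normal mean and `xx` | 3 |
| 1 | 1 | — | 4 |
| 0 | 1 | heart proxy above `w` | 5 |
| 0 | 1 | heart proxy below `w` | 6 |

The printed rules cover five of the six announced codes and never assign
code 4; the combined-risk cell `dia = 1 & hea = 1` is the only unhandled
combination, so code 4 is assigned there. The schema has no continuous
cardiac marker, so age — the dominant cardiac risk proxy available — is the
comparison variable for codes 5/6, with `w` its mean among heart-disease
records; `xx` is the mean glucose among diabetic-class records. All
thresholds are overridable in the configuration (the `fuzzy:` block) so the
cut-points are auditable.

Fuzzification uses a trapezoidal membership on the relevant axis (right
plateaus extend beyond the physiological range so extreme values never
decay back toward a milder code). Defuzzification is an activation-weighted
centroid of codes: the membership grades the hard code against its milder
neighbour, so the crisp value slides continuously between adjacent codes
and always stays in `[1, 6]`. Codes 1 and 4 are crisp cells.

## The adaptive-weight Bi-LSTM

Each record becomes a short sequence: one standardized selected feature per
time step, in selection order, with the standardized crisp fuzzy value
appended as a final step (a `replace` mode feeds the crisp value alone; a
single-step vector mode is available by passing a 3-d input array). Both
directions run a standard LSTM cell (sigmoid gates, tanh candidate); the
readout concatenates the two final hidden states, applies a linear map and
a softmax.

Training follows a three-branch mutation-selection scheme per minibatch:
snapshot the weights; spawn one branch per loss (mean square, mean
absolute, Huber with `delta = 1`, all applied between the softmax output
and the one-hot target — a classification adaptation of regression-style
losses); perturb each branch with Gaussian noise whose per-input-column
scale is proportional to that feature's mean absolute value (scale 0.01);
apply one full backpropagation-through-time gradient step under the
branch's loss; adopt the branch with the smallest batch loss. The outer
loop is a conventional epoch/minibatch structure (the source pseudocode's
loop bound is not interpretable as printed, so the reconstruction is the
conventional one). Gradient correctness is enforced by a finite-difference
test at relative error < 1e-4.

Defaults: hidden size 16 per direction, batch 64, 30 epochs, learning rate
0.5, plain gradient descent. The learning rate is higher than typical
cross-entropy practice because the square-loss-through-softmax gradient is
small near uniform outputs; 0.5 with 30 epochs reaches the capacity
plateau on separable cohorts of a few thousand records. Ties in the argmax
prediction break to the lowest class index.

## Metrics

One-vs-rest confusion counts feed precision, recall/sensitivity,
specificity, F-measure, accuracy, NPV and MCC; multi-class reports
macro-average by default with a micro mode. Two printed formulas in the
source material are internally inconsistent (an NPV numerator of TP and an
MCC denominator term `(TP+TN)`); the standard forms `TN/(TN+FN)` and
`sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` are implemented, and the deviations
are noted where the functions are documented. Metrics with a 0/0
denominator are reported as 0 and flagged `undefined` rather than raising.

## Secure storage

Predicted records are encrypted under EC-ElGamal over a prime-field
Weierstrass curve, with a third, salted key: `S_k = MD5(encode(A) || salt)`
(public key encoded x‖y big-endian; MD5 consumed from the standard digest
implementation, not re-implemented). Because a hash cannot be "added" to a
curve point directly, `S_k` is mapped to the scalar `s_k = int(S_k) mod n`
and enters the scheme as the point `s_k·B` added to both ciphertext
components; decryption applies the algebraically consistent inverse
`M = (E2 - S_kP) - K(E1 - S_kP)` (the printed decryption formula does not
invert the printed encryption and was repaired to this form). Setting
`s_k = 0` recovers textbook EC-ElGamal, which is cross-checked in the
tests.

Messages are embedded by Koblitz's method (window 64, 2-byte blocks, a
2-byte length prefix providing an integrity check). Two curves ship with
the package: a toy curve over F_17 (order 19) small enough for exhaustive
group-law verification, and the operational default `y^2 = x^3 + x` over
F_16777199 — chosen supersingular (order p+1, so no point counting is
needed) with p below 2^26 so that every modular product stays exact in
double-precision arithmetic. This is a didactic, desk-verifiable
instantiation of the scheme, not a production key size; any prime-field
curve below that bound can be supplied in the `security:` block.

## Problem sizes, tolerances, degenerate inputs

* Whitening declares identity covariance at 1e-6; ICA converges at 1e-4 on
  the unmixing update.
* The wrapper's mask threshold is 0.5; an empty decoded mask falls back to
  the strongest single coordinate.
* k-means inside the fitness uses 3 restarts and 20 iterations — enough
  for the small candidate subspaces it scores.
* Test and demonstration runs use cohorts of 150–2,000 records, wrapper
  budgets of 3–30 iterations and 3–30 training epochs; these sizes put
  every stage's behaviour (including the end-to-end separable-recovery
  run) within a few minutes on one CPU while leaving the conclusions
  unchanged at larger sizes.
* Degenerate inputs are defined, not fatal: constant columns are dropped by
  rank reduction, all-equal GA goodness selects uniformly, all-zero fuzzy
  activations return the hard code, 0/0 metrics are flagged, and a
  clustering with an empty cluster is repaired before use.

## Known limitations

* The correlation pre-filter is permissive by construction; feature
  economy comes from the wrapper, whose Rand-index fitness favours
  cluster-aligned signal and may under-select features whose effect is
  real but not cluster-structured (e.g. weak additive effects on a
  balanced binary column).
* The Bi-LSTM consumes tabular records as artificial sequences; the
  sequence order is the selection order, which is reproducible but
  arbitrary. The vector mode avoids this at the cost of departing from the
  sequence formulation.
* MD5 is retained for fidelity with the scheme's definition; it is not a
  collision-resistant choice today, and the curve sizes here are
  illustrative. Neither should be used for actual patient data.
* Fuzzy thresholds derived from cohort aggregates shift with the cohort;
  fixed clinical cut-points can be supplied instead.
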