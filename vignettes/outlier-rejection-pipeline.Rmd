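---
title: "Two-phase outlier rejection and ensemble diagnosis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-phase outlier rejection and ensemble diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortecm)
```

## The problem

Tabular clinical datasets — the motivating case is fine-needle-aspirate
cytology scores for breast tumours, nine integer features on a 1–10 scale
with benign/malignant labels — contain a minority of anomalous training
instances: transcription errors, mislabeled cases, biologically atypical
samples. Such instances drag a classifier's decision boundary toward
themselves and cost accuracy on ordinary patients. This package implements
a training-set cleaning pipeline (min–max normalization, information-gain
feature ranking, two-phase outlier rejection) in front of a majority-vote
ensemble classifier, with stratified cross-validation as the evaluation
protocol.

## Quick rejection phase

For each class the per-feature mean $\mu_{cl}$ and *sample* standard
deviation $\sigma_{cl}$ (denominator $d-1$) are fitted. An instance's
score is the mean over features of its standardized absolute deviation
from its own class profile,
$$\mathrm{SD}(I, cl) = \frac{1}{b}\sum_{j=1}^b
  \frac{|I(f_j) - \mu_{cl}(f_j)|}{\sigma_{cl}(f_j)},$$
and the global threshold is $trd = \sum_{cl} trd_{cl}$ with $trd_{cl}$
the mean score inside class $cl$. Scores strictly above $trd$ reject the
instance; ties are kept.

Design notes, in order of consequence:

* **Scalarization.** The deviation is a per-feature vector while the
  threshold is a scalar; we aggregate by the mean over features, which
  keeps scores comparable across feature counts and matches the
  "average deviation" reading of the threshold.
* **Standardized vs literal threshold.** The threshold's natural form is
  a raw mean absolute deviation, which is dimensionally inconsistent with
  a σ-standardized score. The default mode standardizes both sides;
  `threshold_mode = "literal"` reproduces the raw form. Under the
  standardized default the minimum score in every class is provably below
  the threshold, so whole-class rejection cannot occur; in literal mode
  it can, and a guard then retains the class's least deviant instance
  with a warning.
* **Variance floor.** σ components below `sd_epsilon` (default `1e-8`)
  are floored so constant features and singleton classes stay finite.
* The summed threshold grows with the number of classes; with the
  two-class data this package targets that is immaterial, but it makes
  the filter increasingly permissive on many-class problems.

## Accurate rejection phase: binary Harris hawks optimization

Survivors of the quick phase become candidates for subset search: one bit
per instance, 1 = keep. The optimizer mimics a hawk flock converging on
prey (the incumbent best solution). Per hawk and iteration the prey's
escape energy $G = 2 G_0 (1 - J/J_{max})$, $G_0 \sim U(-1,1)$, dispatches
the update: exploration while $|G| \ge 1$, then soft or hard "sieges"
depending on $|G| \gtrless 0.5$ and an escape draw $e \sim U(0,1)$, the
escaped-prey variants adding heavy-tailed Levy-flight dives
(Mantegna construction, stability exponent $\beta = 1.5$, scale
$\sigma(\beta) \approx 0.6966$). Each continuous update is clipped to
`[lb, ub]` (default $[-4, 4]$, spanning sigmoid activations of roughly
0.018–0.982) and immediately re-binarized through
$S(x) = 1/(1+e^{-x})$: bit $j$ is set where a fresh uniform draw falls
below $S(x_j)$. **Positions are therefore binary**, and the continuous
rule is only the intermediate step — this follows the procedure's own
per-update "binarize the new position" step and the published binary
variants of the algorithm. We measured the alternative (continuous
positions with binary views sampled at evaluation time) and found it
concentrates evaluations near the incumbent: on structureless random
fitness tables of dimension 10 it attains the exhaustive optimum in 62.5%
of 40 seeds versus 95–100% for the binary-position scheme at dimensions
≤ 9 (pop 10, 200 iterations). A coverage argument sets expectations here:
at ~2,500 evaluations even an ideal uniform sampler finds the optimum of
a random 1024-entry table only ~91% of the time, so oracle-equivalence
checks are run at dimension 8, where the property holds with margin.

The prey is updated after every evaluation (elitism), so the
best-fitness trace is non-increasing and the returned solution is never
worse than any seeded candidate. The all-ones mask is seeded into the
initial population: the accurate phase can only improve on "reject
nothing".

## The subset fitness

A mask $R$ over $N$ candidates is scored
$$F(R) = \alpha\, \gamma_R(D) + \delta\, \frac{N - |R|}{N},
  \qquad \alpha = 0.99,\ \delta = 1 - \alpha,$$
minimized. $\gamma_R(D)$ is the error, over **all** candidates, of the
k-nearest-neighbour classifier induced by the kept set (Euclidean
distance, $k = 5$, an instance's own copy excluded when kept); for
$R = N$ this is exactly the leave-one-out error of the candidate set.
Masks with $|R| < k+1$ or with a class absent are invalid and score
$\infty$. Two design choices deserve emphasis:

* **Evaluation over all candidates.** Scoring only the kept instances
  lets a mask erase an instance's error term by discarding the instance,
  which cascades into wholesale boundary erosion (we measured mean clean
  retention of 0.75–0.80 on overlapping synthetic data). Scoring all
  candidates means rejection pays only when the removed instance was
  corrupting its *neighbours'* classification — the operational
  difference between an outlier and a merely hard point.
* **Penalty direction.** The size term is transplanted from wrapper
  feature selection, where small subsets are desirable; copied verbatim
  ($\delta |R|/N$) it turns the search into prototype condensation and,
  on separable data, collapses the kept set to about $k+1$ instances.
  The default penalizes the *rejected* fraction instead, so among
  equally consistent subsets the largest wins. The transliterated form
  remains available (`subset_penalty = "kept_fraction"`) for comparison.

Even with both choices, $\alpha = 0.99$ makes any reduction in
$\gamma_R(D)$ worth up to 99 times the retention penalty. On overlapping
classes the optimizer therefore behaves like a k-NN editing algorithm:
beyond planted outliers it removes boundary instances whose absence flips
their neighbours' (and eventually their own) induced predictions. On
near-separable data the all-ones mask is optimal and everything is
retained. Users who want rejection limited to gross anomalies can raise
$\delta$ or rely on the quick phase alone.

## Upstream stages

* **Normalization.** Min–max statistics are fitted on training folds only
  and applied to test folds (values clipped to $[0,1]$; constant features
  map to 0). Normalizing the pooled dataset before splitting would leak
  test-fold ranges into training; fold-safe fitting is the defensible
  protocol.
* **Information gain.** Shannon entropy, base 2. Integer features taking
  at most `bins` distinct values are treated as discrete (the natural
  treatment of 10-point cytology scales); continuous features are
  discretized into `bins = 10` equal-width bins over their observed
  range. No selection cutoff is prescribed upstream, so the default
  policy keeps features with gain strictly above the mean gain (falling
  back to all features when gains are flat, so the selection is never
  empty), with `top_k` as the alternative; the choice is echoed in every
  report.

## Ensemble and evaluation

Gaussian naive Bayes, k-NN ($k=5$, Euclidean) and an RBF-kernel SVM
(cost 1) are trained on the cleaned fold; the modal label of the three
votes is the diagnosis (no tie is possible with three voters over two
classes; a `tie_order` resolves more general configurations). k-NN
prediction is implemented from distance matrices with deterministic
tie-breaking — distance ties to the lowest index, vote ties by
`tie_order` — because the reference implementations break ties randomly,
which would violate the package's bit-reproducibility guarantees; the
reference `class::knn.cv` serves as an independent oracle in the test
suite on tie-free data. Malignant is the positive class. Metrics are the
standard confusion-matrix set; percentages are truncated, not rounded, to
three decimals, matching the convention of the published comparison
tables (e.g. precision 98.4 and recall 98 give F1 98.199). Zero
denominators define the affected metric as 0 with a warning.

Cross-validation is stratified (class counts per fold within one
instance), seeded, and runs the entire pipeline inside each fold with no
test-fold leakage. Per-fold seeds derive from the configured seed plus
the fold index.

## What the synthetic generator emulates — and what it does not

`generate_synthetic()` draws two Gaussian classes whose mean vectors are
`class_separation` apart (defaults: 9 features, within-class SD 1,
separation 4 — about 2.3% Bayes overlap, comparable to the few-percent
error rates reported for k-NN on real cytology tables), clips values to
the 1–10 range, optionally rounds to integers, and perturbs a fraction
`outlier_rate` of instances: `mean_shift` places them $4.5\sigma$ from
their class mean (the placement guarantee refers to the continuous
positions, before optional integer rounding), `label_flip` inverts
labels, `uniform_noise` redraws features. It does *not* model the
correlation structure, skewness or class imbalance of real cytology
data, so passing recovery tests demonstrates correct mechanics — the
filter removes what it is designed to remove under known truth — not
clinical performance. Problem sizes used in the shipped checks (n = 120
recovery runs over 20 seeds, dimension-8 oracle comparisons over 40
seeds, 200-instance cross-validations) were chosen to exercise every
phase at full fidelity while keeping a complete run in the low minutes.

## Numerical and degenerate-input choices

* All randomness flows through explicit seeds (`withr::with_seed`); no
  global RNG state leaks. Identical inputs and seed give bit-identical
  results, including the optimizer trace.
* σ floor `1e-8`; strict inequality at the rejection threshold (ties
  kept); invalid optimizer masks score $\infty$ rather than raising.
* Files with every row incomplete, single-class training tables,
  classes smaller than the fold count, and feature-count mismatches all
  fail fast with named errors.
* WBCD-dialect rows must have exactly 11 fields; the row and offending
  value are named in parse errors. Rows with missing values are dropped,
  never imputed, with counts logged and recorded as attributes.

## Known limitations

* The rejection threshold sums per-class contributions, so the quick
  phase weakens as the number of classes grows.
* On heavily overlapping classes the accurate phase edits boundary
  regions beyond planted anomalies (see the fitness discussion); clean-
  data retention around 75–80% at 2.3% Bayes overlap is expected
  behaviour of the objective, not an optimizer failure.
* The ensemble's base-learner hyperparameters are deliberately plain
  (defaults echoed in every report); no tuning layer is provided.
* Binary classification is assumed throughout the metrics; multi-class
  tables pass through the cleaning stages but the confusion matrix is
  one-vs-rest on the positive class.
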