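---
title: "Behavioral screening of student mental-health risk: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioral screening of student mental-health risk: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The screening problem

Boarding schools hold routine digital traces of every student: canteen
payment events, internet-session logs, course grades. The premise of this
package is that elevated mental-disorder (MD) risk leaves a multimodal
footprint in those traces — irregular meal timing, late-night internet
activity, declining grades, frequent insomnia nights — and that a
screening model over these channels can flag students for follow-up by
counselors. The positive class is "any concern level" (mild, moderate or
severe collapsed to a binary indicator), because the operational question
is *who should be seen*, and the quantity that matters most is MD-class
recall: the fraction of at-risk students the screen actually flags.

No real cohort ships with the package. Every empirical statement in the
tests and in `scripts/acceptance.R` is computed on the bundled synthetic
cohort generator, so all results are statements about the pipeline's
behavior under controlled, planted signal — not about real adolescents
(see *What the simulator does and does not emulate*).

## Engineered features

For each student the pipeline produces a fixed six-column feature vector.

**Grades.** A course score $s \in [0, 100]$ maps to the grade point
$F = (s - 50)/10$; the per-course quality is $Q = \mathrm{credit} \times F$
and the aggregate is $F_{avg} = \sum_i Q_i \big/ \sum_i \mathrm{Score}_i$.
The score-sum denominator is unconventional (credit-weighted GPA divides by
$\sum_i \mathrm{credit}_i$), but it is the definition this pipeline
implements as its primary mode; the credit denominator is available via
`gpa_average(..., denominator = "credit")`. Because both numerator and
denominator are exact rational functions of integer scores and credits,
the tests verify the implementation against a direct-summation oracle at
$10^{-12}$.

**Dining regularity.** Meal events are binned into four windows —
breakfast 06:00–09:00, lunch 11:00–14:00, dinner 17:00–20:00, and an
*other* catch-all. The three canonical windows represent "three meals a
day"; the catch-all exists so eating at irregular hours raises, rather
than silently truncates, the profile. The dining entropy is Shannon
entropy $E = -\sum_i p_i \log p_i$ in natural log (the base only rescales
a feature consumed by scale-tolerant models downstream; nats are the
default convention here).

**Dining anomaly score.** Students with similar entropy can still differ
in kind — sparse canteen users versus frequent regulars — so students are
clustered with k-means ($k = 3$, matching the three qualitative dining
regimes: good, poor, sparse) on a three-dimensional vector: entropy,
meals per day, and mean daily coverage of the canonical windows. The
coordinates are standardized to zero mean and unit variance before
clustering so no single unit dominates the Euclidean metric. The anomaly
score of a student at point $x$ in cluster $i$ is

$$M = D(x, c_i)\left(1 - \frac{|C_i|}{N}\right),$$

the Euclidean distance to the centroid weighted up for small clusters:
far-from-centroid members of small clusters are the most anomalous diners,
and a cluster containing the whole cohort scores zero for everyone. $M$ is
scale-covariant (scaling all coordinates by $\alpha$ scales $M$ by
$\alpha$), which is tested as an invariant.

The clustering engine is Lloyd's algorithm restarted from 25 random
initializations with the best within-cluster sum of squares kept.
Restarts are driven manually so a degenerate restart (duplicate initial
centers, an emptied cluster) is discarded rather than propagated; the
acceptance suite checks the restarted solution against exhaustive
enumeration of all $3^8$ assignments on 8-point instances.

**Insomnia.** The insomnia probability is $P = t/T$: insomnia nights over
observed days. On generated cohorts the per-student insomnia-night count
is an explicit field of the record; for real logs that lack such an
indicator, `insomnia_nights_from_sessions()` derives it behaviorally as
"any night with an internet session intersecting 00:00–06:00". The
generated count is authoritative on synthetic cohorts so that the
insomnia channel remains statistically separable from the network channel
in ablation experiments.

**Network summaries.** Mean sessions per day and the fraction of sessions
starting in 00:00–06:00.

Missing channels (a student with no meal events, say) are flagged,
imputed with the cohort median and reported via a warning; the feature
table never contains missing values.

## The trajectory representation and the base CNN

A student's internet behavior is encoded as weekly **activity grids**:
7×24 matrices of minutes online per hour, normalized to $[0,1]$ and capped
at 1 when overlapping sessions exceed an hour. The observation window is
split into weeks of 7 days; a trailing partial week is zero-padded rather
than dropped, so late-window behavior still contributes. The weekly grid
is the natural scale for school routines (weekday/weekend structure falls
along the rows, time-of-day along the columns).

The five-layer base CNN — conv(3×3) → pool(2×2) → conv(3×3) → pool(2×2) →
fully connected — extracts a fixed-length embedding from one grid. Each
pooling layer applies a learned per-map scalar weight and bias after the
2×2 downsample, $\hat x = f(w \cdot \mathrm{down}(x) + b)$; the
downsampling function is the block **mean** by default (a learned affine
on top of mean pooling is the conventional reading of a weighted
subsampling layer; max pooling is available by flag). The weight is a
scalar per map, not a full matrix — the leaner of the two readings, chosen
because the subsequent convolution already provides cross-map mixing.
Kernel counts for the base CNN default to 4 and 32, mirroring the fusion
model below. Hidden activations are ReLU; the embedding output is linear.
Maps with odd extent are zero-padded on the right/bottom before pooling.

## DeepPsy: the CNN + LSTM + FCNN fusion model

The full model has two branches trained jointly end to end.

The **trajectory branch** applies, per weekly grid:
conv(4 kernels, 3×3, same padding) → batchnorm → 2×2 mean pool →
conv(32 kernels, 3×3, same) → batchnorm → 2×2 mean pool →
fully connected (16) → dropout (0.5). Same padding keeps the 7×24 extent
through each convolution; the two pools reduce it to 4×12 and then 2×6,
giving a 384-dimensional flattened map. The per-week 16-vector is then
projected linearly to 64 dimensions and the week sequence is consumed by
an LSTM with 4 units whose final hidden state summarizes the trajectory.
The 16→64 projection is a reconstruction: the architecture prescribes an
LSTM input width of 64 but a fully connected width of 16, and a learned
linear projection is the minimal bridge between the two.

The **basic branch** is a two-layer fully connected network (8 then 4
units, ReLU) over the tabular feature vector.

The branch outputs (4 + 4) are concatenated, passed through a fully
connected fusion layer of width 4 and a softmax head. The default head is
binary (MD vs none) because recall over the binary MD indicator is the
screening criterion; a 4-class severity mode (`n_classes = 4`) is also
supported, which is the natural reading of a four-unit fusion layer.

Training: 60 epochs of Adam at learning rate $10^{-3}$ with batch size 4
and cross-entropy weighted inversely to class frequency (the MD class is
the minority; unweighted training collapses recall). "Iterations" are
epochs here: the training curves stabilize on an epoch axis, and 60
batches would not complete one pass over the data. Batch normalization
uses per-batch statistics during training and running averages (momentum
0.9) at inference; dropout is active in training only. One backward pass
updates both branches — tested structurally by asserting that parameters
in both branches move after a single step.

Numerical choices: weights use fan-in scaled uniform initialization;
biases start at zero; BN $\varepsilon = 10^{-5}$; softmax probabilities
are floored at $10^{-12}$ inside the loss. All layer gradients are
hand-derived and verified against central finite differences at $10^{-4}$
on toy instances. The conv/pool/batchnorm stack is implemented as fused
C++ kernels (with BLAS for the convolution contractions) behind thin R
wrappers; no randomness lives in C++, so a single integer seed fixes
initialization, batch order and dropout masks, and a rerun is bit-identical
on one platform.

## Classifier bench and evaluation

Five standard classifiers — random forest, naive Bayes, gradient
boosting, a single-hidden-layer neural network, and a decision tree — are
trained on the tabular features with small fixed hyperparameter grids,
tuned on the validation split by F1 with a recall tiebreak, and reported
on the held-out test split. The split is 60/20/20 stratified by the
binary label (three named splits, conventional fractions), deterministic
under a seed, with largest-remainder rounding so the sizes are exact.
Selection by validation F1 with recall tiebreak reflects the screening
emphasis: recall is the operational quantity, F1 guards against trivially
flagging everyone. Recall is computed on the MD class only, not
macro-averaged. AUC is the rank statistic (concordant pairs with half
credit for ties), checked against a brute-force pair count.

## The synthetic cohort: what it emulates and what it does not

`simulate_cohort()` generates 210 students — 70 per school level, gender
balanced — over 60 days, with MD prevalence 0.30 and severity mix
0.5/0.3/0.2 (mild/moderate/severe). Severity scales every planted shift
by 0.6/1/1.4. The channel models are deliberately simple and
controllable:

* meals: three canonical windows attended with probability 0.92 and
  Gaussian jitter (SD 25 min); MD inflates the jitter and depresses
  attendance in proportion to the `dining_irregularity` effect;
* sessions: Poisson(3) per day, daytime Gaussian component around 16:30
  plus a night component uniform over 00:00–06:00 whose weight rises with
  `late_night_use`;
* scores: integers from Normal(75, 8) clamped to [50, 100], shifted down
  by 8 points per unit of `grade_deficit` (times severity);
* insomnia nights: Binomial(60, p) with baseline p = 0.06 raised by
  `insomnia_rate`.

The default effect sizes are 1.0 on every channel. Four channels each
shifted by one baseline standard deviation compound to a strongly
separable cohort at n = 210 — classifiers typically sit at or near
ceiling under the defaults, and harder regimes are obtained by lowering
`effect_sizes`. Prevalence 0.30 keeps enough
positives in every stratified split for stable recall estimates while
remaining a minority class; a realistic population prevalence would be
far lower, which is one of several reasons these numbers do not transfer
to real screening. The "strong effects" condition used by the
signal-recovery checks sets every effect to 2.0; the null condition sets
all to 0, under which every channel distribution is identical between
classes by construction.

What the simulator does **not** emulate: label noise (concern levels come
from questionnaires, not oracles), within-student nonstationarity (exam
periods, holidays), correlated channels beyond the shared MD indicator,
school-level effects, missingness mechanisms other than the explicit
corruption injector, and any clinical construct validity. Passing tests
therefore demonstrate that the pipeline recovers signal *of the kind it
assumes*, deterministically and with correct arithmetic — not that these
features measure adolescent psychopathology.

## Experiment designs

All experiment drivers use paired designs: the same seeds and identical
splits across arms (comparison), across datasets (ablation) and across
swept values (sweeps), so differences are within-seed contrasts.

* `run_comparison()` — selected tabular classifier vs DeepPsy on
  identical splits, paired metric differences with a sign test.
* `run_ablation()` — DeepPsy retrained on four nested channel sets
  (all → performance+consumption → network+performance → performance
  only). Variants without the network channel drop the trajectory branch
  entirely; retraining per dataset (rather than masking inputs of a fixed
  model) is the chosen reading, since a fixed model's batchnorm and fusion
  statistics would be miscalibrated under masked inputs.
* `run_sweep()` — robustness over first-layer kernel counts and batch
  sizes on the geometric grid {2, 4, 8, 16, 32}; the fluctuation summary
  is the max − min of per-value medians.
* `plot_training()` / `stabilization_epoch()` — training curves with the
  stabilization epoch annotated: the first epoch from which the loss
  suffix varies by less than 1% of the loss range.

Replication counts are 10 seeds for comparison/ablation medians (single
runs of a stochastic trainer are not interpretable) and medians rather
than means throughout, for robustness to occasional bad runs.

## Problem sizes and defaults used by the shipped checks

The test suite exercises unit behavior on reduced cohorts (24–60
students, 2–3 training epochs) and reserves the full conditions — the
210-student cohort, the complete 60-epoch architecture, 10 seeds — for
the end-to-end acceptance checks and `scripts/acceptance.R` (which uses
10 comparison seeds and 5 ablation seeds). These sizes are the package's
chosen desk-scale study conditions; they keep a full reproduction in the
tens of minutes on a single core.

## Known limitations

* The generator's effect parametrization is linear in severity and
  channel-independent given MD status; real comorbidity structure is
  richer.
* The Eq-style anomaly weighting `1 - |C_i|/N` is one reading of an
  ambiguously printed formula (a centroid divided by a student count is
  not dimensionally meaningful); the cluster-size fraction is implemented
  and documented as such.
* With strong planted effects the tabular features alone are nearly
  sufficient, so the fusion model's advantage over the best tabular
  classifier is often a tie at ceiling rather than a strict improvement;
  the paired design reports the direction without overclaiming.
* Bit-stability holds within one platform/BLAS; across BLAS builds,
  floating-point reductions may differ in the last ulp.
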