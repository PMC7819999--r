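---
title: "Methylation-based tumour classification with sarclass: models and methods"
author: "sarclass authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation-based tumour classification with sarclass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`sarclass` implements an end-to-end DNA methylation array classification
pipeline of the kind used for sarcoma diagnostics: two-channel intensity
normalization, batch adjustment, beta values, sample and probe quality
filtering, unsupervised cohort structure (t-SNE, Ward clustering), a
class-balanced Random Forest whose vote fractions are mapped to calibrated
class probabilities by a penalized multinomial regression, methylation class
family (MCF) aggregation, a common 0.9 reporting threshold, and copy-number
profiles inferred from the combined probe intensities. Because real
reference cohorts of this kind (thousands of IDAT pairs, vendor manifests,
dbSNP annotations) are not shipped with a package, `sarclass` also contains
a first-class synthetic-cohort generator that reproduces the statistical
structure these methods assume, so every step of the pipeline is exercised
and tested end to end.

# The generative model of the synthetic cohorts

`simulateCohort()` draws cohorts under an explicit model:

* **Class archetypes.** Each of $K$ methylation classes has an archetype
  beta profile. At the `nInformative` class-informative CpGs the archetypes
  take one of two levels, $0.5 \pm s/2$ where $s$ is
  `archetypeSeparation`; each class is "high" on its own block of
  informative CpGs and "low" elsewhere. For two classes this makes the
  archetype distance exactly $s$ at every informative CpG. All other CpGs
  share a common bimodal tumour baseline, as methylomes are bimodal.
  A deliberately *confusable* pair (separation $s' \ll s$ between two
  classes that share their main signature) can be configured to emulate
  closely related entities that motivate family-level scores.
* **Purity mixing.** A sample with tumour purity $p$ has expected beta
  $p\,\beta_{\text{class}} + (1-p)\,\beta_{\text{leukocyte}}$, the convex
  dilution of tumour signal by non-neoplastic (leukocyte-like)
  cells. Purity is drawn uniformly from `purityRange`
  (default $U(0.6, 1)$, a realistic distribution for clinical specimens).
* **Dispersion.** Observed betas are Beta-distributed around the mixed
  mean with concentration `betaConcentration` (default 50);
  `betaConcentration = Inf` is the noiseless limit used by the exactness
  tests.
* **Intensities.** Total intensity per probe is log-normal with median
  5,000 and 0.3 log2 sd. Most of that spread is probe affinity shared
  across samples (as on real arrays, where it cancels against a cohort
  baseline); a 0.08 log2-sd per-sample component remains. The channels
  split as $M = T\beta$, $U = T(1-\beta)$.
* **Background.** An additive optical background (median 200 per channel
  and sample) is added to every measured intensity; the negative control
  probes read pure background. This is exactly what the background
  correction step removes. `backgroundLevel = 0` gives the pure mixing
  model, used where tests assert exact archetype recovery.
* **Batch effects.** One additive log2 shift per factor level
  (default 0.5): the material effect (FFPE) on the methylated channel and
  the array effect (EPIC) on the unmethylated channel. A shift common to
  both channels would cancel in $M/(M+U)$ and be unobservable downstream;
  putting the shifts on different channels makes the batch structure
  visible in beta space and removable by the channel-wise linear-model
  correction — the situation that correction exists for. Batch shifts
  apply to measurement probes, not control probes: control-anchored
  per-sample normalization would otherwise silently absorb the batch
  effect and leave the cohort-level correction nothing to do. Material and
  array labels alternate within each class (a balanced design), so the
  batch factors are orthogonal to class and the correction cannot absorb
  class signal.
* **Copy-number events.** `injectCNV()` scales the genomic signal of all
  probes in a region by $p \cdot c/2 + (1-p)$ for copy state $c$ and
  purity $p$, equally in both channels, so betas are unchanged. The
  optical background is not scaled: amplification acts on genomic
  material, not on the scanner floor.
* **Novel entities.** Out-of-reference samples draw their own archetypes
  on CpGs disjoint from the reference-informative set, exercising the
  non-classifiable pathway.
* **Controls.** Negative controls read background; normalization controls
  sit near the median probe intensity with a tight 0.05 log2 sd (their
  mean sets the dye scale, and a noisy scale would itself distort betas
  between channels); bisulfite-conversion control blocks are drawn at
  4,000 median for the QC metrics.

Everything is deterministic given the configuration seed.

What the generator does *not* emulate: Infinium I/II chemistry
differences, probe cross-hybridization sequence effects, realistic genome
coordinates (synthetic chromosomes carry evenly spaced probes), or
CpG-island spatial correlation. Tests passing on these fixtures therefore
demonstrate the correctness of the pipeline's logic and its statistical
behaviour under the stated model, not clinical performance on real
tumours.

# Normalization and batch adjustment

Each sample is normalized individually, in this order:

1. **Background correction**: per colour channel, the 5th percentile of
   the negative-control intensities (linear interpolation between order
   statistics, the standard quantile definition) is subtracted from every
   intensity of that channel, so that percentile becomes exactly 0.
2. **Dye-bias correction**: per channel, all intensities are scaled so the
   mean of the normalization controls is exactly 10,000.

The order matters: scaling before the background shift would rescale the
background itself, and the pipeline asserts the stated order. Cohort-level
batch adjustment then fits, per probe, a linear model of the
log2-intensities on the material (FFPE/frozen) and array (450k/EPIC)
factors jointly and removes the fitted factor effects while keeping the
intercept (`limma::removeBatchEffect` is the established implementation of
exactly this model). The methylated and unmethylated channels are adjusted
individually. Values driven non-positive by background subtraction are
floored at 1 before the log2 transform; the retransformed value is used as
is. Finally `computeBeta()` computes
$\beta = M / (M + U + 100)$ with negative intensities clipped to 0, which
keeps every beta in $[0, 1)$.

Platform harmonization restricts all statistics to probes present on both
the 450k and EPIC arrays before anything else happens.

# Quality and probe filtering

The per-sample QC gate compares the mean bisulfite-conversion control
intensities against a reference distribution and excludes a sample when at
least one control block falls in the lowest decile *and* the overall noise
level exceeds 3. The conjunction is the literal reading of the rule this
gate reproduces; `logic = "or"` provides the disjunctive alternative. When
no external reference set is available the cohort itself serves as the
reference distribution. The noise level is the standard deviation of first
differences of the genome-ordered log2 ratios divided by $\sqrt 2$,
calibrated so unit-variance white noise scores 1.0 while smooth
copy-number steps contribute negligibly; the underlying tool this emulates
does not publish its formula, so the estimator here is the package's own
definition and the ">3" threshold is meaningful relative to this scale.

Probe filtering removes, in a fixed order so per-filter counts are
reproducible: chrX/chrY probes, probes with a SNP within 5 bp of (and
including) the targeted CpG, probes not mapping uniquely to the reference
allowing one mismatch, and probes absent from either array. Each probe is
attributed to the first filter that removes it, making the bookkeeping an
exact partition. SNP overlap and mapping uniqueness arrive as annotation
flags; the package does not re-derive them.

# Unsupervised structure

t-SNE runs on the 10,000 most variable CpGs by standard deviation
(denominator $n-1$; ties broken lexicographically by probe id for
determinism) with perplexity 30 and 3,000 iterations, initialized from the
first two principal components under a fixed seed so embeddings are
reproducible. Projection stability is assessed by re-embedding random 90%
subsamples (500 repetitions at study scale); as the stability statistic
the package reports, per repetition, the fraction of samples whose
10-nearest-neighbour class majority in the embedding matches their own
class — a concrete operationalization chosen here because the procedure
this emulates names no summary statistic. Hierarchical clustering uses the
20,000 most variable CpGs by median absolute deviation (1.4826 scaling),
Euclidean distance and Ward's linkage.

# The classifier

Training grows 10,000 binary decision trees (at fixture scale the tests
use 150–1,000). Class imbalance is addressed by downsampling: every tree
is grown on a stratified draw of equal size from each class — the smallest
class count — without replacement, which removes the prior bias toward
large classes. CpG selection takes the 10,000 probes with highest variable
importance (Gini mean decrease by default, permutation importance by
option) from a preliminary forest of one tenth the tree count; importance
ranks stabilize far before vote probabilities do, which is why the
preliminary forest can be small. Probe selection is re-run inside every
cross-validation training fold, so no information from held-out samples
leaks into the ranking; a global pre-selection would bias the
cross-validated error optimistically. The raw score of class $k$ for a
sample is the fraction of trees voting $k$; raw score rows sum to 1 by
construction.

# Calibration

Raw vote fractions are not comparable across classes, so they are mapped
to calibrated probabilities by an L2-penalized multinomial logistic
regression: the methylation class is the response and the $K$ raw scores
are the covariates. The fit maximizes

$$\sum_i \log p_{y_i}(x_i) - \frac{\lambda}{2}\lVert W \rVert^2$$

with softmax link, unpenalized intercepts, and the symmetric
parameterization (one weight row per class). The ridge penalty keeps the
problem well posed when classes are perfectly separable — exactly the
regime a well-trained forest produces. Optimization is BFGS followed by
Newton polishing with an analytic Hessian; the fit refuses to return
unless the gradient norm at the optimum is below $10^{-6}$. The common
intercept shift is a null direction of the objective; intercepts are
centred after fitting for identifiability, which leaves the probabilities
untouched.

Calibration must be fitted on *independent* scores: scores of samples the
forest was trained on are biased toward 1 and would mis-calibrate unseen
cases. `oofRawScores()` therefore generates out-of-fold scores by
class-stratified threefold cross-validation, and the nested
cross-validation harness embeds this inner threefold loop inside each
outer training fold.

The penalty $\lambda$ is tuned by resampling: 500 times (20–50 at test
scale), 70% of the out-of-fold scores are drawn (stratified by class so
every repetition retains all classes — plain subsampling can drop a small
class at fixture scale), a calibration model is fitted per candidate
$\lambda$ on a log-spaced grid ($10^{-4}$ to $10$, 50 points by default),
and the held-out 30% are calibrated. Each held-out sample is labelled
correct/incorrect by its calibrated argmax, and the Youden index
(sensitivity + specificity − 1) of the rule "maximum calibrated score
$\ge$ 0.9" is computed; vacuous groups count as perfect. The $\lambda$
with the best repetition-averaged Youden index at the prespecified 0.9
cutoff wins, ties going to the smaller (smoother) penalty. Tuning at the
deployment cutoff regulates the calibration strength so the scores behave
well exactly where the reporting decision is made.

# Families and the reporting threshold

A methylation class family (MCF) groups biologically close classes whose
mutual confusions are diagnostically irrelevant; the family score is the
exact sum of the member calibrated scores. Family membership is
configuration input, never hard-coded, because family composition depends
on the reference cohort at hand. A sample is *classifiable* when its best
class score or best family score reaches the common cutoff of 0.9; the
argmax class is reported either way (ties broken lexicographically — a
measure-zero event in float scores, fixed for determinism). A single
shared cutoff, rather than per-class cutoffs, keeps reports comparable
across classes and classifier versions.

# Evaluation

`nestedCV()` reports the misclassification rate of raw and calibrated
argmax predictions, the family-level error, the multi-class AUC and the
Brier score, all on pooled outer-test predictions. The multi-class AUC is
the Hand–Till construction: for every unordered class pair the two
conditional two-class AUCs are averaged, then averaged over pairs
(one-vs-rest macro-averaging is deliberately not the default). The Brier
score is $\frac1n\sum_i \sum_k (p_{ik} - y_{ik})^2$ with one-hot truth —
sum over classes, mean over samples, no extra $1/K$. Fold assignments are
stratified, seeded, and recorded in the report for exact replay, and the
report retains the training-id sets so leakage can be audited.

# Copy-number profiles

Combined intensities $M + U$ are compared against a per-probe cohort
median baseline: $r = \log_2((M+U)/\text{baseline})$ over the
filter-surviving autosomal probes, genome-ordered. The profile is then
recentred by the mode of its ratio distribution (kernel-density peak,
refined by the median of the surrounding bulk for variance reduction) so
the copy-neutral state sits at 0 even in aneuploid genomes — the
"additional baseline correction"; the mode is preferred over the plain
median because large aberrant fractions move the median but not the
neutral peak. Probes are grouped into fixed-width bins (100 kb default)
merged rightward until each holds at least 5 probes, and bins are
segmented per chromosome by an exact penalized least-squares change-point
fit (dynamic programming over all breakpoints). The default penalty is
BIC-like, $2\hat\sigma^2\log n$, with $\hat\sigma^2$ estimated robustly
from first differences of the bin values ($\mathrm{sd} = 1.4826 \cdot
\mathrm{median}|\Delta|$, halved for the differencing); no established
change-point package is assumed, and the dynamic program is exact rather
than heuristic. Class summaries report, per bin, the fraction of samples
whose covering segment exceeds $+0.15$ (gain) or falls below $-0.15$
(loss); these thresholds are configuration, not claims. Coordinates are
half-open and 0-based internally, 1-based in SEG exports.

# Numerical choices and degenerate inputs

* Quantiles use linear interpolation between order statistics throughout.
* Probe-statistic ties (variance ranking, importance ranking) break
  lexicographically by probe id, so all rankings are total orders.
* `computeBeta(0, 0)` is 0: the offset prevents 0/0.
* A batch factor with a single level is skipped with a message rather
  than an error.
* An all-constant beta matrix short-circuits importance ranking to the
  lexicographic order (the underlying forest code cannot grow trees
  without a single valid split).
* Leave-one-out is supported as the special case `nFolds = n`, which
  cannot be class-stratified.
* A copy-number region overlapping no probe warns and returns the sample
  unchanged.

# Problem sizes

The test-suite and the acceptance script run scaled-down analogues of the
study conditions, chosen so the whole suite completes in minutes on one
CPU while every statistical claim stays testable: cohorts of 2–6 classes
with 8–20 samples per class, 300–2,400 probes with 20–50 informative
CpGs, forests of 100–1,000 trees, tuning grids of 5–8 penalties with
20–50 repetitions. The headline numbers of the full-scale study (error
rates below 2%, AUC 0.99 at 65 classes and 1,077 reference samples)
require the original reference data and are not reproducible at this
scale; the package asserts instead the properties that make those numbers
possible: exact normalization, leakage-free nested validation, calibration
that never hurts the Brier score, family rescue of confusable classes, and
unbiased copy-number recovery.

# Known limitations

* The QC noise statistic is this package's own estimator; its absolute
  scale matches the conventional ">3" rule only in the sense documented
  above.
* The calibration model assumes the raw-score geometry of a vote-fraction
  simplex; applying it to scores from other classifier families is
  untested.
* Segmentation is exact but $O(n^2)$ per chromosome in the number of
  bins — ample for array-scale bins, not for sequencing-scale ones.
* The generator's batch and background models are deliberately simple
  (one shift per factor level, one background level per channel); real
  FFPE artefacts are richer.
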