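---
title: "Methods: semantic feature clustering and hierarchical boosted ensembles for ICU mortality risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semantic feature clustering and hierarchical boosted ensembles for ICU mortality risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The modelling problem

`icuhybrid` builds short-term (7-day) risk-of-death models for mechanically
ventilated ICU patients in a way that keeps the model's reasoning legible
to clinicians. The key idea is to organize the clinical feature space
*before* any patient data are touched: each feature (a vital sign, a lab
value, a comorbidity flag) is described in a short free-text document
explaining how it relates to ICU mortality; the documents are vectorized
with TF-IDF and soft-clustered with fuzzy C-means; and the resulting
clusters — which in practice align with mortality causes such as liver
failure, infection, renal failure, hypoxia, cardiac failure and the
mechanics of ventilation — define one weak boosted-tree classifier each.
A strong boosted-tree classifier combines the weak classifiers' output
probabilities into the final risk. Explanations then live at the level of
mortality causes rather than dozens of correlated raw features.

## Cohort construction

Raw input is a long-format table of time-stamped signals per ICU stay plus
stay metadata. Time is handled internally as hours from ICU admission.

* **Ventilation onset** is the first recorded PEEP value; a stay without
  PEEP records is treated as never ventilated and excluded.
* **Inclusion/exclusion**: age at least 18; ventilation spanning at least
  24 h from onset; no death within the first 24 h from ICU admission
  (admission-anchored, deliberately distinct from the ventilation-anchored
  observation window); stays with missing age are counted separately as
  unevaluable rather than silently retained. The per-criterion counts
  partition the input, as in a consort diagram.
* **Observation window**: the 24 h following ventilation onset. Each
  signal contributes mean, median, minimum, maximum and standard deviation
  over samples in `[onset, onset + 24 h)`. No samples give five missing
  values; a single sample leaves the standard deviation missing.
* **Criteria-based flags**: the ARDS flag requires PaO2/FiO2 <= 300 *and*
  PEEP >= 5 cmH2O sustained for at least 8 consecutive hours inside the
  window. Clinical measurements are sparse and irregular, so the joint
  condition is evaluated under last-observation-carried-forward
  step-function interpolation (the standard bedside reading of monitor
  values); thresholds and the 8 h span are closed (boundary values
  qualify). The organ-dysfunction flag is a strict disjunction:
  platelets < 100 x 10^9/L, lactate > 2 mmol/L, or INR > 1.5, over
  whichever inputs are available.
* **Derived values**: eGFR uses the race-free CKD-EPI (2021) closed form
  (142, kappa 0.7/0.9, alpha -0.241/-0.302, exponent -1.200, 0.9938^age,
  1.012 for females). Because creatinine circulates in both mg/dL and
  umol/L conventions, both unit modes are supported explicitly rather
  than guessed. BMI is binned left-closed at 18.5/25/30/35/40.
* **Missingness** stays explicit (`NA`) end to end; boosted trees route
  missing values natively, so no imputation is performed.

## Corpus preprocessing and TF-IDF

Documents are elicited with a fixed two-slot prompt (word count and
feature name) and validated for coverage, duplicates, empty bodies and
word-count outliers. Preprocessing is a fixed pipeline: non-alphabetic
characters become separators (digits are dropped — lab thresholds written
in prose would otherwise fragment the vocabulary), text is lowercased and
split into maximal alphabetic runs, stop words from a fixed list shipped
in the package are removed, and tokens are stemmed with an in-package
implementation of the Porter (1980) algorithm. Porter is the canonical,
fully specified English stemmer, which keeps the vocabulary reproducible
bit-for-bit across platforms. One subtlety: Porter stems are not always
fixed points of the stemmer (increased -> increas -> increa), so the
pipeline applies stemming exactly once; the cleaning, tokenization and
stop-word stages are idempotent.

The TF-IDF variant is fixed: raw term counts, `idf = ln((1 + N)/(1 + df))
+ 1`, rows L2-normalized. The smoothed, strictly positive idf down-weights
ubiquitous terms without deleting them, and unit rows make Euclidean
distance rank-equivalent to cosine similarity, which is what the
clustering step assumes.

## Fuzzy C-means and multi-membership assignment

Clustering uses the standard fuzzy C-means fixed point
(`u_ij = 1 / sum_l (d_ij/d_lj)^(2/(m-1))`,
`c_i = sum_j u_ij^m x_j / sum_j u_ij^m`) with `K = 6` clusters and
fuzziness `m = 1.2`, iterated until the objective
`J_m = sum u_ij^m ||x_j - c_i||^2` changes by less than `1e-7`
(cap 500 iterations). Because fuzzy C-means is sensitive to starts and
has no canonical initialization, centroids are drawn from distinct data
points and the best of 10 restarts by final objective is kept, with the
seed recorded. Membership columns sum to one after every iteration and
the objective trace is non-increasing by construction of the alternating
updates; both are asserted as typed invariants. Points exactly coincident
with a centroid receive membership one there (the zero-distance limit of
the update). Documents that preprocess to zero tokens are excluded from
clustering with a warning and attached post hoc to their nearest nonempty
neighbour's clusters.

A feature joins every cluster whose membership reaches the cutoff 0.2
(soft multi-membership — a marker like the organ-dysfunction flag
legitimately belongs to several failure modes); memberships within 1e-12
of the cutoff are retained as exact ties, and a feature reaching no
cluster falls back to its argmax cluster so that every feature is owned.
Cluster labels (e.g. "Liver Failure") are attached from configuration
after clinician review; the package treats the label map as data.

## The hybrid ensemble

One weak XGBoost classifier is trained per cluster on exactly that
cluster's feature columns (multi-cluster features are used by each owning
learner); a strong XGBoost classifier over the K weak output
probabilities produces the final risk. Probabilities rather than hard
labels are passed upward, preserving ranking information. All boosters
use the binary logistic objective with AUC as the early-stopping metric
(patience 10 rounds by default, on a stratified 20% holdout inside each
training set), exact greedy splits (`tree_method = "exact"`; histogram
binning can misplace cuts on small cohorts), one thread and fixed seeds,
so training is bit-reproducible. Hyperparameters are grid-searched with
stratified 5-fold cross-validation by mean out-of-fold AUC (default grid:
depth 2-4 by learning rate 0.05/0.1/0.3, up to 400 trees under early
stopping); the benchmark "global" model on the unstructured feature list
uses the identical protocol.

Two design points deserve explanation:

* **Stacking inputs.** The strong learner can be trained on out-of-fold
  weak predictions from a shared 5-fold partition (`stacking = "oof"`) or
  on the final weak models' in-sample outputs (`"insample"`, the
  default). Out-of-fold stacking avoids leaking training labels into the
  meta-learner, but in this architecture the meta-learner's deployment
  inputs come from the full-data weak models, whose output distribution
  differs from the out-of-fold one; across seeded synthetic cohorts this
  mismatch consistently cost about 0.02 validation AUC. In-sample
  stacking matches the deployment distribution and validated better in
  every replicate, at the price of optimistic derivation-cohort metrics —
  an optimism the test suite quantifies directly by comparing the two
  modes. Model quality should therefore always be judged on held-out
  data, and the package's evaluation utilities tag metrics by cohort.
* **Monotone meta-model.** The strong learner is constrained to be
  monotone increasing in every cluster probability: a higher
  cause-specific risk cannot lower overall predicted risk. This is
  clinically necessary and regularizes the stacking stage.

## Interpretation

* **Hierarchical importance.** Cluster weights `w_i` are the strong
  learner's normalized gain shares over its K inputs; within-cluster
  shares `f_ij` are each weak learner's normalized gains; the final
  importance of feature j in cluster i is `w_i * f_ij`, renormalized to
  sum to one over all (cluster, feature) pairs. Features owned by several
  clusters keep one entry per owner and are additionally summed per
  feature; both views are exported, since a single resolution of
  multi-membership would be arbitrary.
* **Shapley explanations.** For one stay, the strong model over its K
  cluster probabilities is explained exactly by coalition enumeration
  (feasible for K <= 15), with the value of a coalition defined as the
  interventional expectation over an explicit, seeded background sample
  (default 100 rows) — fixing the estimand makes explanations
  reproducible rather than dependent on a library default. Efficiency
  (baseline + contributions = model output) holds by construction and is
  asserted to 1e-6. For feature-level explanations (e.g. the global
  model's 48 inputs) a permutation-sampling estimator is provided; each
  sampled ordering is evaluated against the full background, so additive
  models are recovered exactly regardless of the permutation budget,
  Monte-Carlo standard errors are reported, and the small efficiency
  residual is redistributed proportionally to absolute contributions.
  Waterfall export sorts contributions by absolute value and aggregates
  the remainder into an "other" row.

## Evaluation

AUC is computed by the rank (concordance) formulation with ties counted
one half, which makes the identity `AUC = U/(n1 n0)` with the
Mann-Whitney statistic exact — the test suite asserts it on random
instances. Decision thresholds maximize accuracy over midpoints of
consecutive distinct scores (with infinite sentinels); among ties the
smallest maximizing threshold is returned, favouring sensitivity, and the
decision rule is "positive when score >= threshold". Precision or recall
with empty denominators are reported as missing with an explicit flag,
never as zero. The Mann-Whitney p-value is exact (by enumeration, via
`wilcox.test`) when the combined sample size is at most 20 without ties
and a tie-corrected normal approximation otherwise. Model comparison runs
the test per metric on matched per-fold values and declares "no
significant difference" only if every metric's p-value reaches the 0.05
level; with five folds per side the power is limited, which the verdict
records as a note.

## Synthetic data: what it emulates and what it does not

The generators make every stage testable offline.

* **Corpus**: `n_causes = 6` planted vocabularies, 8 single-cause
  features per cause plus 2 dual-cause features, 150-word documents with
  a fraction `rho = 0.5` of cause words (dual features split their cause
  slots), hallucination noise `h` redirecting cause slots to a random
  other cause (0 by default), and a shared filler vocabulary. Tokens are
  synthetic letter-only strings engineered to pass the preprocessing
  pipeline unchanged, so stemming collisions cannot blur the planted
  structure.
* **Patients**: independent standard-normal cause severities `z_k`;
  death probability `logistic(beta0 + sum(beta_k z_k))` with
  `beta = (1.6, 0.9, 0.8, 0.7, 0.6, 0.5)` and `beta0 = -3.1`, giving a
  marginal 7-day death rate near 13-14% — the typical rate in
  mechanically ventilated cohorts — and one clearly dominant cause so
  that effect-ordering recovery is a well-posed question. Feature j of a
  cause loads `lambda * 0.7^(rank-1)` on its severity with noise sd 0.5:
  a lead marker that measures its cause almost directly, then geometrically
  weaker correlates. This concentration mirrors what importance analyses
  show in real cohorts (one or two dominant markers per cause) and is
  also what makes per-cluster weak learners information-sufficient, so
  that the hybrid's discrimination can match an unstructured model — on
  diffuse equal loadings a pooled model genuinely wins, which is a
  statement about the data geometry, not the architecture. One mid-rank
  feature per cause is dichotomized at its 70th percentile as a
  comorbidity analogue. Labels are Bernoulli draws from the true
  probability, keeping AUC targets well defined. Severities are
  independent across causes by default — real causes co-occur, but
  independence keeps recovery tests sharp.
* **Time series**: step-wise vitals/labs with configurable PEEP onset and
  planted ARDS-qualifying spans of known length, exercising the cohort
  path against planted truth.

Passing tests on these cohorts demonstrate internal correctness and the
architecture's behaviour under a known latent-cause model; they say
nothing about calibration or discrimination on real ICU data, which have
correlated causes, informative missingness, unit heterogeneity and
temporal drift that the generators deliberately omit.

## Reference study sizes and numerical choices

The packaged simulation study (`run_parity_study()`) uses 10 replicates
of 4000 patients and 50 features, a 75/25 derivation/validation split,
and a single conservative boosting configuration (depth 2, learning rate
0.05, up to 600 rounds, patience 30, per-node feature sampling 0.5, row
subsampling 0.8, histogram splits for compatibility with per-node
sampling) instead of the full grid search; the grid adds nothing on this
generator and a fixed configuration keeps multi-seed studies tractable on
a single CPU. Per-node feature sampling matters for one reason worth
recording: greedy deterministic splitting never chooses a single-cut
binary feature that is partly redundant with its cluster's continuous
lead marker, so without sampling the comorbidity analogues receive zero
gain; stochastic candidate sets restore their participation, which is
also the practical reason column sampling is near-universal in applied
boosting.

Numerical conventions collected in one place: fuzzy C-means tolerance
1e-7 on the objective; membership column sums asserted to 1e-9; Shapley
efficiency to 1e-6; importance normalizations to 1e-9; threshold
tie-break smallest; cutoff ties at 1e-12; all seeds derived from one
master seed via named substreams so stages are independently
reproducible.

## Known limitations

* Cluster count and fuzziness are taken as given (`K = 6`, `m = 1.2`);
  no model-selection machinery is provided.
* In-sample stacking (the default) makes derivation-cohort metrics
  optimistic; held-out evaluation is mandatory.
* The exact Shapley path is limited to 15 players; beyond that only the
  sampling estimator applies.
* The Mann-Whitney model comparison on five folds has little power;
  "no significant difference" is weak evidence of equivalence.
* Real-data concerns — unit conversion beyond declared units, EHR
  connectivity, calibration, temporal validation — are out of scope.
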