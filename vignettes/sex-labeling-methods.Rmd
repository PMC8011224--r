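---
title: "Methods: expression-based sex labeling, swap detection, and sex-bias summaries"
author: "sexlabelr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression-based sex labeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its models and of the design
choices made where the methodology was genuinely open. It states no
empirical result that the test-suite does not itself compute.

## 1. The inference model

Sex leaves a strong, low-dimensional signature in transcriptomes: Y-linked
genes are expressed in males and near floor in females, while a subset of
X-linked genes escapes X inactivation and is expressed from both X copies,
hence higher in females. The sample sex score is the predicted probability
of a penalized logistic regression over X/Y genes only (autosomal features
are deliberately excluded; they carry tissue- and disease-confounded sex
differences):

$$P(\text{male} \mid x) = \operatorname{logit}^{-1}\!\Big(\beta_0 +
\sum_{g \in XY} \beta_g \tilde x_g\Big),$$

with features standardized internally (coefficients are reported on the
standardized scale; the training means double as the imputation value for
genes missing at prediction time, i.e. 0 after standardization). Female is
coded 0, male 1, so Y-gene coefficients should be non-negative and X-escape
coefficients non-positive — an orientation the acceptance suite asserts on
synthetic data.

### Nested cross-validation (percentile rule)

Public corpora have strong between-study heterogeneity and within-study
correlation, so hyperparameter selection is study-stratified end to end:

* Studies sharing a sample with more than five other studies are removed;
  the rest are merged into **study groups** (connected components of the
  shared-sample graph). Groups — never samples — are the unit of all
  partitioning.
* Six outer folds partition the study groups, balanced by sample count
  (greedy bin packing).
* For each outer fold and each `alpha` in 0.1…1.0 (step 0.1), `lambda` is
  chosen as **lambda-1se** by cross-validation on the other five folds
  (fold ids = the five outer folds), and the misclassification error of
  that model is recorded on the held-out fold.
* The final `alpha` minimizes the **median** of its six validation errors;
  ties prefer the **largest alpha** (the sparser, more interpretable
  model). The final `lambda` is the **median** of that alpha's six
  per-fold lambda-1se values, and the model is refit on all training data
  there. This is the percentile rule at the 50th percentile, applied to
  both hyperparameters.

One numerical choice deserves emphasis: the *inner* lambda-1se criterion is
the cross-validated **binomial deviance** (glmnet's mean CV error for
logistic models), while the *outer* comparison across alphas uses
classification error. With a few percent of label noise (real corpora have
swapped labels; the generator injects 3%) the classification-error curve is
flat near its noise floor, its 1-SE band is enormous, and selecting on it
collapses the model toward the intercept — scores compress into the
unclassified band and coverage at the 0.7 threshold drops to nearly zero.
The deviance criterion keeps the probability scale sharp; the package's
acceptance criterion (≥ 95% concordance with ≥ 85% coverage on the default
synthetic corpus) fails under class-error inner selection and passes under
deviance, which is why the choice is hard-wired rather than exposed.

### Train/test construction

At most five labeled samples are drawn per study (limits overfitting to
large studies), the majority sex is randomly downsampled so the pool is
balanced, and whole study groups are assigned to train or test by a seeded
greedy search targeting 20% test samples with the male proportion inside
[0.45, 0.55] on both sides. An unsatisfiable balance request errors with
the class counts rather than silently degrading.

### Thresholds, sweep, and platform QC

Labels use the open unclassified band (0.3, 0.7): score ≥ 0.7 is male,
≤ 0.3 female, boundaries inclusive. `threshold_sweep()` traces the
concordance/coverage trade-off on a 0.5–0.99 grid. Coverage is
non-increasing in the threshold by construction. Concordance is
non-decreasing *provided* misclassified samples are never more
score-extreme than correctly classified ones — true in the strong-signal
regime the generator emulates (and empirically in well-separated corpora),
but not a theorem for adversarial score tables: one confidently wrong score
at 0.99 breaks it. The acceptance property is therefore tested on score
tables drawn from the strong-signal world (logit means ±5, SD 1), where
errors are confined below the labeling thresholds with overwhelming
probability.

Platforms are excluded when labeled-sample concordance falls below 0.70
with at least 20 evaluable samples (`min_n` guards against excluding
platforms on noise; platforms with fewer evaluable samples are flagged
`insufficient` instead).

## 2. Swap detection by per-study mixtures

Sample sex scores are heterogeneous across studies, so misannotation is
assessed *locally*: within each mixed-sex study the scores are fit with 1-
and 2-component unequal-variance Gaussian mixtures by EM, and BIC
(`k ln n − 2 ln L`, counting means, variances, and free weights) selects
the model.

* **Variance prior.** The original analysis used a model-based clustering
  package's "default prior with a larger scale parameter (0.15)"; the
  exact hyperprior form is not public, so this package implements a MAP EM
  with an inverse-gamma prior IG(shape = 1/2, rate = scale/2) on each
  variance, giving the closed-form M-step
  `sigma_k^2 = (S_k + scale) / (n_k + 3)`. Only the scale (0.15, on the
  variance scale of the [0, 1] score axis) is treated as normative; the
  form is a documented substitute. Because the M-step maximizes the
  *penalized* likelihood, the quantity EM provably never decreases is the
  penalized objective (log-likelihood + log prior); the fit records that
  trace and the tests assert its monotonicity, alongside a raw
  log-likelihood used for BIC.
* **Noise component.** A uniform density on [0, 1] is added iff any score
  falls in the unclassified band (0.3, 0.7) and at most one third of the
  study's scores do (more than that and the noise term is dropped to help
  convergence). Its responsibilities are initialized to exactly the
  in-band samples.
* **Initialization.** Five deterministic restarts (component means at the
  {0.1, 0.9}, {0.25, 0.75}, {0, 1}, {1/3, 2/3}, {0.4, 0.6} quantiles,
  hard-assigned responsibilities); the best penalized objective wins.
  Convergence at |Δobjective| < 1e-8 or 500 iterations.
* **Filters and flags.** One-component fits are discarded
  (`single_component`), as are two-component fits with means closer than
  0.3 (`low_separation`; filtering happens before any flagging). Clusters
  are oriented by mean (higher = male; ties are impossible past the
  separation filter). A sample with cluster posterior > 0.95 is a
  `mismatch` if the cluster sex contradicts its metadata, else a `match`;
  noise-captured samples are `unclassified`; the rest `unclear`. Samples
  without metadata sex receive NA.

Two cheaper estimators complement the mixtures: stratified mismatch rates
in large (≥ 10 samples) single- vs mixed-sex studies with a 2×2 chi-squared
(the "mostly-" categories are excluded from both strata as ambiguous;
when neither stratum has any mismatch the proportions are identical by
definition and the test degenerates to statistic 0, p = 1), and a
conservative consensus that flags a sample only when *every* non-abstaining
expression-based labeler contradicts the metadata (a generic two-cluster
labeler on mean Y expression ships as a stand-in voter).

## 3. Entity normalization

Cell-line and drug references are simplified TSV lexicons, not full
ontology parsers. Terms are lowercased; a punctuation-stripped variant of
every term is indexed so names differing only in punctuation match.
Tokenization splits on whitespace and punctuation but keeps internal
hyphens (cell lines like `kyse-30`, control terms like `non-treated`).

Cell-line rules, in order: identically named lines sharing a parent
collapse to the parent accession; duplicate names (exact or
punctuation-stripped) map to *all* their accessions; a synonym colliding
with another line's canonical name is dropped in favor of the name's owner;
terms shorter than 3 characters, all-numeric terms, stop words and mouse
strains are removed (the latter two as editable lists — the source analyses
reference such lists without enumerating them). Mapping tries three
attribute tiers of decreasing specificity — keys containing "cell"+"line",
values containing both, any mention of "cell" — with whole-value exact
matching before n-gram (n = 1..3) matching inside each tier; the first tier
with a hit wins and later tiers are never consulted (instrumented and
asserted in tests).

Drug terms of 3 or fewer characters are discarded; n-gram matches are
scanned longest-first so a 3-gram hit shadows its sub-grams
(`all-trans retinoic acid` does not double-count `retinoic acid`); the
18-term control vocabulary (none, control, untreated, dmso, na, placebo,
saline, pbs, mock, baseline, unstimulated, etoh, ethanol, ctrl,
non-treated, vehicle, ctl, no treatment) is matched independently, and a
text may map to both a drug and a control term. A *drug-mention* study's
title/description maps to ≥ 1 drug; a *drug-exposure* study additionally
has a sample-level treatment field mapping to one of the same drugs, and
the reported study–drug pairs are restricted to that intersection.

The source-type classifier applies exact keyword tests in a fixed
precedence (xenograft > stem cell > primary cell > cancer cell > cell line,
named when an accession attached > tissue > other); the original decision
diagram is not in prose, so this precedence is a documented substitute.

## 4. Bias statistics

Study categories from labels: `unlabeled` (strictly less than half labeled
for studies of ≤ 60 samples; strictly fewer than 30 labeled for larger
ones), then `female-only`/`male-only`, then `mostly-*` above a strict 80%
cutoff among male+female labels, else `mixed`. Pooled-sample labels count
as labeled for the unlabeled rule but not toward the sex proportion; a
labeled study with only pooled labels is categorized `mixed`.

ATC enrichment runs two 2×2 chi-squared tests per class (male-only vs
female-only, and single-sex vs mixed, where "mixed" includes the mostly-*
categories since those studies contain both sexes) against the *other
classified study–class pairs* — studies mapped to no class are not a
comparison population. No Yates correction (the ≥ 5 count filter already
guards small cells; switchable). The Bonferroni denominator defaults to the
number of tests actually run, with a fixed-n option (e.g. 48) for fidelity
to a pre-registered test count. Per-drug profiles flag a drug as sex-biased
with ≥ 3 categorized studies, one single-sex fraction > 2/3 and the other
< 1/3.

## 5. The synthetic world

`generate_corpus()` draws, per study: a size in [10, 20], a platform, and
flags for single-sex (30%, half female-only), cell-line origin (10%), and
drug treatment (30%). Per sample, expression is
`base_g + effect + batch_{study,gene} + noise` with Y-gene base 1 and
effect +4 log2 units in males, X-escape base 6 and effect +1 in females,
batch SD 0.5 and noise SD 0.5 — a strongly separable world, as real
corpora are for these genes. Metadata sex is the truth except for 3%
flipped labels (swaps) and 30% missing; pooled samples (1% of mixed-study
samples) mix the sex profiles with u ~ Uniform(0.2, 0.8) — the real
composition of pooled samples is unreported, so the uniform mixture is an
explicit assumption. Cell-line samples inherit the donor sex; half of the
male-donor lines carry Y loss, silencing Y genes in half of their samples.
RNA-seq mode exponentiates and Poisson-samples counts at a configurable
depth (with an optional low-depth fraction to exercise the 100,000-count
filter); microarray mode stays continuous and is passed through untouched,
matching upstream-normalized compendia. Ground truth is returned (and
written) separately from everything pipeline stages read.

What the generator does **not** emulate: probe-level microarray structure,
platform-specific gene panels, sequence-level effects, correlated
gene-gene noise, tissue heterogeneity, or adversarial metadata text. A
green test therefore establishes that the machinery is correct and
calibrated in the regime the method assumes — not that real-corpus accuracy
numbers transfer.

## 6. Numerical choices and degenerate inputs

* Box-Cox is fit per gene (that is how features enter the model) by
  golden-section maximization of the profile log-likelihood over
  λ ∈ [−2, 2] (tests cross-check a Δλ = 0.01 grid); vectors containing
  zeros get a +0.5 offset; constant vectors are returned unchanged with
  λ = NA. For symmetric data with small coefficient of variation the
  profile likelihood is nearly flat in λ — the fitted λ can sit far from 1
  while the transform stays essentially affine.
* The low-count filter keeps the boundary (removal is "fewer than"), is
  idempotent, and refuses (with a warning) to run on microarray data.
* All randomness flows through explicit `seed` arguments; `with_rng_seed`
  saves and restores the caller's RNG state, so same config + seed means
  byte-identical outputs (asserted file-level in tests). The pipeline
  derives per-stage seeds as `seed + stage index` and logs them in the
  manifest.
* Pipeline configs serialize to JSON (no YAML parser is assumed in the
  runtime environment); unknown keys are rejected before any stage runs.

## 7. Known limitations

* The elastic-net fit itself is delegated to `glmnet`; the package owns
  the percentile selection rule, fold construction, and calibration
  around it.
* The mixture's prior *form* is a substitute for an unpublished one; only
  the scale is treated as normative.
* Consensus calling ships with a generic two-cluster baseline, not
  re-implementations of published external labelers.
* Entity matching is exact/n-gram only — no edit-distance or contextual
  disambiguation; heavily abbreviated or multilingual metadata will be
  missed.
* Scores are calibrated against metadata, which itself contains errors;
  all "accuracy" on real data is concordance, not truth.
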