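---
title: "Immune microenvironment subtyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune microenvironment subtyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Bulk tumor transcriptomes mix malignant cells with a variable immune and
stromal infiltrate, and that infiltrate — not any single marker — governs
both prognosis and the response to immune-checkpoint blockade (ICB).
`tmesubtype` implements a complete subtyping pipeline for this setting:
tumors are described by the abundance of 64 immune/stromal cell populations
(as produced by deconvolution tools such as xCell), grouped into four
recurrent immune subtypes, and new samples are assigned to those subtypes by
correlation to subtype centroids. The subtypes carry the biology the field
repeatedly finds in colorectal tumors: a low-infiltration "immune desert"
(C1), a stromal/fibroblast-high class (C2), an immune-high class with
cytotoxic T cells, PD-L1 and tertiary lymphoid structures (C3), and an
ion-channel-dominated class (C4). Around the subtypes sit the quantitative
companions used to interrogate ICB response: signature scores (TLSscore,
FTBRS, TFRscore), single-sample enrichment, exact contingency tests and
survival statistics.

# Subtype discovery: consensus clustering

Discovery follows the Monti resampling procedure. Abundance profiles are
first z-scored per cell type across the cohort (`zscore_features()`, sample
SD with the $n-1$ denominator; constant features map to zero so they drop
out of correlation distances). Then, for each of `iterations` runs, a
fraction `subsample_fraction` of the samples is drawn without replacement
and partitioned by PAM (k-medoids) under the distance

$$d(i,j) \;=\; 1 - \operatorname{Pearson}(\mathbf{z}_i, \mathbf{z}_j),$$

and the consensus matrix records, for every pair, the fraction of
co-sampled runs in which the pair co-clustered. Final labels come from an
average-linkage hierarchical cut of $1 - \text{consensus}$ into $k$
groups — the standard consensus-to-labels step. Defaults are 100
iterations and an 80% subsample, the common defaults of consensus
clustering implementations; $k$ is a user parameter (the cohorts this
models are well described by $k = 4$) and `silhouette_sweep()` reports mean
silhouettes across candidate $k$ without making an automatic choice.

Numerical choices worth knowing:

* The inner k-medoids step is the canonical PAM build+swap algorithm, via
  `cluster::pam` on the precomputed dissimilarity.
* Pairs never co-sampled (possible at very low iteration counts) receive
  consensus 0 with a warning; the diagonal is forced to 1.
* Samples that are constant across features have undefined correlations and
  are rejected by name rather than silently dropped.
* Silhouettes (`silhouette_scores()`) use the same $1-$Pearson distance;
  singleton clusters score 0 by convention.

Subtype centroids are simply per-feature mean z-values within each subtype
(`compute_centroids()`), which is what makes the classifier portable across
cohorts.

# Subtype prediction with quality control

`classify_cohort()` z-scores the cohort being classified *within that
cohort* (abundance scores are only comparable after per-cohort
standardization; this also means classification of a new cohort never needs
the discovery data), correlates each sample with each centroid over the
shared features, and applies two QC rules before accepting the argmax
subtype:

* maximum correlation below `min_correlation = 0.15` → `UNCLASSIFIED`
  (reason `low_max_corr`);
* margin between the best and second-best correlation below
  `min_gap = 0.06` → `UNCLASSIFIED` (reason `low_gap`).

Both rules are strict "less than" comparisons, so a sample sitting exactly
at a threshold is assigned; an exact tie for the top correlation has margin
0 and is therefore unclassifiable. Centroid features absent from a cohort
are dropped with a warning as long as at least
`min_feature_overlap_fraction = 0.8` of the centroid features remain;
below that, classification errors out. Whether cohort z-scores should be
computed before or after removing eventually-unclassifiable samples is
genuinely open; we standardize on the full cohort, which is the only
option that does not make a sample's z-scores depend on other samples'
classification outcomes.

# Single-sample enrichment

Pathway characterization and signature-based abundance use a rank-based
running-sum score (`ssgsea_scores()`). Within each sample, genes are ranked
(average ranks on ties) and walked from highest to lowest expression;
in-set steps add $r^\alpha$ (normalized over in-set weights), out-of-set
steps subtract $1/n_{\text{out}}$, and the score is the signed area of the
walk — positive area minus negative area. This preserves the
difference-of-deviations semantics of `mx.diff`-style GSVA scoring while
depending on the data only through within-sample ranks, so scores are
invariant to monotone transforms of expression — the right property when
scores are consumed ordinally (top-10 pathway ranking, between-group
tests), which is how this pipeline uses them. The kernel-density scoring
of GSVA proper is deliberately not reproduced. `alpha` defaults to 0.25,
the conventional weight of the running-sum variant; `alpha = 0` gives the
unweighted zero-sum walk under which a set and its complement score exact
negatives.

Subtype marker pathways (`subtype_marker_pathways()`) are ranked
one-vs-rest: a pathway is subtype-specific when all its pairwise rank-sum
comparisons against the other subtypes survive BH adjustment (applied
across pathways within each contrast) below 0.05 *and* its mean enrichment
is highest in that subtype; the top 10 by within-subtype mean are
reported. The rank-sum test replaces a moderated linear model because it
is distribution-free and the pathway scores have no error-model to
moderate; the subtype mean (rather than median) defines "maximum
enrichment", a choice the source material leaves ambiguous.

# Signature scores

* **TLSscore** — the unweighted mean of the 7 tertiary-lymphoid-structure
  marker genes CCL19, CCL21, CXCL13, CCR7, CXCR5, SELL, LAMP3.
* **FTBRS** — the mean of a 19-gene pan-fibroblast TGF-β response
  signature. The published gene list is an input, not a bundled constant;
  tests use synthetic panels.
* **TFRscore** — a centroid-discriminant score for follicular regulatory
  T-cell (Tfr) activity relative to conventional Tregs. The DEG panel and
  the two group centroids come from `derive_two_group_centroids()` (gene-wise
  rank-sum tests with BH control and a mean-log2-difference floor — a
  rank-based replacement for a negative-binomial DEG model, chosen because
  the consumers only need a stable discriminative panel, not calibrated
  fold-change inference). The score itself is
  $\rho(\mathbf{z}, \mathbf{c}_{\text{Tfr}}) -
   \rho(\mathbf{z}, \mathbf{c}_{\text{Treg}})$ on cohort-wise z-scored
  expression over the panel. The exact algebraic form of the published
  centroid score is not restated in the source material, so two standard
  kernels are implemented — correlation-difference (default) and
  normalized-euclidean-distance-difference — and the choice is an explicit
  parameter rather than a silent guess. Both are antisymmetric under
  swapping the centroids. Z-scoring is within-cohort, consistent with the
  classifier.

For survival stratification, `dichotomize_score()` cuts at an empirical
quantile (default 66.66%, linear interpolation) with values exactly at the
cut going to "low", matching the strict-greater-than convention.

# Statistics

Association between subtype and categorical outcomes uses the Pearson
chi-square without continuity correction (the r×c statistics this must
match come from uncorrected tests; keeping 2×2 uncorrected keeps all
shapes on one statistic), switching to the exact Freeman–Halton test when
any expected cell is below 5. The Freeman–Halton test enumerates every
margin-fixed table, summing the multivariate hypergeometric probability
of all tables at most as probable as the observed one; a relative
tolerance of $1+10^{-7}$ guards floating-point ties, enumeration is capped
(default $2\times10^5$ tables) and beyond the cap a Monte Carlo estimate
over Patefield-sampled tables is returned with its standard error. On 2×2
tables the enumeration reduces exactly to the classical two-sided
hypergeometric test, which the test suite verifies exhaustively for all
tables with $N \le 12$.

Kaplan–Meier curves and the k-group log-rank test are implemented natively
(product-limit estimator with censoring-after-events at tied times; the
log-rank quadratic form drops the last group and inverts the summed
hypergeometric covariance), and are cross-checked in the test suite
against `survival::survfit`/`survdiff` and a brute-force
observed-minus-expected oracle. Cox regression is deliberately delegated
to `survival::coxph`. Kruskal–Wallis and BH adjustment wrap the standard
implementations behind validating interfaces, with configurable post-hoc
pairwise rank-sum comparisons — the source material's post-hoc procedure
is unstated, so it is a parameter.

Unclassifiable samples are excluded from response tables and survival
comparisons; how such samples should enter survival models is unstated in
the source material, and exclusion is the only choice that keeps the
subtype factor well defined.

# The synthetic cohort generator

Every downstream stage is exercised on cohorts from `cohort_spec()` /
`generate_*()`, which emulate exactly the statistical structure the
analyses assume:

* **Abundance**: four subtypes, each with its own contiguous block of 16
  of the 64 cell types elevated by `separation` (in within-subtype SD
  units), unit-variance Gaussian noise. Noise is generated directly on the
  z-like scale because every consumer z-scores abundances first — only the
  post-standardization geometry matters. Subtype counts are fixed by
  largest-remainder rounding of the proportions, so margins are a
  deterministic function of the spec.
* **Expression**: signature-gene blocks (TLS, FTBRS, Tfr-up, Treg-up)
  shifted up by `separation` in their designated subtype — TLS and Tfr-up
  in the immune-high C3, FTBRS and Treg-up in the stromal C2 — over a
  Gaussian filler background.
* **Clinical**: response is Bernoulli with per-subtype rates defaulting to
  21/88, 7/64, 20/60 and 9/39 — the ICB response pattern these subtypes
  show; survival is exponential with per-subtype hazard ratios defaulting
  to (1, 3.239, 0.921, 1.660) against a baseline hazard of 0.02/month,
  the reported recurrence pattern; censoring is administrative-uniform
  with the window solved numerically to hit the target censor fraction
  (default 20%, a realistic follow-up loss for these cohorts).
* **Paired transitions**: `generate_paired_transitions()` realizes a 4×4
  pre/post-treatment transition table *exactly* (default: the 20-pair
  table with pre margins 9/3/3/5 and post margins 4/9/4/3), drawing each
  member of a pair from its designated subtype profile.

What the generator does **not** emulate: gene–gene correlation beyond the
signature blocks, batch and platform effects, probe-level artifacts,
non-exponential hazards, or dependence between response and survival.
Passing tests therefore demonstrate that the machinery is correct under
its own model assumptions, not that real cohorts will separate as cleanly;
on real data the unclassified fraction (about 16% in the cohorts this
emulates) and the subtype recovery will be worse than the synthetic
figures.

# Problem sizes and reproducibility

The test suite and the acceptance script run at deliberately desk-scale
sizes: discovery cohorts of 200 samples × 64 cell types with 100
resampling iterations, 500-replicate response simulations, 200-replicate
null calibrations for the log-rank test, exhaustive oracle sweeps up to 8
genes (enrichment) and table totals of 12 (exact tests). These sizes give
tight Monte Carlo error on every reported quantity while keeping a full
run in minutes on one core. All generators and the pipeline driver are
pure functions of their seed; `run_pipeline()` derives per-stage seeds
deterministically from the one run seed so stages can be re-run
independently, and writes an MD5 manifest so reproducibility is checkable
end to end.

# Known limitations

* The classifier assumes cohort-level z-scoring is meaningful, i.e. the
  cohort is reasonably heterogeneous; it will misbehave on a cohort of
  near-identical samples (by design these become unclassifiable).
* The enrichment score is a rank-based stand-in: it preserves ordering and
  group contrasts but will not numerically match kernel-density GSVA or
  xCell scores.
* The exact test's enumeration grows combinatorially with table margins;
  large sparse tables silently switch to Monte Carlo (with reported SE).
* The TFRscore kernel is a documented choice between two plausible forms,
  not a reproduction of a published formula.
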