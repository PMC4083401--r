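---
title: "The Clinical Outcome score: model, null distribution, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Clinical Outcome score: model, null distribution, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coscore)
```

`coscore` scores how a feature's (gene's or exon's) expression associates
with patient outcome across a multi-cohort transcriptome meta-dataset, and
implements the filtering stages that surround such a score in a
target-discovery pipeline. This vignette explains the statistical model,
the procedure's tunable parameters, what the synthetic-data generator does
and does not emulate, and the design decisions taken where more than one
reasonable construction existed.

## The scoring model

### Dichotomization

For a single feature, expression values across samples are split into two
clusters by 2-means and the cluster with the higher median is labelled UP.
In one dimension, any partition minimizing the within-cluster sum of
squares is a *threshold* partition of the sorted values, so
`kmeans_dichotomize()` scans all admissible splits of the sorted vector and
returns the global optimum exactly. This removes the two pathologies of
Lloyd-style k-means in this setting — dependence on random initialization
and convergence to local optima — and makes the entire downstream score
deterministic. Ties between equally good splits are broken toward the
larger DOWN cluster; clusters with equal medians (possible with heavily
tied data) are treated as unscorable and the feature is skipped with a
recorded reason. A single sample may form a cluster by itself
(`min_cluster_size = 1`): in real cohorts strongly right-skewed markers do
produce tiny high-expression clusters, and excluding them silently would
bias the screen; the parameter is exposed for sensitivity analyses.

### Censored exponential survival comparison

Follow-up within each label group is modelled as exponential with constant
hazard λ, right-censored. With d events and total exposure T the MLE is
λ̂ = d/T and the profile log-likelihood is ℓ = d·log λ̂ − λ̂·T =
d·log(d/T) − d. The UP/DOWN difference is tested by the likelihood-ratio
statistic

LRT = 2(ℓ_UP + ℓ_DOWN − ℓ_pooled),  P_true = P(χ²₁ ≥ LRT).

A likelihood-ratio test was chosen over Wald or score forms because the
comparison is exactly a nested-model comparison (two rates vs one), and the
LRT is parameterization-invariant — it inherits the procedure's invariance
to rescaling all times by a constant, so cohorts reporting follow-up in
different units need only a linear conversion. The exponential model's
constant-hazard assumption is strong but deliberate: with aggressive
disease and administrative censoring it captures the rate difference that
matters for ranking, is estimable in closed form inside a 10⁴-iteration
permutation loop, and never fails to converge.

Two degenerate situations have declared conventions. A group with zero
events contributes 0 to the log-likelihood (its likelihood supremum as
λ → 0 is 1), keeping the LRT finite — small UP clusters will hit this
regularly. Follow-up times equal to 0 are replaced by half the smallest
positive time in the dataset, with a warning; leaving them at 0 would
corrupt the exposure sum, and the choice of convention only matters in
cohorts recording events at the enrolment visit.

### The permutation/subsampling null and the CO score

P_true alone overstates certainty: the dichotomization threshold was chosen
by looking at the same data, and survival p-values can hinge on a handful
of patients. The null distribution is therefore built by repeating, n times
(default n = 10000, `n_repetitions`): remove ⌊0.10·n_samples⌋ samples
uniformly at random without replacement (`removal_fraction = 0.10`), permute
the observed UP/DOWN labels among the retained samples, and recompute the
significance P*. The CO score is the empirical permutation p-value

CO = #{ i : P*ᵢ ≤ P_true } / n_effective ∈ [0, 1],

where n_effective counts repetitions that produced a scorable null model
(a repetition whose subsample loses one label group entirely is dropped,
not imputed). Small CO means the observed association is more significant
than essentially every relabelled subsample — an association that is both
strong and stable under cohort perturbation. The complement 1 − CO is
emitted as a secondary column (`co_complement`) so the score can also be
read as "fraction of null models beaten". The default reporting threshold
flags CO < 0.05 as significant; it is a configurable label, not a
multiple-testing-corrected decision rule — no correction across features is
applied at this stage, because the score's role is ranking a pre-filtered
candidate list that is then required to replicate in an independent
validation split.

Three further constructions were open and are fixed as follows:

* **Label randomization** permutes the observed label vector among retained
  samples, preserving the UP/DOWN proportions — the standard
  exchangeability-preserving choice. An i.i.d. Bernoulli relabelling mode
  (`iid_relabel = TRUE`) is available; it adds variance in the group sizes
  and makes the null slightly heavier-tailed.
* **P_true is computed once on the full sample.** A per-subsample mode
  (`per_subsample_p_true = TRUE`), in which each P*ᵢ is compared against the
  observed-label significance of its own subsample, is provided for
  sensitivity analysis.
* **Randomization is joint**: each repetition draws a fresh subsample *and*
  a fresh permutation, rather than alternating pure-permutation and
  pure-jackknife phases.

### Reproducibility

A master seed lives in `score_config()`. Every feature × endpoint
combination derives its own RNG sub-stream by hashing the feature id and
endpoint name into a 31-bit seed, so results are independent of the order
in which features are scored and of how many features a table contains;
with a fixed configuration the output tables are byte-identical across
runs. Scoring is also invariant to affine transforms of the expression
values, since the dichotomy depends on the values only through the
threshold-split geometry.

## Candidate, fusion, and cohort stages

**Differential-expression filters** consume result tables from standard DE
engines (an upstream adapter only needs to provide `feature_id`, `log2fc`,
`fdr`). Thresholds are strict inequalities at the conventional values
FDR < 0.1 and log2FC > 1; rows sitting exactly on a boundary are excluded,
and the synthetic DE generator plants such rows to pin the semantics. The
exon-level filter collapses qualifying exons to genes; whether the
fold-change criterion applies at exon level in addition to FDR is exposed
(`use_lfc`, default `TRUE`).

**Fusion post-filtering** reasons at the level of ordered (5′, 3′) gene
pairs — upstream callers emit many breakpoints per pair and the biology of
the artifact classes lives at pair level. The filter keeps pairs reported
in every tumor replicate, removes pairs reported in *any* wild-type
replicate (the conservative reading of control subtraction), and classifies
the remainder: *read-through* if the partners are on the same chromosome
and strand, non-overlapping, in transcriptional order, and separated by at
most `readthrough_max_gap` (default 200 kb — a declared convention, since
no standard definition exists; an `adjacent_only` mode additionally forbids
intervening same-strand genes); *homologue pair* if the partners share a
homology group in the annotation (an input table — no sequence alignment is
performed, keeping the package self-contained). Calls with partners missing
from the annotation are kept and flagged rather than silently dropped.

**Cohort harmonization** deduplicates samples (conflicts resolved by a
cohort priority order and reported), maps each cohort's raw outcome fields
onto standardized survival/metastasis records via a user-editable mapping
(field names, event coding, time unit — converted to months), and splits the
meta-dataset into test and validation groups *by whole cohort* on
publication year (threshold 2009 by default). Cohort-level splitting is
essential: a within-cohort split would leak batch structure into both
groups and make "replication" circular. Every standardized record carries a
provenance column naming the raw fields it came from. Cross-platform
expression integration (probe remapping, normalization) is out of scope;
scoring is per-dataset, so expression only needs to be comparable within a
dataset.

## The synthetic cohort generator

`generate_cohort()` emulates exactly the structure the scoring model
assumes, plus ground truth: per-feature expression is a two-component
Gaussian mixture (components separated by `mixture_delta` log2 units,
common `mixture_sd`, high-component frequency `frac_up`), and event times
are exponential with hazard `baseline_rate` for low-risk samples and
`baseline_rate × hazard_ratio` for high-risk ones, censored at a fixed
horizon `censor_time`. All *true* features share a single latent risk
partition (their mixture membership *is* that partition); null features
draw independent memberships, making their expression exactly independent
of outcome. One latent partition, rather than per-feature outcome draws,
keeps a single coherent clinical table per endpoint while making every true
feature informative.

Defaults are chosen to be realistic for an aggressive-cancer cohort:
expression on a log2 scale around 6 with unit within-component standard
deviation and a 4-unit component separation; events at 0.02 per month with
a 60-month horizon (≈70% event fraction for low-risk samples); 30% of
samples in the high-expression component; hazard ratio 4 for true targets.
Time units are abstract months — the procedure is scale-invariant, so only
the product rate × horizon matters. Censoring is administrative (fixed
horizon): the simplest mechanism that exercises the censored MLE. Samples
are spread over three synthetic cohorts with publication years 2006, 2008
and 2012 so the year-threshold split produces a ~70/30 test/validation
partition, mirroring the shape of real multi-cohort compendia.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: platform and batch effects between cohorts,
non-Gaussian and correlated expression across genes, non-constant hazards,
informative censoring, competing risks between metastasis and death, and
missing or misrecorded clinical annotation. Results on synthetic data
validate the *machinery* (calibration under the null, power under the
stated effect size, determinism), not the biology of any particular cohort.

Companion generators plant fixtures for the other stages:
`generate_fusion_fixture()` lays out genes so that read-through pairs are
adjacent same-strand genes and homologue pairs share a family tag, and
returns the exactly expected retained set; `generate_de_table()` plants
pass/fail rows including exact-boundary rows.

## Numerical choices and edge cases

* Within-cluster sum-of-squares comparisons use a relative tolerance of
  10⁻¹²; admissible splits never separate tied values, so the partition is
  always a clean threshold partition.
* The LRT is clamped at 0 (nested models; tiny negative values can arise
  from floating-point cancellation) and compared against χ²₁.
* CO has granularity 1/n_effective; with the default 10⁴ repetitions this
  is far below any reporting threshold, but calibration tests against a
  continuous uniform must expect ties.
* Degenerate features (constant expression, equal-median clusters, no
  admissible split) are skipped with machine-readable reasons collected in
  the output's `skipped` attribute — on real data such features are common
  and a hard failure would be wrong.

## Problem sizes in the shipped checks

The test suite and the acceptance script exercise the pipeline at sizes
chosen to make the statistical checks sharp while keeping a full run in the
tens of seconds: null calibration over 200 features × 200 samples at 500
repetitions; power/recovery over 50 replicates of a 10-feature, 300-sample
cohort with two planted hazard-ratio-4 targets at 500 repetitions; the
1-D 2-means solver against an exhaustive oracle on 1000 random vectors. The
defaults users see (`n_repetitions = 10000`) match the intended production
setting, not the test setting.

## Known limitations

The exponential model ranks features by average hazard contrast and will
under-weight late-diverging or crossing survival curves. The CO score is a
ranking statistic, not a calibrated error rate across features. Homology
and compartment annotation are inputs, trusted as given. And the
test/validation replication logic requires honest cohort-level metadata —
publication year standing in for independence of data collection.
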