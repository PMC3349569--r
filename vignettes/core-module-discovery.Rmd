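---
title: "Core-module biomarker discovery across expression cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core-module biomarker discovery across expression cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coremod)
```

## The problem

Gene signatures derived from single expression cohorts reproduce poorly:
signatures fitted on different breast-cancer cohorts famously share only
a handful of genes. A common interpretation is that each cohort's
differentially expressed genes (DEGs) are dominated by *passenger*
genes — downstream, cohort-specific consequences of disease — while the
*driver* genes and their first-degree interaction neighbours (the
disease *core module*) change consistently everywhere but are a
minority of the DEG list. `coremod` implements a pathway-based pipeline
for isolating that core module from several case/control cohorts:

1. summarize each pathway as a per-sample **pathway activity** (PA)
   inferred on one cohort,
2. keep only activities whose discriminative power **reproduces** in
   the other cohorts, using ensemble feature elimination against the
   validation cohort's labels,
3. intersect selections over every ordered inference/validation pair to
   assemble the core module, and
4. identify **driver genes** as core-module genes that are hubs of the
   gene-interaction subnetwork induced on the module.

## Pathway-activity inference

All inference operates on per-cohort z-scores: each gene row is scaled
to mean 0, sample sd 1 over all samples of that cohort (cases and
controls pooled). Z-scores are recomputed per cohort rather than frozen
from the inference cohort, because independent cohorts are measured on
heterogeneous platforms where raw scales do not transfer.

The core-module inference (CMI) activity of a pathway is built from its
DEGs only (two-tailed pooled-variance t-test, p ≤ 0.05 by default).
DEGs are ranked by descending |t|, and for each prefix of size *j* the
candidate activity of sample *s* is

$$P_j(s) = \frac{1}{j}\sum_{i\le j} z_i(s)\,\mathrm{sign}(t_i),$$

so up- and down-regulated genes reinforce one another. The retained
member count *K* maximizes the two-sample t-score of $P_j$ over the
inference cohort's labels, with ties resolved toward the smallest *j*
and membership capped at 20 DEGs. Because every admissible prefix is
evaluated, the search is exhaustive over the ranked list, not greedy.
The signed t-score maximized is the natural objective here since
sign-alignment makes the constructed activity's t positive whenever any
member discriminates; in the degenerate case where every prefix scores
non-positive we fall back to the largest |t|.

Two implementation choices deserve a note. The prefix normalizer is
*j* (an average). The condition-responsive-gene (CORG) comparator uses
the $\sqrt{j}$ convention of its original formulation, grows members
greedily (stopping at the first non-improving addition), and is
restricted to the up- *or* down-regulated subset, whichever wins —
which is exactly what makes it blind to pathways with coherent signal
in both directions. A `divisor = "sqrt_j"` switch is available for CMI
as well. Second, gene ties in |t| are broken by gene id so inference is
deterministic.

The remaining comparators (MEAN, MEDIAN, first-principal-component
PCA, per-gene Gaussian log-likelihood-ratio LLR, and the no-inference
GENE method) summarize *all* pathway genes and are provided for
benchmarking. PCA orientation is fixed so the inference t-score is
non-negative; LLR class variances are floored at $10^{-6}$ to keep
log-densities finite.

A fitted model freezes its members, signs, normalizer and parameters;
projecting it onto another cohort only re-reads that cohort's z-rows.
Members missing from a target cohort are dropped with a warning and the
normalizer adjusts to the survivors — preferable to failing outright on
partially overlapping platforms, but reported loudly because it changes
the activity's variance.

## Reproducibility score

For activities ranked by inference t-score, the reproducibility of an
(inference, validation) pair at depth *N* is

$$\mathrm{Cscore}(N) = \frac{1}{N}\sum_{i=1}^{N}
  t(P^I_i)\; t(P^V_i),$$

the mean product of each activity's t-scores in the two cohorts.
Direction agreement is rewarded, reversal penalized; the overall value
averages all ordered pairs (six for three cohorts). Sign-aligned
constructions (CMI, CORG) are ranked by signed t; methods whose
activities can point either way (MEAN, MEDIAN, PCA, GENE) are ranked by
|t| with the sign carried in the product, which preserves the penalty
for direction reversal. LLR is excluded from these comparisons because
its activity is a log-likelihood, not a statistic in the expression
space the score assumes.

## Consensus feature elimination

Classifiers are linear, $D(x) = w\cdot x + b$: Fisher LDA with a
Ledoit–Wolf shrinkage estimate of the pooled covariance (activities are
often collinear; the shrinkage intensity also has a floor of $10^{-6}$
so a feature that is constant within classes cannot make the system
exactly singular), or a soft-margin linear SVM via `e1071` with the
primal weights extracted. AUC is the Mann–Whitney probability with the
midrank tie convention.

At each elimination step, 100 stratified 5-fold splits yield 500 fits;
each feature is scored by its mean squared weight over the 500 weight
vectors and the weakest feature removed, down to a single feature. The
retained set is the one with maximal mean held-out AUC (ties toward
fewer features). Stratification is used because the cohorts this
method targets are class-imbalanced and unstratified folds can lose a
class entirely. Because the maximum of the trajectory is not always
unique in the feature sets it selects, the whole procedure is repeated
(100 times by default) with derived seeds and the most frequent exact
set is kept; per-feature selection frequencies are reported as a
stability diagnostic. All randomness flows from one integer seed, so
runs are bit-reproducible.

A caveat worth stating plainly: the mean AUC trajectory is evaluated by
cross-validation *inside* the cohort that also drives the elimination,
so it is optimistically biased — under a pure-noise input the maximum
of the trajectory concentrates around the in-sample AUC of the most
spuriously class-correlated feature (about 0.65–0.8 for 20 features at
n = 60), not around 0.5. This selection bias is inherent to recursive
feature elimination assessed internally and is the reason the pipeline
never interprets the CFE AUC as an unbiased accuracy estimate; the
cross-cohort intersection step below is what provides the real control
against spurious selections.

## Assembling the core module

For every ordered cohort pair, the top 100 activities by inference
t-score are projected onto the validation cohort and CFE is run against
the validation labels. A pathway inferred from cohort *D* becomes a
core marker only if it is selected against **every** other cohort —
the strictest reading of "reproducible in all cohorts"; the provenance
of each marker (inference cohort, validation partners) is retained so
looser unions can be audited. Core genes are the union of member genes
of core markers, annotated per cohort with the sign of their t-score:
`up` or `down` when all cohorts agree, `contradictory` otherwise
(a zero t counts as no direction).

Enrichment of a signature against a reference gene list uses the
strict hypergeometric upper tail $P(X > K)$ over the study universe
(genes shared by all cohorts and present in the filtered pathway
collection); the conventional $P(X \ge K)$ is a flag away, and no
multiple-testing correction is applied across reference lists by
default (a Bonferroni option exists). Hubs of the core-module
subnetwork are the top-k nodes by confidence-weighted degree (k = 20 by
default, configurable since "highly connected" has no canonical
cutoff); drivers are hubs intersected with the common marker genes.

## Pathway filtering

Pathway collections are read from GMT files, intersected with the
genes shared by all cohorts, and pruned to sizes in [5, 200] by
default. The upper bound removes bulky catch-all pathways (several
hundred genes) whose activities blur submodule-level signal; the lower
bound removes sets too small to aggregate. Both bounds are exposed
because no published cutoff exists for "bulky".

## The synthetic study generator

`simulation_config()` encodes the study conditions used throughout the
tests: 3 cohorts of 100 samples (50% cases), 600 genes, 50 pathways of
8–15 genes, 5 driver pathways each with 5 member genes shifted by
0.8 sd in cases with one shared sign per gene across cohorts, 25
cohort-private passenger DEGs (disjoint across cohorts, placed outside
driver pathways but inside ordinary pathways, shifted 0.8 sd in their
own cohort only), unit Gaussian noise, and an interaction network in
which driver genes receive 30 extra random edges over a sparse
(mean degree 4) background. The 0.8 sd effect on 5 member genes at
n = 100 gives each driver activity a standardized effect near 1.8 —
strong but not trivial, comparable to what pathway aggregation achieves
on real prognostic cohorts; passengers are given the same per-gene
effect so that cross-cohort consistency, not effect size, is what
separates drivers from passengers. A heavier-tailed Student-t noise
option exists for robustness checks.

What the generator deliberately does *not* emulate: platform/batch
effects, probe-level artefacts, missing values, correlated background
expression, or class imbalance. Passing tests on this generator
therefore demonstrate the machinery (selection, intersection, scoring)
under the method's own assumptions, not robustness to real microarray
pathology.

## Problem sizes and numerical choices

The test-suite and acceptance runs use scaled-down ensembles
(8–25 splits, 3–5 repeats instead of 100/100) — at the planted effect
sizes the selections are already stable at these ensemble sizes, and
the full-size defaults remain in the API. Other numerical decisions:
zero-variance genes are z-scored to all zeros (kept, with a warning, so
cohort universes stay aligned); pooled-variance t is the default test
(Welch behind a switch) since degrees of freedom are then deterministic;
`which.max` tie-breaks systematically favour the earliest/smallest
candidate; and all derived seeds are drawn below $2^{31}$.

## Worked example

```{r example, eval = FALSE}
study <- simulate_study(simulation_config(seed = 1))
run <- run_study(study$cohorts, study$pathways,
                 top_n = 50, n_repeats = 3, n_splits = 8,
                 network = study$network, seed = 1)
run$core
run$core$marker_pathways
head(run$core$core_genes)
```

On the default simulated study this recovers all five planted driver
pathways and rejects every passenger-containing pathway (the exact
numbers for a given seed are computed by `scripts/acceptance.R`).

## Known limitations

* The CFE AUC is internally cross-validated and optimistic (see above);
  only the cross-cohort intersection confers specificity.
* Core assembly is all-or-nothing per inference cohort; a pathway
  reproducible in most but not all validation partners is discarded.
* Gene identity is exact symbol matching; no identifier translation.
* Two-class phenotypes only; no survival or multi-class support.
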