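---
title: "Genetic phenotypes of drug targets and clinical side effects: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic phenotypes of drug targets and clinical side effects: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetsafety)
```

# The analysis in one paragraph

A drug's intended target is a protein whose gene may carry phenotype
annotations from two kinds of natural experiment: Mendelian syndromes and
genome-wide association studies. This package asks whether those
annotations predict the organ systems in which the drug shows side effects
in clinical trials. The unit of analysis is the drug x organ-system pair,
with organ systems fixed to 21 MedDRA system-organ-class (SOC) categories.
Each pair gets a genetic-support level, a side-effect flag, and an
on-indication flag; on these the package computes enrichment statistics,
permutation nulls, per-organ regression models, and a grouped
cross-validation that quantifies the predictive value genetics adds over
everything else.

# Genetic support encoding

For one drug, one organ system, and one source (Mendelian or GWAS):

* `MATCH` — at least one target gene has a phenotype in that SOC;
* `MISMATCH` — no target matches, but at least one target has phenotypes
  in *other* SOCs (the absence of a match is informative);
* `NO_INFO` — no target carries any phenotype from that source.

`any_support` is a MATCH from either source; it drives the enrichment
analyses. A separate flag, `all_targets_informative`, records whether
*every* target gene carries some genetic information from either source.
The two notions deliberately coexist: MISMATCH requires only one
informative target, while the de-risk split conditions on full
informativeness, because a drug with an unannotated target may simply be
missing data rather than genuinely lacking phenotypes. Where the
regression's "no information" level is ambiguous in principle, we define
it as *no target has any information* (NO_INFO above); the stricter
alternative (some target uninformative) is representable via
`all_targets_informative` but is not the regression baseline.

# Enrichment statistics

Each analysis reduces to a 2x2 table `(a, b, c, d)` = (support & side
effect, support only, side effect only, neither). We report:

* the unconditional cross-product odds ratio ad/bc — not the conditional
  maximum-likelihood estimate, because the reference tables print the
  cross-product value;
* the Woolf interval exp(log OR ± z·sqrt(1/a+1/b+1/c+1/d)), z = 1.959964;
* the two-sided Fisher exact p by the probability-mass rule: the sum of
  hypergeometric point probabilities no larger than the observed one,
  within a relative tolerance of 1e-7 (the same convention as
  `stats::fisher.test`, which the tests use as an independent
  cross-check along with brute-force enumeration).

Zero cells leave the odds ratio at `Inf`/0 with an `NA` interval; a
Haldane-Anscombe +0.5 variant is available for interval display only, so
the primary estimator is never silently corrected. Per-category p-values
are reported raw, without multiplicity adjustment; the only multiplicity
control in the package is the conservative 0.05/18 threshold used when
*reporting* which regression models count as significant.

The de-risk split restricts to unsupported pairs and compares side-effect
rates between fully-informative target sets (mismatched genetics) and
target sets with at least one uninformative gene (possibly missing data).
An odds ratio below 1 means absent phenotypes in otherwise well-annotated
genes are themselves evidence of safety.

The treatment-versus-placebo arm filter applies a one-tailed Fisher test
in the treatment direction; an adverse event is drug-related when its
treatment-arm rate exceeds placebo with p < 0.05. The direction condition
is checked explicitly, so a significant *deficit* in the treatment arm is
never kept.

# Permutation nulls

Two structured randomisations address composition biases:

* **genetics**: the multiset of (Mendelian, GWAS) phenotype-set pairs is
  reassigned to gene ids by a uniform permutation. Keeping the pair
  together preserves the cross-source correlation, and permuting whole
  sets preserves both the fraction of uninformative genes and the set-size
  distribution. Whether the two sources should instead be permuted
  independently is not dictated by the analysis; we default to joint
  permutation (preserving more of the real structure makes the null
  stricter) and expose per-source permutation as an option. Permutation is
  restricted to genes that actually appear as drug targets.
* **side effects**: whole side-effect profiles are shuffled among drugs,
  preserving per-organ side-effect counts exactly.

Empirical p-values use the add-one convention (r+1)/(n+1), which never
reports zero and matches the "< 0.001 at 1000 permutations" floor.
Replicate seeds derive from one master seed, so runs are reproducible and
replicates order-independent.

# Regression models

Only organ systems with at least 100 affected drugs (18 of 21 in the
reference dataset) are modelled; sparser categories do not support stable
multivariate fits. Each model regresses the binary side-effect response on:
20 indication indicators (Neoplasm excluded — oncology indications were
excluded upstream, so the column would be structurally empty), modality
(small-molecule baseline), four non-exclusive route indicators (no
reference level is dropped; collinearity is tolerated by the penalised fit
and flagged by a condition-number warning in the unpenalised one), three
expression-breadth indicators (baseline `none_detected`), a constraint
indicator, and MATCH/MISMATCH indicators per genetic source (baseline
NO_INFO). A continuous-expression variant replaces the breadth indicators
with per-tissue means of log2(TPM+1) over the targets; the +1 offset is
our choice to handle zeros.

The lasso penalty is chosen by repeated cross-validation: a fixed
100-point log-spaced grid from the smallest all-zeroing penalty down by
1e-4, 10-fold AUC-scored cross-validation repeated 100 times, per repeat
recording lambda.min (AUC-maximal) and lambda.1se (largest penalty within
one standard error of the maximum, the SE taken across folds within that
repeat — the natural reading when each repeat is an independent CV), and
finally averaging the two means. Folds are stratified by response;
degenerate folds are refolded from a fresh substream.

# Leave-one-target-set-out cross-validation

Ordinary cross-validation would leak genetic information: two drugs
sharing a target share that target's phenotypes. The grouped procedure
enumerates each unique target set, holds out all drugs with exactly that
set, and trains on drugs sharing *none* of its genes. The per-fold model
is the full unpenalised logistic fit; pooled out-of-fold predictions give
one ROC AUC (Mann-Whitney with ties counted one half — tie handling is our
choice and is pinned against a brute-force concordance oracle in the
tests). The leakage invariant — no test-set gene among training drugs'
targets — is asserted programmatically on every fold of every run, not
just in tests.

Folds whose training set is empty, or whose training response is
single-class, are skipped and counted; their drugs contribute no
predictions. The permuted-genetics AUC null reuses the true folds, which
is exact here because fold structure depends only on target sets, never on
phenotypes. The fast per-fold solver is a Newton iteration on the
cross-product matrices with a vanishing (1e-10) ridge for rank-deficient
training subsets and a `glm.fit` fallback; the tests pin it to `glm.fit`
coefficients at 1e-10.

# The synthetic-data generator

The generator emulates the features of the real dataset that the analysis
logically depends on, under a single logistic generative model with no
overdispersion (matching the analysis model, so parameter recovery is a
clean end-to-end check):

```
P(side effect | drug i, SOC s) =
  logistic(alpha_s + beta_genetic * any_support(i, s)
           + beta_indication * on_indication(i, s) + covariate terms)
```

* per-SOC intercepts `alpha_s` default to baseline rates spread from 3% to
  35%, mirroring the wide spread of per-organ side-effect frequencies in
  trial data;
* drugs draw 1-3 targets with popularity weighting, and with probability
  `target_sharing` copy an earlier drug's entire target set, so both
  partial gene sharing and exact set sharing occur and the grouped CV is
  genuinely exercised;
* a configurable fraction of genes is uninformative per source (defaults
  0.5 Mendelian, 0.6 GWAS, in the neighbourhood of the roughly 60% of
  pursued targets with genetic information in the reference dataset);
* indication-genetics confounding is generated in the indication
  direction: with probability `confounding` a drug's indication is drawn
  from its targets' phenotype SOCs instead of uniformly. This is the
  simplest mechanism that reproduces the real correlation between
  indications and target genetics, and it leaves the uninformative-gene
  fractions exactly intact;
* default effect sizes (`beta_genetic` = log 1.5, `beta_indication` =
  log 2.5, confounding 0.25) are chosen once as a realistic regime in
  which the marginal enrichment exceeds the conditional genetic effect —
  the confounding narrative — without either vanishing.

One global random stream is consumed in a documented order (genes, then
drugs, then side effects), so a seed pins the catalogs byte-for-byte.

What the generator does *not* emulate: per-organ marginal frequencies of
any real dataset, drug chemistry, correlated side effects within a drug
beyond what covariates induce, reporting biases, or trial-size effects.
Passing tests on synthetic data therefore validate the statistical
machinery and its calibration, not the clinical conclusions one would
draw from real catalogs.

# Study conditions used in the checks

The test suite fixes these problem sizes as its study conditions:
calibration of the permutation test uses 500 null datasets of 250 drugs
with 99 permutations each; parameter recovery uses 50 datasets of 2000
drugs at a generative genetic log odds ratio of ln 2 (with GWAS silenced
so the Mendelian MATCH coefficient estimates the generative effect
directly, fit as a pooled per-SOC-intercept logistic model — the
generative model itself); the cross-validation contribution check uses 20
datasets of 800 drugs with 60% target-set sharing and a 99-replicate
permuted-genetics null. The Fisher implementation is checked against full
enumeration on 1000 random tables of total at most 40.

# Degenerate inputs and numerical choices

* Tables with a zero margin return Fisher p = 1; all-zero tables render
  as `NA` rates in reports.
* Constant-response designs error with a diagnostic rather than fitting.
* Perfect separation in the unpenalised fit warns and reports
  `converged = FALSE` with coefficients, rather than erroring, because
  separated fits still produce usable rankings in cross-validation.
* Permutation replicates that fail are dropped and logged; more than 10%
  failures abort the analysis.
* The flat observation table is the interchange format for pre-flattened
  datasets; reading it reconstructs `any_support` from the two support
  columns, and catalog input and flat input are tested to give identical
  results.

# Known limitations

The package consumes SOC-mapped data; ontology mapping, drug-name
normalisation, and database merging are out of scope. The de-risk and
per-source analyses need the respective strata populated and error
informatively otherwise. The cross-validation AUC is a conservative
measure of genetics' contribution: every other covariate is available to
the model first, so the increment attributable to genetics is a lower
bound on its marginal information.
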