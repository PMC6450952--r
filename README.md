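# targetsafety

Retrospective analysis linking the human-genetic phenotypes of drug-target
genes to the side effects drugs show in clinical trials.

## The problem

Most drug programs fail on safety or efficacy, and an unacceptable
side-effect profile often only surfaces in human trials. Natural genetic
variation in the gene encoding a drug target is a "natural experiment" on
that protein: if mutations in the gene produce phenotypes in some organ
system, pharmacological modulation of the protein may produce effects
there too. `targetsafety` implements, as a tested and reusable R package,
the statistical pipeline for asking whether that logic holds at scale:

- Drugs are annotated with their target genes, modality, delivery routes,
  pursued indications, and observed trial side effects; genes carry their
  Mendelian-syndrome and GWAS phenotypes. All phenotypes live in a fixed
  vocabulary of 21 MedDRA system-organ-class (SOC) categories.
- Every drug x organ-system pair is classified by **genetic support**:
  `MATCH` (some target gene has a phenotype in that organ system),
  `MISMATCH` (targets are informative but only for other organ systems),
  or `NO_INFO`.
- **Enrichment**: 2x2 tables of support x side effect per organ system and
  pooled, with the cross-product odds ratio OR = ad/bc, the Woolf interval
  exp(log OR ± 1.96·sqrt(1/a + 1/b + 1/c + 1/d)), and the two-sided Fisher
  exact test; an off-indication mode removes pairs where the organ is the
  intended site of action; a "de-risk" split asks whether informative but
  mismatched genetics predicts *fewer* side effects than missing genetics.
- **Permutation nulls** that randomise either gene-to-phenotype
  assignments or whole drug side-effect profiles, preserving the marginal
  structure, with add-one Monte-Carlo empirical p-values.
- **Per-organ regression**: logistic models of each side-effect class on
  indications, modality, routes, expression breadth, constraint, and the
  genetic-support indicators; a lasso variant selects features with a
  repeated 10-fold cross-validated-AUC rule for the penalty
  (mean lambda.min and mean lambda.1se averaged).
- **Leave-one-target-set-out cross-validation**: each unique target-gene
  combination is held out in turn and every drug sharing *any* of its
  genes is excluded from training, so genetic information never leaks;
  pooled out-of-fold predictions give a ROC AUC, compared against a
  no-genetics model and a 1000-fold permuted-genetics AUC null.
- A **synthetic-data generator** reproducing the dataset's statistical
  structure (per-organ baseline rates, a genetic effect on side-effect
  odds, indication-genetics confounding, shared target sets, uninformative
  genes) so the whole pipeline is testable without licensed databases.

## Worked example

```r
library(targetsafety)

# per-organ enrichment from the published reference counts
enrichment_from_counts(reference_soc_counts()) |>
  dplyr::filter(soc %in% c("Heart", "Endocrine", "Total")) |>
  dplyr::select(soc, a, b, c, d, odds_ratio, p_two_tailed)
#> # A tibble: 3 × 7
#>   soc           a     b     c     d odds_ratio p_two_tailed
#>   <chr>     <dbl> <dbl> <dbl> <dbl>      <dbl>        <dbl>
#> 1 Heart       145   176   451  1047       1.91     3.92e- 7
#> 2 Endocrine    97   252   177  1293       2.81     3.71e-12
#> 3 Total      2512  5862  5729 24096       1.80     1.73e-94
```

Drugs whose targets carry a cardiac genetic phenotype show cardiac trial
side effects at 45.2% versus 30.1% without such genetics (OR 1.91); pooled
over all 21 organ systems the rates are 30.0% versus 19.2% (OR 1.80,
95% CI 1.71-1.90). The same machinery runs on your own catalogs:

```r
sim <- simulate_catalogs(sim_config(n_drugs = 500, seed = 1))
obs <- build_observations(sim$drugs, sim$genes, mode = "off_indication")
enrichment_analysis(obs)          # pooled off-indication odds ratio
derisk_analysis(obs)              # mismatched vs missing genetics
permutation_test(sim$genes, sim$drugs, n_perm = 199, seed = 2)
loto_cv(sim$drugs, sim$genes, "Nervous")   # leakage-proof CV AUC
```

`run_pipeline()` chains every stage (enrichment, permutation, per-organ
models over the eligible categories, cross-validation) and writes a report
bundle; `autoplot()` draws forest, null-distribution, and ROC figures;
`tidy()`/`glance()` give broom-style access to fits and CV results.

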