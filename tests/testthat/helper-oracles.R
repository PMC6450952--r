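# Independent brute-force oracles used across tests. These enumerate by
# combinatorics (choose) rather than going through the distribution
# functions the implementation uses.

# Two-sided Fisher p by full enumeration of all tables with the observed
# margins: sum of point probabilities <= observed (with the standard
# relative tolerance).
brute_fisher_two <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  total <- choose(m + n, k)
  support <- max(0, k - n):min(k, m)
  probs <- choose(m, support) * choose(n, k - support) / total
  p_obs <- choose(m, a) * choose(n, k - a) / total
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Upper-tail Fisher p: P(A >= a) by term-wise summation.
brute_fisher_greater <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  total <- choose(m + n, k)
  support <- a:min(k, m)
  sum(choose(m, support) * choose(n, k - support)) / total
}

# AUC as the exact pairwise concordance fraction (ties count one half).
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  grid <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(grid)
}

# Random 2x2 table with total at most n_max.
random_table <- function(n_max = 40) {
  n <- sample.int(n_max - 3, 1) + 3
  cuts <- sort(sample.int(n + 1, 3) - 1)
  c(cuts[1], cuts[2] - cuts[1], cuts[3] - cuts[2], n - cuts[3])
}

# Small random catalog pair for property tests.
random_catalogs <- function(n_drugs = 8, n_genes = 6) {
  socs <- soc_categories()
  genes <- gene_catalog(
    gene_id = paste0("g", seq_len(n_genes)),
    mendelian_socs = replicate(n_genes, {
      if (runif(1) < 0.3) character(0) else sample(socs, sample.int(3, 1))
    }, simplify = FALSE),
    gwas_socs = replicate(n_genes, {
      if (runif(1) < 0.5) character(0) else sample(socs, sample.int(2, 1))
    }, simplify = FALSE),
    constrained = runif(n_genes) < 0.3,
    expression_breadth = sample(c("all", "mixed", "enriched", "none_detected"), n_genes, TRUE)
  )
  drugs <- drug_catalog(
    drug_id = paste0("d", seq_len(n_drugs)),
    targets = replicate(n_drugs, sample(genes$gene_id, sample.int(2, 1)), simplify = FALSE),
    modality = sample(c("small_molecule", "biological"), n_drugs, TRUE),
    routes = replicate(n_drugs, sample(c("enteral", "parenteral", "topical", "other"), 1), simplify = FALSE),
    indications = replicate(n_drugs, sample(socs, sample.int(2, 1)), simplify = FALSE),
    side_effects = replicate(n_drugs, sample(socs, sample.int(4, 1) - 1), simplify = FALSE),
    genes = genes
  )
  list(genes = genes, drugs = drugs)
}
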