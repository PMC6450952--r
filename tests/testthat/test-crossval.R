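mini_genes <- function(ids) {
  gene_catalog(ids,
    mendelian_socs = rep(list("Heart"), length(ids)),
    gwas_socs = rep(list(character(0)), length(ids))
  )
}

test_that("target-set folds exclude every gene-sharing drug from training", {
  genes <- mini_genes(c("g1", "g2"))
  drugs <- drug_catalog(c("d1", "d2", "d3"),
                        list("g1", "g1", "g2"), genes = genes)
  folds <- target_set_partition(drugs)
  expect_equal(nrow(folds), 2)
  expect_setequal(folds$test_drugs[[1]], c("d1", "d2"))
  expect_setequal(folds$train_drugs[[1]], "d3")
  expect_setequal(folds$test_drugs[[2]], "d3")
  expect_setequal(folds$train_drugs[[2]], c("d1", "d2"))
  expect_false(any(folds$skipped))
})

test_that("a fold overlapping all other drugs is skipped for lack of training data", {
  genes <- mini_genes(c("g1", "g2"))
  drugs <- drug_catalog(c("d1", "d2", "d3"),
                        list("g1", c("g1", "g2"), "g2"), genes = genes)
  folds <- target_set_partition(drugs)
  expect_equal(nrow(folds), 3)
  shared <- which(vapply(folds$target_set, length, integer(1)) == 2)
  expect_true(folds$skipped[shared])
  expect_equal(folds$reason[shared], "empty training set")
})

test_that("fixture folds match the hand enumeration", {
  fx <- fixture_small()
  folds <- target_set_partition(fx$drugs)
  expect_equal(nrow(folds), 5)
  key <- vapply(folds$target_set, paste, character(1), collapse = ";")
  get <- function(k) folds[key == k, ]
  expect_setequal(get("g1")$test_drugs[[1]], c("d1", "d2"))
  expect_setequal(get("g1")$train_drugs[[1]], c("d3", "d4", "d6"))
  expect_setequal(get("g2;g3")$test_drugs[[1]], "d3")
  expect_setequal(get("g2;g3")$train_drugs[[1]], c("d1", "d2", "d4", "d5"))
  expect_setequal(get("g4")$train_drugs[[1]], c("d1", "d2", "d3", "d5", "d6"))
  expect_setequal(get("g1;g5")$train_drugs[[1]], c("d3", "d4", "d6"))
  expect_setequal(get("g3")$train_drugs[[1]], c("d1", "d2", "d4", "d5"))
  expect_false(any(folds$skipped))
})

test_that("every drug is tested exactly once across non-skipped folds", {
  set.seed(31)
  for (i in 1:10) {
    cats <- random_catalogs(n_drugs = 12, n_genes = 5)
    folds <- target_set_partition(cats$drugs)
    tested <- unlist(folds$test_drugs)
    expect_setequal(tested, cats$drugs$drug_id)
    expect_false(any(duplicated(tested)))
    for (f in seq_len(nrow(folds))) {
      train_targets <- unlist(cats$drugs$targets[match(folds$train_drugs[[f]], cats$drugs$drug_id)])
      expect_length(intersect(folds$target_set[[f]], train_targets), 0)
    }
  }
})

test_that("ROC AUC follows the Mann-Whitney statistic with half ties", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(1:10, c(rep(0, 5), rep(1, 5))), 1)
  expect_equal(roc_auc(rep(0.5, 8), rep(c(0, 1), 4)), 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "Both outcome classes")
  set.seed(32)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # force ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels), brute_auc(scores, labels))
  }
})

test_that("cross-validation pools one prediction per drug and drops genetics on request", {
  sim <- simulate_catalogs(sim_config(
    n_drugs = 150, n_genes = 80, target_sharing = 0.4, seed = 8
  ))
  cv <- loto_cv(sim$drugs, sim$genes, "Vascular", exclude_on_indication = FALSE)
  expect_false(any(duplicated(cv$predictions$drug_id)))
  tested <- unlist(cv$folds$test_drugs[!cv$folds$skipped])
  expect_setequal(cv$predictions$drug_id, tested)
  expect_true(cv$auc >= 0 && cv$auc <= 1)
  g <- glance(cv)
  expect_equal(g$n_predictions, nrow(cv$predictions))
  # no-genetics variant gives different predictions for supported drugs
  cv0 <- loto_cv(sim$drugs, sim$genes, "Vascular", "no_genetics",
                 exclude_on_indication = FALSE)
  expect_equal(cv0$variant, "no_genetics")
  expect_setequal(cv0$predictions$drug_id, cv$predictions$drug_id)
})

test_that("distinct singleton target sets reduce to leave-one-drug-out", {
  genes <- mini_genes(paste0("g", 1:6))
  genes$mendelian_socs <- list("Heart", "Skin", character(0), "Blood", "Heart", "Skin")
  drugs <- drug_catalog(paste0("d", 1:6), as.list(paste0("g", 1:6)),
                        side_effects = list("Heart", character(0), "Heart", "Skin",
                                            character(0), "Heart"),
                        genes = genes)
  folds <- target_set_partition(drugs)
  expect_equal(nrow(folds), 6)
  expect_true(all(lengths(folds$test_drugs) == 1))
  expect_true(all(lengths(folds$train_drugs) == 5))
})

test_that("null synthetic data give chance-level cross-validated AUC", {
  sim <- simulate_catalogs(sim_config(
    n_drugs = 800, n_genes = 250, target_sharing = 0.6, targets_per_drug = c(1, 2),
    beta_genetic = 0, beta_indication = 0, confounding = 0, seed = 1
  ))
  cv <- loto_cv(sim$drugs, sim$genes, "Nervous")
  expect_gt(cv$auc, 0.45)
  expect_lt(cv$auc, 0.55)
})

test_that("the permuted-genetics AUC null is deterministic given the seed", {
  sim <- simulate_catalogs(sim_config(
    n_drugs = 120, n_genes = 60, target_sharing = 0.4, seed = 4
  ))
  n1 <- genetics_null_cv(sim$drugs, sim$genes, "Vascular", n_perm = 5, seed = 11,
                         exclude_on_indication = FALSE)
  n2 <- genetics_null_cv(sim$drugs, sim$genes, "Vascular", n_perm = 5, seed = 11,
                         exclude_on_indication = FALSE)
  expect_identical(n1$null_values, n2$null_values)
  expect_equal(n1$observed,
               loto_cv(sim$drugs, sim$genes, "Vascular", exclude_on_indication = FALSE)$auc)
  expect_gte(n1$empirical_p, 1 / 6)
})
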