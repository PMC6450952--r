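#' Leave-one-target-set-out fold enumeration
#'
#' Enumerates every unique target set (the exact combination of target
#' genes of some drug). Each set defines one fold: the test drugs are all
#' drugs with exactly that target set, and the training drugs are all
#' drugs sharing none of its genes - drugs overlapping the test set in even
#' one target are excluded so no genetic information leaks from training to
#' test. Folds whose training set is empty are marked skipped.
#'
#' @param drugs A `drug_catalog`.
#' @return A tibble with one row per unique target set: list-columns
#'   `target_set`, `test_drugs`, `train_drugs`, plus `skipped` and
#'   `reason`.
#' @examples
#' fx <- fixture_small()
#' target_set_partition(fx$drugs)
#' @export
target_set_partition <- function(drugs) {
  if (nrow(drugs) == 0) abort("Empty drug catalog")
  sets <- map(drugs$targets, ~ sort(unique(.x)))
  keys <- map_chr(sets, join_set)
  uniq <- which(!duplicated(keys))
  gene_ids <- unique(unlist(sets))
  # drug x gene incidence; a drug trains for a fold iff it shares no gene
  # with the fold's target set
  D <- matrix(FALSE, length(sets), length(gene_ids))
  D[cbind(rep.int(seq_along(sets), lengths(sets)), match(unlist(sets), gene_ids))] <- TRUE
  U <- D[uniq, , drop = FALSE]
  overlap <- tcrossprod(U, D) > 0   # unique sets x drugs
  folds <- tibble(
    target_set = sets[uniq],
    test_drugs = map(keys[uniq], ~ drugs$drug_id[keys == .x]),
    train_drugs = map(seq_along(uniq), ~ drugs$drug_id[!overlap[.x, ]])
  )
  folds$skipped <- lengths(folds$train_drugs) == 0
  folds$reason <- ifelse(folds$skipped, "empty training set", NA_character_)
  folds
}

#' Area under the ROC curve
#'
#' The Mann-Whitney formulation: the probability that a random positive
#' outscores a random negative, with ties counted one half (average
#' ranks).
#'
#' @param scores Numeric predictions.
#' @param labels Binary (0/1 or logical) true outcomes; both classes must
#'   be present.
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("Both outcome classes must be present to compute AUC")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Leave-one-target-set-out cross-validation of a side-effect model
#'
#' For one organ-system model, fits the full multivariate logistic
#' regression (no feature selection) on each fold's training drugs and
#' predicts the held-out drugs, pooling all out-of-fold predictions into a
#' single ROC AUC. Because training excludes every drug sharing a target
#' gene with the test set, the genetic information of the test drugs is
#' never seen in training. The leakage invariant is asserted on every fold
#' of every run. `variant = "no_genetics"` drops the four genetic-support
#' indicators, giving the baseline AUC attributable to the other
#' covariates.
#'
#' @param drugs,genes The catalogs.
#' @param soc The modeled SOC label.
#' @param variant `"full"` or `"no_genetics"`.
#' @param exclude_on_indication Drop drugs indicated in `soc` (default
#'   `TRUE`, matching the off-indication focus of the CV analysis).
#' @return An object of class `cv_result`: list with `predictions` (tibble
#'   of `drug_id`, `score`, `label`), `auc`, `folds`, `n_skipped`,
#'   `variant`, `soc`.
#' @export
loto_cv <- function(drugs, genes, soc, variant = c("full", "no_genetics"),
                    exclude_on_indication = TRUE) {
  variant <- match.arg(variant)
  soc <- validate_socs(soc, "modeled SOC")
  stopifnot(length(soc) == 1)
  cols <- design_columns(drugs, genes, soc)
  keep <- if (exclude_on_indication) !cols$ind[, soc] else rep(TRUE, nrow(drugs))
  drugs <- drugs[keep, ]
  if (nrow(drugs) == 0) abort(sprintf("No drugs left for SOC %s after exclusion", soc))
  X <- as.matrix(cols$pred[keep, ])
  y <- as.integer(cols$se[keep, soc])
  if (variant == "no_genetics") {
    X <- X[, !colnames(X) %in% c("mend_match", "mend_mismatch", "gwas_match", "gwas_mismatch"),
           drop = FALSE]
  }
  folds <- target_set_partition(drugs)
  start <- if (length(unique(y)) > 1) {
    tryCatch(fit_logistic_fast(X, y), error = function(e) NULL)
  }
  id_index <- setNames(seq_len(nrow(drugs)), drugs$drug_id)
  # gene -> drugs carrying it, for the per-fold leakage assertion
  tg_len <- lengths(drugs$targets)
  carriers <- split(rep(drugs$drug_id, tg_len), unlist(drugs$targets))
  preds <- vector("list", nrow(folds))
  for (f in seq_len(nrow(folds))) {
    if (folds$skipped[f]) next
    train <- id_index[folds$train_drugs[[f]]]
    test <- id_index[folds$test_drugs[[f]]]
    # leakage invariant: no drug carrying a test-set target gene trains
    sharing <- unique(unlist(carriers[folds$target_set[[f]]], use.names = FALSE))
    stopifnot(!any(sharing %in% folds$train_drugs[[f]]))
    if (length(unique(y[train])) < 2) {
      folds$skipped[f] <- TRUE
      folds$reason[f] <- "single-class training response"
      next
    }
    cf <- fit_logistic_fast(X[train, , drop = FALSE], y[train], start = start)
    eta <- cbind(1, X[test, , drop = FALSE]) %*% cf
    preds[[f]] <- tibble(
      drug_id = drugs$drug_id[test],
      score = plogis(as.vector(eta)),
      label = y[test]
    )
  }
  predictions <- bind_rows(preds)
  if (nrow(predictions) == 0) abort("All folds skipped; no out-of-fold predictions")
  structure(
    list(
      predictions = predictions,
      auc = roc_auc(predictions$score, predictions$label),
      folds = folds,
      n_skipped = sum(folds$skipped),
      variant = variant, soc = soc
    ),
    class = "cv_result"
  )
}

#' Permuted-genetics null distribution of the cross-validation AUC
#'
#' The observed statistic is the full-model leave-one-target-set-out AUC.
#' Each null replicate permutes the gene-to-phenotype assignments (jointly
#' across sources, within the genes appearing as drug targets) and reruns
#' the identical cross-validation; the empirical p-value is the add-one
#' fraction of null AUCs at least as large as the observed one. Because
#' the fold structure depends only on target sets, folds are identical
#' across replicates.
#'
#' @inheritParams loto_cv
#' @param n_perm Number of permutation replicates. Default 1000.
#' @param seed Master seed.
#' @return A `permutation_result` whose `observed` is the true-data AUC;
#'   the full `cv_result` is attached as attribute `"cv"`.
#' @export
genetics_null_cv <- function(drugs, genes, soc, n_perm = 1000, seed = 1L,
                             exclude_on_indication = TRUE) {
  stopifnot(n_perm >= 1)
  cv <- loto_cv(drugs, genes, soc, "full", exclude_on_indication)
  target_genes <- intersect(genes$gene_id, unique(unlist(drugs$targets)))
  rep_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n_perm))
  null_values <- map_dbl(rep_seeds, function(s) {
    tryCatch({
      g <- permute_gene_phenotypes(genes, "both", rng_seed = s, gene_ids = target_genes)
      loto_cv(drugs, g, soc, "full", exclude_on_indication)$auc
    }, error = function(e) NA_real_)
  })
  dropped <- sum(is.na(null_values))
  if (dropped > 0) {
    warn(sprintf("%d null replicate(s) failed and were dropped", dropped))
    if (dropped >= 0.1 * n_perm) abort("More than 10% of null replicates failed")
    null_values <- null_values[!is.na(null_values)]
  }
  out <- structure(
    list(
      observed = cv$auc, null_values = null_values,
      empirical_p = empirical_p(cv$auc, null_values),
      n_perm = length(null_values), seed = seed, mode = "genetics_cv"
    ),
    class = "permutation_result"
  )
  attr(out, "cv") <- cv
  out
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "Leave-one-target-set-out CV (%s, %s): AUC = %.4f over %d predictions (%d/%d folds skipped)\n",
    x$soc, x$variant, x$auc, nrow(x$predictions), x$n_skipped, nrow(x$folds)
  ))
  invisible(x)
}

#' Broom-style accessors for cross-validation results
#'
#' `tidy()` returns the pooled out-of-fold predictions; `glance()` the
#' one-row summary (AUC, fold counts).
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cv_result <- function(x, ...) x$predictions

#' @rdname tidy.cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble(
    soc = x$soc, variant = x$variant, auc = x$auc,
    n_predictions = nrow(x$predictions),
    n_folds = nrow(x$folds), n_skipped = x$n_skipped
  )
}
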