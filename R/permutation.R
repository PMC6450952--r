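# Add-one Monte-Carlo empirical p-value: (r + 1)/(n + 1) with r the number
# of null statistics at least as large as the observed one; never zero.
empirical_p <- function(observed, null_values) {
  (sum(null_values >= observed) + 1) / (length(null_values) + 1)
}

#' Permute gene-to-phenotype assignments
#'
#' Structured permutation null for the enrichment analysis: the multiset of
#' phenotype SOC sets (including empty sets) is reassigned to gene ids by a
#' uniform permutation, so the fraction of uninformative genes and the size
#' distribution of phenotype sets are preserved exactly. With
#' `source = "both"` the (Mendelian, GWAS) pair of sets travels together,
#' preserving the co-occurrence of evidence across sources.
#'
#' @param genes A `gene_catalog`.
#' @param source Which source's assignments to permute: `"both"` (jointly,
#'   the default), `"mendelian"`, or `"gwas"`.
#' @param rng_seed Integer seed making the permutation deterministic.
#' @param gene_ids Optional character vector restricting the permutation to
#'   a subset of genes (e.g. the genes actually appearing as drug targets);
#'   other rows are untouched.
#' @return A `gene_catalog` with permuted phenotype sets.
#' @export
permute_gene_phenotypes <- function(genes, source = c("both", "mendelian", "gwas"),
                                    rng_seed = 1L, gene_ids = NULL) {
  source <- match.arg(source)
  if (nrow(genes) == 0) abort("Cannot permute an empty gene catalog")
  rows <- if (is.null(gene_ids)) seq_len(nrow(genes)) else {
    idx <- match(gene_ids, genes$gene_id)
    if (anyNA(idx)) abort("gene_ids not all present in catalog")
    idx
  }
  perm <- withr::with_seed(rng_seed, sample(length(rows)))
  out <- genes
  if (source %in% c("both", "mendelian")) {
    out$mendelian_socs[rows] <- genes$mendelian_socs[rows][perm]
  }
  if (source == "gwas") {
    out$gwas_socs[rows] <- genes$gwas_socs[rows][perm]
  } else if (source == "both") {
    out$gwas_socs[rows] <- genes$gwas_socs[rows][perm]
  }
  out
}

#' Permute drug side-effect profiles
#'
#' Reassigns the side-effect SOC sets among drugs by a uniform permutation,
#' leaving targets, indications, and covariates untouched. The multiset of
#' side-effect profiles - hence the per-SOC side-effect counts - is
#' preserved exactly.
#'
#' @param drugs A `drug_catalog`.
#' @param rng_seed Integer seed.
#' @return A `drug_catalog` with permuted side-effect sets.
#' @export
permute_drug_side_effects <- function(drugs, rng_seed = 1L) {
  if (nrow(drugs) == 0) abort("Cannot permute an empty drug catalog")
  perm <- withr::with_seed(rng_seed, sample(nrow(drugs)))
  out <- drugs
  out$side_effects <- drugs$side_effects[perm]
  out
}

#' Pooled enrichment odds ratio of an observation set
#'
#' The default scalar statistic for permutation tests: the cross-product
#' odds ratio of the pooled (genetic support x side effect) table.
#'
#' @param observations An observation tibble.
#' @return A single number.
#' @export
stat_pooled_or <- function(observations) {
  odds_ratio_ci(tabulate_observations(observations, "any"))$odds_ratio
}

#' Monte-Carlo permutation test of the enrichment statistic
#'
#' Compares the observed enrichment statistic against a structured null in
#' which either the gene-to-phenotype assignments (`mode = "genetics"`,
#' permuted jointly across sources and restricted to genes appearing as
#' drug targets) or the drug side-effect profiles
#' (`mode = "side_effects"`) are randomised. Observations are rebuilt for
#' every replicate. The empirical p-value uses the add-one convention
#' (r + 1)/(n + 1), never reporting zero, where r counts null statistics at
#' least as large as the observed one.
#'
#' @param genes,drugs The catalogs.
#' @param statistic Function of an observation tibble returning a scalar;
#'   default [stat_pooled_or()].
#' @param mode `"genetics"` or `"side_effects"`.
#' @param n_perm Number of permutations.
#' @param seed Master seed; replicate seeds are derived from it, so the
#'   same seed yields an identical null distribution.
#' @param obs_mode Observation mode passed to [build_observations()].
#' @return An object of class `permutation_result`: list with `observed`,
#'   `null_values`, `empirical_p`, `n_perm` (valid replicates), `seed`,
#'   `mode`.
#' @examples
#' fx <- fixture_small()
#' permutation_test(fx$genes, fx$drugs, n_perm = 19, seed = 2)
#' @export
permutation_test <- function(genes, drugs, statistic = stat_pooled_or,
                             mode = c("genetics", "side_effects"),
                             n_perm = 999L, seed = 1L,
                             obs_mode = c("all", "off_indication")) {
  mode <- match.arg(mode)
  obs_mode <- match.arg(obs_mode)
  stopifnot(n_perm >= 1)
  observed <- statistic(build_observations(drugs, genes, obs_mode))
  target_genes <- intersect(genes$gene_id, unique(unlist(drugs$targets)))
  rep_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n_perm))
  null_values <- map_dbl(rep_seeds, function(s) {
    tryCatch({
      if (mode == "genetics") {
        g <- permute_gene_phenotypes(genes, "both", rng_seed = s, gene_ids = target_genes)
        statistic(build_observations(drugs, g, obs_mode))
      } else {
        d <- permute_drug_side_effects(drugs, rng_seed = s)
        statistic(build_observations(d, genes, obs_mode))
      }
    }, error = function(e) NA_real_)
  })
  dropped <- sum(is.na(null_values))
  if (dropped > 0) {
    warn(sprintf("%d permutation replicate(s) failed and were dropped", dropped))
    if (dropped >= 0.1 * n_perm) abort("More than 10% of permutation replicates failed")
    null_values <- null_values[!is.na(null_values)]
  }
  structure(
    list(
      observed = observed, null_values = null_values,
      empirical_p = empirical_p(observed, null_values),
      n_perm = length(null_values), seed = seed, mode = mode
    ),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Permutation test (%s): observed = %.4g, empirical P = %.4g (%d permutations)\n",
    x$mode, x$observed, x$empirical_p, x$n_perm
  ))
  invisible(x)
}

#' @rdname permutation_test
#' @param x A `permutation_result`.
#' @param ... Unused.
#' @export
tidy.permutation_result <- function(x, ...) {
  tibble(
    mode = x$mode, observed = x$observed, empirical_p = x$empirical_p,
    n_perm = x$n_perm,
    null_mean = mean(x$null_values), null_sd = sd(x$null_values),
    null_q025 = unname(quantile(x$null_values, 0.025)),
    null_q975 = unname(quantile(x$null_values, 0.975))
  )
}
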