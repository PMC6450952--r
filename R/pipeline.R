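format_p <- function(p) {
  ifelse(is.na(p), "NA",
    ifelse(p >= 0.001, format(signif(p, 3), trim = TRUE), sprintf("%.2E", p))
  )
}

#' Render the per-organ enrichment report table
#'
#' Formats a 21-row per-SOC enrichment result in the reference layout:
#' the four contingency counts, the two side-effect rates at one decimal
#' percent, the odds ratio at two decimals, and the Fisher p-value, with a
#' `Total` row equal to the cell-wise sums. Degenerate rates render as
#' `NA`.
#'
#' @param results A per-SOC `enrichment_tbl` (all 21 categories present).
#' @return A single TSV-formatted character string.
#' @examples
#' reference_soc_counts() |>
#'   enrichment_from_counts(total = FALSE) |>
#'   render_table1() |>
#'   cat()
#' @export
render_table1 <- function(results) {
  missing_socs <- setdiff(soc_categories(), results$soc)
  if (length(missing_socs) > 0) {
    abort(paste("Missing categories:", paste(missing_socs, collapse = ", ")))
  }
  results <- results[match(soc_categories(), results$soc), ]
  total_tab <- c(a = sum(results$a), b = sum(results$b), c = sum(results$c), d = sum(results$d))
  rows <- bind_rows(results, enrichment_row(total_tab, "Total"))
  fmt_rate <- function(r) ifelse(is.na(r), "NA", sprintf("%.1f%%", 100 * r))
  fmt_or <- function(o) ifelse(is.na(o), "NA", ifelse(is.infinite(o), "Inf", sprintf("%.2f", o)))
  body <- sprintf(
    "%s\t%d\t%d\t%d\t%d\t%s\t%s\t%s\t%s",
    rows$soc, rows$a, rows$b, rows$c, rows$d,
    fmt_rate(rows$rate_support), fmt_rate(rows$rate_no_support),
    fmt_or(rows$odds_ratio), format_p(rows$p_two_tailed)
  )
  header <- paste(
    "phenotype_category", "n_genetics_se", "n_genetics_no_se",
    "n_no_genetics_se", "n_no_genetics_no_se",
    "rate_se_with_genetics", "rate_se_without_genetics", "odds_ratio", "p_two_tailed",
    sep = "\t"
  )
  paste0(paste(c(header, body), collapse = "\n"), "\n")
}

#' Run the full analysis pipeline
#'
#' Ties the stages together: obtain catalogs (simulated from a
#' [sim_config()], loaded from gene/drug TSV tables, or a pre-flattened
#' observation table), build observations, run the pooled, per-organ and
#' de-risk enrichment analyses, the two permutation nulls, the per-organ
#' logistic models over eligible categories, and - for categories where a
#' genetic predictor is significant - the leave-one-target-set-out
#' cross-validation. All randomness derives from `seed`, so a rerun with
#' the same inputs reproduces every number.
#'
#' @param sim Optional `sim_config` (synthetic-data input).
#' @param gene_table,drug_table Optional paths to catalog TSVs.
#' @param flat_table Optional path to a flat observation TSV.
#' @param mode `"all"` or `"off_indication"`.
#' @param seed Master seed.
#' @param n_perm Permutation-count for the enrichment nulls (0 skips them).
#' @param min_count Eligibility threshold for regression models.
#' @param cv_significance p-value threshold on the genetic coefficients
#'   that promotes a category to cross-validation. Default 0.05.
#' @param run_cv Run the cross-validation stage. Default `TRUE`.
#' @param cv_n_perm Replicates for the permuted-genetics AUC null per
#'   cross-validated category (0 skips the null).
#' @param out_dir Optional directory; when given, writes the catalogs,
#'   observation table, rendered report table, pooled-summary JSON, and a
#'   run manifest.
#' @return A list with elements `genes`, `drugs`, `observations`,
#'   `enrichment` (list `pooled`, `per_soc`, `derisk`), `permutation`
#'   (list `genetics`, `side_effects`), `models` (named list of `ts_fit`),
#'   `cv` (named list per cross-validated SOC), `manifest`.
#' @export
run_pipeline <- function(sim = NULL, gene_table = NULL, drug_table = NULL,
                         flat_table = NULL, mode = c("all", "off_indication"),
                         seed = 1L, n_perm = 99L, min_count = 100,
                         cv_significance = 0.05, run_cv = TRUE, cv_n_perm = 0L,
                         out_dir = NULL) {
  mode <- match.arg(mode)
  inputs <- c(!is.null(sim), !is.null(gene_table) || !is.null(drug_table), !is.null(flat_table))
  if (sum(inputs) != 1) {
    abort("Specify exactly one input: sim, gene_table+drug_table, or flat_table")
  }
  genes <- drugs <- NULL
  if (!is.null(sim)) {
    cat_pair <- simulate_catalogs(sim)
    genes <- cat_pair$genes
    drugs <- cat_pair$drugs
    observations <- build_observations(drugs, genes, mode)
  } else if (!is.null(flat_table)) {
    observations <- read_observation_table(flat_table)
    if (mode == "off_indication") {
      observations <- observations[!observations$on_indication, ]
      attr(observations, "mode") <- "off_indication"
    }
  } else {
    if (is.null(gene_table) || is.null(drug_table)) {
      abort("Both gene_table and drug_table are required for catalog input")
    }
    genes <- read_gene_table(gene_table)
    drugs <- read_drug_table(drug_table, genes = genes)
    observations <- build_observations(drugs, genes, mode)
  }

  enrichment <- list(
    pooled = enrichment_analysis(observations),
    per_soc = enrichment_analysis(observations, per_soc = TRUE),
    derisk = tryCatch(derisk_analysis(observations), error = function(e) {
      warn(paste("De-risk analysis skipped:", conditionMessage(e)))
      NULL
    })
  )

  permutation <- list(genetics = NULL, side_effects = NULL)
  models <- list()
  cv <- list()
  if (!is.null(drugs)) {
    if (n_perm > 0) {
      permutation$genetics <- permutation_test(
        genes, drugs, mode = "genetics", n_perm = n_perm, seed = seed, obs_mode = mode
      )
      permutation$side_effects <- permutation_test(
        genes, drugs, mode = "side_effects", n_perm = n_perm, seed = seed + 1L, obs_mode = mode
      )
    }
    eligible <- eligible_categories(drugs, min_count = min_count)
    excl <- mode == "off_indication"
    for (soc in eligible) {
      fit <- tryCatch(
        fit_logistic(build_design(drugs, genes, soc, exclude_on_indication = excl)),
        error = function(e) NULL
      )
      if (!is.null(fit)) models[[soc]] <- fit
    }
    if (run_cv && length(models) > 0) {
      gen_terms <- c("mend_match", "gwas_match")
      sig_socs <- names(models)[map_lgl(models, function(f) {
        p <- f$terms$p_value[f$terms$term %in% gen_terms]
        any(!is.na(p) & p < cv_significance)
      })]
      for (soc in sig_socs) {
        cv[[soc]] <- tryCatch({
          res <- list(
            full = loto_cv(drugs, genes, soc, "full"),
            no_genetics = loto_cv(drugs, genes, soc, "no_genetics")
          )
          if (cv_n_perm > 0) {
            res$null <- genetics_null_cv(drugs, genes, soc, n_perm = cv_n_perm, seed = seed + 2L)
          }
          res
        }, error = function(e) {
          warn(sprintf("Cross-validation skipped for %s: %s", soc, conditionMessage(e)))
          NULL
        })
      }
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("targetsafety")),
    seed = seed, mode = mode, n_perm = n_perm, min_count = min_count,
    cv_significance = cv_significance, cv_n_perm = cv_n_perm,
    input = if (!is.null(sim)) c(type = "simulate", unclass(sim)[c(
      "n_drugs", "n_genes", "target_sharing", "beta_genetic",
      "beta_indication", "confounding", "frac_no_mendelian", "frac_no_gwas", "seed"
    )]) else if (!is.null(flat_table)) list(type = "flat", path = flat_table)
    else list(type = "catalogs", gene_table = gene_table, drug_table = drug_table),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  result <- list(
    genes = genes, drugs = drugs, observations = observations,
    enrichment = enrichment, permutation = permutation,
    models = models, cv = cv, manifest = manifest
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(genes)) write_gene_table(genes, file.path(out_dir, "genes.tsv"))
    if (!is.null(drugs)) write_drug_table(drugs, file.path(out_dir, "drugs.tsv"))
    write_observation_table(observations, file.path(out_dir, "observations.tsv"))
    writeLines(render_table1(enrichment$per_soc), file.path(out_dir, "enrichment_per_soc.tsv"))
    jsonlite::write_json(
      list(
        pooled = as.list(enrichment$pooled),
        derisk = if (!is.null(enrichment$derisk)) as.list(enrichment$derisk),
        permutation = map(
          keep(permutation, ~ !is.null(.x)),
          ~ list(observed = .x$observed, empirical_p = .x$empirical_p, n_perm = .x$n_perm)
        ),
        cv = map(cv, ~ list(
          auc_full = .x$full$auc, auc_no_genetics = .x$no_genetics$auc,
          empirical_p = if (!is.null(.x$null)) .x$null$empirical_p
        ))
      ),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  }
  result
}
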