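support_levels <- function() c("MATCH", "MISMATCH", "NO_INFO")

# Incidence matrices shared by the support/observation machinery:
# Tm is drugs x genes (targeting), M_m / M_g are genes x 21 phenotype
# indicators for the Mendelian and GWAS sources.
catalog_matrices <- function(drugs, genes) {
  socs <- soc_categories()
  n_d <- nrow(drugs)
  n_g <- nrow(genes)
  Tm <- matrix(0, n_d, n_g)
  if (n_d > 0) {
    tg <- drugs$targets
    rows <- rep.int(seq_len(n_d), lengths(tg))
    cols <- match(unlist(tg), genes$gene_id)
    if (anyNA(cols)) {
      missing_genes <- setdiff(unique(unlist(tg)), genes$gene_id)
      abort(paste("Target genes absent from gene catalog:", paste(missing_genes, collapse = ", ")))
    }
    Tm[cbind(rows, cols)] <- 1
  }
  set_matrix <- function(sets) {
    M <- matrix(0, n_g, length(socs), dimnames = list(NULL, socs))
    if (n_g > 0) {
      r <- rep.int(seq_len(n_g), lengths(sets))
      cc <- match(unlist(sets), socs)
      M[cbind(r, cc)] <- 1
    }
    M
  }
  drug_set_matrix <- function(sets) {
    M <- matrix(FALSE, n_d, length(socs), dimnames = list(NULL, socs))
    if (n_d > 0) {
      r <- rep.int(seq_len(n_d), lengths(sets))
      cc <- match(unlist(sets), socs)
      M[cbind(r, cc)] <- TRUE
    }
    M
  }
  list(
    Tm = Tm,
    M_m = set_matrix(genes$mendelian_socs),
    M_g = set_matrix(genes$gwas_socs),
    se = drug_set_matrix(drugs$side_effects),
    ind = drug_set_matrix(drugs$indications)
  )
}

# Per-drug x SOC support level matrices ("MATCH"/"MISMATCH"/"NO_INFO") and
# the all-targets-informative flag, from the incidence matrices.
support_from_matrices <- function(mats) {
  match_m <- (mats$Tm %*% mats$M_m) > 0
  match_g <- (mats$Tm %*% mats$M_g) > 0
  info_m <- rowSums(mats$M_m) > 0
  info_g <- rowSums(mats$M_g) > 0
  informative_m <- (mats$Tm %*% info_m) > 0
  informative_g <- (mats$Tm %*% info_g) > 0
  level <- function(match, informative) {
    out <- matrix("NO_INFO", nrow(match), ncol(match), dimnames = dimnames(match))
    out[as.vector(informative), ] <- "MISMATCH"
    out[match] <- "MATCH"
    out
  }
  list(
    mendelian = level(match_m, informative_m),
    gwas = level(match_g, informative_g),
    all_targets_informative = as.vector(mats$Tm %*% (!(info_m | info_g))) == 0
  )
}

#' Genetic support of drugs for an organ system
#'
#' For each drug, classifies the evidence its target genes carry about one
#' organ-system category, from one genetic source: `"MATCH"` if at least one
#' target gene has a phenotype in that SOC, `"MISMATCH"` if no target
#' matches but at least one target has phenotypes in other SOCs (an
#' informative gene), and `"NO_INFO"` if no target carries any phenotype
#' from the source.
#'
#' @param drugs A `drug_catalog` (one or more rows).
#' @param genes A `gene_catalog` resolving every target.
#' @param soc A single SOC label.
#' @param source `"mendelian"` or `"gwas"`.
#' @return Character vector of support levels, one per drug.
#' @examples
#' fx <- fixture_small()
#' derive_genetic_support(fx$drugs, fx$genes, "Heart", "mendelian")
#' @export
derive_genetic_support <- function(drugs, genes, soc, source = c("mendelian", "gwas")) {
  source <- match.arg(source)
  soc <- validate_socs(soc, "queried SOC")
  stopifnot(length(soc) == 1)
  sup <- support_from_matrices(catalog_matrices(drugs, genes))
  unname(sup[[source]][, soc])
}

#' Flatten catalogs into the drug x organ-system observation table
#'
#' The unit of the enrichment analysis is one drug crossed with one of the
#' 21 organ-system categories. For every pair this computes: whether the
#' drug was pursued for an indication in that organ system, whether a
#' side effect was observed there, Mendelian and GWAS support levels (via
#' [derive_genetic_support()]), the combined `any_support` flag (MATCH from
#' either source), and whether every target gene carries some genetic
#' information (`all_targets_informative`, the basis of the de-risk split).
#' With `mode = "off_indication"` all on-indication pairs are dropped,
#' removing the organ systems where side effects may simply be exaggerated
#' pharmacology of the intended effect.
#'
#' @param drugs A `drug_catalog`.
#' @param genes A `gene_catalog`.
#' @param mode `"all"` (every drug x SOC pair) or `"off_indication"`.
#' @return A tibble with one row per retained pair and columns `drug_id`,
#'   `soc`, `on_indication`, `side_effect`, `mendelian`, `gwas`,
#'   `any_support`, `all_targets_informative`; the mode is recorded in the
#'   `"mode"` attribute.
#' @examples
#' fx <- fixture_small()
#' build_observations(fx$drugs, fx$genes) |> head()
#' @export
build_observations <- function(drugs, genes, mode = c("all", "off_indication")) {
  mode <- match.arg(mode)
  socs <- soc_categories()
  n_d <- nrow(drugs)
  mats <- catalog_matrices(drugs, genes)
  sup <- support_from_matrices(mats)
  # row-major flattening: drug-major, SOCs in canonical order within drug
  flat <- function(M) as.vector(t(M))
  obs <- tibble(
    drug_id = rep(drugs$drug_id, each = length(socs)),
    soc = rep(socs, times = n_d),
    on_indication = flat(mats$ind),
    side_effect = flat(mats$se),
    mendelian = flat(sup$mendelian),
    gwas = flat(sup$gwas),
    all_targets_informative = rep(sup$all_targets_informative, each = length(socs))
  )
  obs$any_support <- obs$mendelian == "MATCH" | obs$gwas == "MATCH"
  obs <- obs[c(
    "drug_id", "soc", "on_indication", "side_effect",
    "mendelian", "gwas", "any_support", "all_targets_informative"
  )]
  if (mode == "off_indication") obs <- obs[!obs$on_indication, ]
  attr(obs, "mode") <- mode
  obs
}

#' Read and write the flat observation table
#'
#' The flat layout mirrors the supplementary full-dataset format: one TSV
#' row per drug x SOC pair with binary flags as 0/1 and support levels as
#' MATCH/MISMATCH/NO_INFO. Reading reconstructs `any_support` from the two
#' support columns, so a pre-flattened dataset can drive the enrichment,
#' de-risk, and permutation analyses without the original catalogs.
#'
#' @param path File path.
#' @param observations An observation tibble from [build_observations()].
#' @return `read_observation_table()` returns the observation tibble;
#'   the writer returns the path invisibly.
#' @name observation_io
#' @export
read_observation_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    drug_id = readr::col_character(), soc = readr::col_character(),
    on_indication = readr::col_integer(), side_effect = readr::col_integer(),
    mendelian_support = readr::col_character(), gwas_support = readr::col_character(),
    all_targets_informative = readr::col_integer()
  ))
  validate_socs(raw$soc, "soc column")
  bad <- setdiff(unique(c(raw$mendelian_support, raw$gwas_support)), support_levels())
  if (length(bad) > 0) abort(paste("Unknown support level:", paste(bad, collapse = ", ")))
  obs <- tibble(
    drug_id = raw$drug_id, soc = raw$soc,
    on_indication = raw$on_indication == 1L,
    side_effect = raw$side_effect == 1L,
    mendelian = raw$mendelian_support, gwas = raw$gwas_support,
    any_support = raw$mendelian_support == "MATCH" | raw$gwas_support == "MATCH",
    all_targets_informative = raw$all_targets_informative == 1L
  )
  attr(obs, "mode") <- if (any(obs$on_indication)) "all" else "off_indication"
  obs
}

#' @rdname observation_io
#' @export
write_observation_table <- function(observations, path) {
  out <- tibble(
    drug_id = observations$drug_id, soc = observations$soc,
    on_indication = as.integer(observations$on_indication),
    side_effect = as.integer(observations$side_effect),
    mendelian_support = observations$mendelian,
    gwas_support = observations$gwas,
    all_targets_informative = as.integer(observations$all_targets_informative)
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Remove side-effect terms reported for a large fraction of drugs
#'
#' Very common side effects (headache and the like) are unlikely to reflect
#' target-mediated biology and would swamp the analysis, so raw side-effect
#' terms observed with at least `threshold` of drugs are dropped before any
#' aggregation to organ-system categories.
#'
#' @param drugs A `drug_catalog` (defines the drug universe size).
#' @param raw_side_effect_terms Named list mapping `drug_id` to a character
#'   vector of raw side-effect terms.
#' @param threshold Fraction of drugs in (0, 1]; a term present in at least
#'   `threshold * nrow(drugs)` drugs is removed. Default 0.10.
#' @return A list with `terms` (the filtered mapping) and `removed`
#'   (character vector of dropped terms).
#' @export
remove_common_side_effects <- function(drugs, raw_side_effect_terms, threshold = 0.10) {
  stopifnot(threshold > 0, threshold <= 1)
  n_drugs <- nrow(drugs)
  counts <- table(unlist(map(raw_side_effect_terms, unique)))
  removed <- names(counts)[counts >= threshold * n_drugs]
  list(
    terms = map(raw_side_effect_terms, ~ setdiff(.x, removed)),
    removed = removed
  )
}
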