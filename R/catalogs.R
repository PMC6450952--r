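drug_modalities <- function() c("small_molecule", "biological")
drug_routes <- function() c("enteral", "parenteral", "topical", "other")
expression_breadth_levels <- function() c("all", "mixed", "enriched", "none_detected")

#' Construct and validate a gene catalog
#'
#' A gene catalog is a tibble with one row per drug-target gene:
#' `gene_id`, list-columns `mendelian_socs` and `gwas_socs` holding the
#' organ-system categories of the gene's Mendelian-syndrome and GWAS
#' phenotypes (an empty set means no genetic information from that source),
#' a `constrained` flag (loss-of-function intolerance, pLI >= 0.9), and an
#' `expression_breadth` category from the cross-tissue expression profile.
#'
#' @param gene_id Character vector of unique, nonempty gene identifiers.
#' @param mendelian_socs,gwas_socs Lists of character vectors of SOC labels
#'   (subsets of [soc_categories()]).
#' @param constrained Logical vector.
#' @param expression_breadth Character vector with values in
#'   `"all"`, `"mixed"`, `"enriched"`, `"none_detected"`.
#' @return A validated tibble of class `gene_catalog`.
#' @examples
#' gene_catalog("G1", list(c("Heart", "Blood")), list(character(0)), TRUE, "enriched")
#' @export
gene_catalog <- function(gene_id, mendelian_socs = list(), gwas_socs = list(),
                         constrained = FALSE, expression_breadth = "none_detected") {
  n <- length(gene_id)
  if (n == 0) {
    return(validate_gene_catalog(tibble(
      gene_id = character(0), mendelian_socs = list(), gwas_socs = list(),
      constrained = logical(0), expression_breadth = character(0)
    )))
  }
  validate_gene_catalog(tibble(
    gene_id = as.character(gene_id),
    mendelian_socs = rep_len(mendelian_socs, n),
    gwas_socs = rep_len(gwas_socs, n),
    constrained = rep_len(as.logical(constrained), n),
    expression_breadth = rep_len(expression_breadth, n)
  ))
}

#' @rdname gene_catalog
#' @param genes A tibble to validate.
#' @export
validate_gene_catalog <- function(genes) {
  req <- c("gene_id", "mendelian_socs", "gwas_socs", "constrained", "expression_breadth")
  missing_cols <- setdiff(req, names(genes))
  if (length(missing_cols) > 0) {
    abort(paste("Gene catalog is missing columns:", paste(missing_cols, collapse = ", ")))
  }
  if (any(is.na(genes$gene_id) | !nzchar(genes$gene_id))) {
    abort("Gene catalog contains empty gene_id values")
  }
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0) {
    abort(paste("Duplicate gene_id:", paste(unique(dup), collapse = ", ")))
  }
  for (i in seq_len(nrow(genes))) {
    validate_socs(genes$mendelian_socs[[i]], sprintf("mendelian_socs of %s", genes$gene_id[i]))
    validate_socs(genes$gwas_socs[[i]], sprintf("gwas_socs of %s", genes$gene_id[i]))
  }
  bad <- setdiff(unique(genes$expression_breadth), expression_breadth_levels())
  if (length(bad) > 0) abort(paste("Unknown expression_breadth:", paste(bad, collapse = ", ")))
  class(genes) <- unique(c("gene_catalog", class(genes)))
  genes
}

#' Construct and validate a drug catalog
#'
#' A drug catalog is a tibble with one row per drug: `drug_id`, a
#' `targets` list-column of gene ids (at least one per drug), `modality`
#' (`"small_molecule"` or `"biological"`), a `routes` list-column with
#' delivery-route flags among `"enteral"`, `"parenteral"`, `"topical"`,
#' `"other"` (non-exclusive), and list-columns `indications` and
#' `side_effects` holding the SOC categories of the drug's pursued
#' indications and observed clinical-trial side effects.
#'
#' @param drug_id Character vector of unique identifiers.
#' @param targets List of character vectors of gene ids (each nonempty).
#' @param modality Character vector.
#' @param routes List of character vectors.
#' @param indications,side_effects Lists of character vectors of SOC labels.
#' @param genes Optional gene catalog; when supplied, every target gene id
#'   must resolve in it.
#' @return A validated tibble of class `drug_catalog`.
#' @export
drug_catalog <- function(drug_id, targets, modality = "small_molecule",
                         routes = list(), indications = list(),
                         side_effects = list(), genes = NULL) {
  n <- length(drug_id)
  if (n == 0) {
    out <- tibble(
      drug_id = character(0), targets = list(), modality = character(0),
      routes = list(), indications = list(), side_effects = list()
    )
    return(validate_drug_catalog(out, genes))
  }
  validate_drug_catalog(tibble(
    drug_id = as.character(drug_id),
    targets = rep_len(targets, n),
    modality = rep_len(modality, n),
    routes = rep_len(if (length(routes)) routes else list(character(0)), n),
    indications = rep_len(if (length(indications)) indications else list(character(0)), n),
    side_effects = rep_len(if (length(side_effects)) side_effects else list(character(0)), n)
  ), genes)
}

#' @rdname drug_catalog
#' @param drugs A tibble to validate.
#' @export
validate_drug_catalog <- function(drugs, genes = NULL) {
  req <- c("drug_id", "targets", "modality", "routes", "indications", "side_effects")
  missing_cols <- setdiff(req, names(drugs))
  if (length(missing_cols) > 0) {
    abort(paste("Drug catalog is missing columns:", paste(missing_cols, collapse = ", ")))
  }
  dup <- drugs$drug_id[duplicated(drugs$drug_id)]
  if (length(dup) > 0) abort(paste("Duplicate drug_id:", paste(unique(dup), collapse = ", ")))
  no_target <- map_lgl(drugs$targets, ~ length(.x) == 0)
  if (any(no_target)) {
    abort(paste("Drugs with zero targets:", paste(drugs$drug_id[no_target], collapse = ", ")))
  }
  bad_mod <- setdiff(unique(drugs$modality), drug_modalities())
  if (length(bad_mod) > 0) abort(paste("Unknown modality:", paste(bad_mod, collapse = ", ")))
  bad_route <- setdiff(unique(unlist(drugs$routes)), drug_routes())
  if (length(bad_route) > 0) abort(paste("Unknown route:", paste(bad_route, collapse = ", ")))
  for (i in seq_len(nrow(drugs))) {
    validate_socs(drugs$indications[[i]], sprintf("indications of %s", drugs$drug_id[i]))
    validate_socs(drugs$side_effects[[i]], sprintf("side_effects of %s", drugs$drug_id[i]))
  }
  if (!is.null(genes)) {
    unresolved <- setdiff(unique(unlist(drugs$targets)), genes$gene_id)
    if (length(unresolved) > 0) {
      abort(paste("Target genes absent from gene catalog:", paste(unresolved, collapse = ", ")))
    }
  }
  class(drugs) <- unique(c("drug_catalog", class(drugs)))
  drugs
}

#' Read and write catalog tables
#'
#' Catalogs are exchanged as TSV files. Set-valued fields (SOC sets, target
#' gene sets, routes) are semicolon-delimited; an empty string is the empty
#' set. The gene table has columns
#' `gene_id  mendelian_socs  gwas_socs  constrained  expression_breadth`
#' (`constrained` as 0/1); the drug table has columns
#' `drug_id  targets  modality  routes  indications  side_effects`.
#' Writers and readers round-trip exactly on valid catalogs.
#'
#' @param path File path.
#' @return `read_gene_table()` a `gene_catalog`; `read_drug_table()` a
#'   `drug_catalog`; writers return the path invisibly.
#' @name catalog_io
#' @export
read_gene_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (nrow(raw) == 0) return(gene_catalog(character(0)))
  gene_catalog(
    gene_id = raw$gene_id,
    mendelian_socs = imap(raw$mendelian_socs, ~ parse_soc_set(.x, sprintf("mendelian_socs row %d", .y))),
    gwas_socs = imap(raw$gwas_socs, ~ parse_soc_set(.x, sprintf("gwas_socs row %d", .y))),
    constrained = raw$constrained == "1",
    expression_breadth = raw$expression_breadth
  )
}

#' @rdname catalog_io
#' @param genes A `gene_catalog`.
#' @export
write_gene_table <- function(genes, path) {
  out <- tibble(
    gene_id = genes$gene_id,
    mendelian_socs = map_chr(genes$mendelian_socs, join_set),
    gwas_socs = map_chr(genes$gwas_socs, join_set),
    constrained = as.integer(genes$constrained),
    expression_breadth = genes$expression_breadth
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname catalog_io
#' @param genes Optional `gene_catalog` used to resolve target gene ids.
#' @export
read_drug_table <- function(path, genes = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (nrow(raw) == 0) return(drug_catalog(character(0), list()))
  split_set <- function(x) {
    if (is.na(x) || !nzchar(x)) character(0) else stringr::str_split_1(x, ";")
  }
  drug_catalog(
    drug_id = raw$drug_id,
    targets = map(raw$targets, split_set),
    modality = raw$modality,
    routes = map(raw$routes, split_set),
    indications = imap(raw$indications, ~ parse_soc_set(.x, sprintf("indications row %d", .y))),
    side_effects = imap(raw$side_effects, ~ parse_soc_set(.x, sprintf("side_effects row %d", .y))),
    genes = genes
  )
}

#' @rdname catalog_io
#' @param drugs A `drug_catalog`.
#' @export
write_drug_table <- function(drugs, path) {
  out <- tibble(
    drug_id = drugs$drug_id,
    targets = map_chr(drugs$targets, join_set),
    modality = drugs$modality,
    routes = map_chr(drugs$routes, join_set),
    indications = map_chr(drugs$indications, join_set),
    side_effects = map_chr(drugs$side_effects, join_set)
  )
  readr::write_tsv(out, path)
  invisible(path)
}
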