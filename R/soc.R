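#' The 21 system-organ-class phenotype categories
#'
#' The analysis works at the level of MedDRA system organ classes (SOCs),
#' collapsed to a fixed vocabulary of 21 organ-system categories covering
#' drug indications, clinical-trial side effects, and the Mendelian/GWAS
#' phenotypes of drug-target genes. Administrative SOCs (social
#' circumstances, surgical procedures) are assumed removed upstream and are
#' not part of the vocabulary. The ordering is fixed and meaningful: report
#' tables and per-category results always follow it.
#'
#' @return A character vector of the 21 category labels, in canonical order.
#' @examples
#' soc_categories()
#' @export
soc_categories <- function() {
  c(
    "Blood", "Heart", "Congenital", "Ear", "Endocrine", "Eye",
    "Gastrointestinal", "Hepatobiliary", "Immune", "Infection",
    "Metabolism", "Musculoskeletal", "Neoplasm", "Nervous", "Pregnancy",
    "Mental", "Urologic", "Reproductive", "Respiratory", "Skin", "Vascular"
  )
}

# Validate a character vector of SOC labels against the fixed vocabulary.
# `what` names the offending field in the error message.
validate_socs <- function(socs, what = "SOC set") {
  socs <- socs[!is.na(socs) & nzchar(socs)]
  bad <- setdiff(unique(socs), soc_categories())
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown SOC label%s in %s: %s",
      if (length(bad) > 1) "s" else "", what,
      paste(bad, collapse = ", ")
    ))
  }
  unique(socs)
}

# Split a semicolon-delimited set field into a validated character vector.
parse_soc_set <- function(x, what) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  validate_socs(stringr::str_split_1(x, ";"), what)
}

join_set <- function(x) paste(x, collapse = ";")
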