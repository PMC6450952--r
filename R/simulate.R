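#' Configuration for the synthetic catalog generator
#'
#' Bundles and validates the parameters of the generative model used to
#' emulate the statistical structure of the drug-target-phenotype dataset:
#' drugs carry 1-3 targets drawn with preferential reuse (so distinct drugs
#' share target genes and whole target sets, exercising the grouped
#' cross-validation), genes carry Mendelian/GWAS phenotype SOC sets with a
#' configurable fraction left uninformative, indications are optionally
#' seeded from target phenotypes (the indication-genetics confounding seen
#' in real drug programs), and side effects are Bernoulli draws from a
#' per-organ logistic model.
#'
#' @param n_drugs,n_genes Catalog sizes.
#' @param targets_per_drug Integer range `c(min, max)` of targets per drug.
#' @param target_sharing Probability that a drug copies the entire target
#'   set of an earlier drug (otherwise targets are drawn gene-by-gene with
#'   popularity weighting).
#' @param baseline_logit Per-SOC intercepts (log-odds of a side effect
#'   absent any effect); length 1 or 21. The default spreads baseline
#'   side-effect rates from 3% to 35% across the 21 organ systems,
#'   mirroring the wide spread seen in trial data.
#' @param beta_genetic Log odds ratio added when the drug has genetic
#'   support (a MATCH) for the organ system.
#' @param beta_indication Log odds ratio added on-indication.
#' @param confounding Probability that each drug indication is drawn from
#'   the phenotype SOCs of its target genes rather than uniformly.
#' @param frac_no_mendelian,frac_no_gwas Fraction of genes with no
#'   phenotype information from each source.
#' @param covariate_effects Named log-OR vector for drug/gene covariates;
#'   recognised names: `modality_biological`, `route_enteral`,
#'   `route_parenteral`, `route_topical`, `route_other`, `expr_all`,
#'   `expr_mixed`, `expr_enriched`, `constrained`. Defaults to all zero.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_drugs = 50, seed = 7)
#' sim <- simulate_catalogs(cfg)
#' @export
sim_config <- function(n_drugs = 1000,
                       n_genes = max(10L, ceiling(0.6 * n_drugs)),
                       targets_per_drug = c(1L, 3L),
                       target_sharing = 0.3,
                       baseline_logit = qlogis(seq(0.03, 0.35, length.out = 21)),
                       beta_genetic = log(1.5),
                       beta_indication = log(2.5),
                       confounding = 0.25,
                       frac_no_mendelian = 0.5,
                       frac_no_gwas = 0.6,
                       covariate_effects = NULL,
                       seed = 1L) {
  stopifnot(
    n_drugs >= 0, n_genes >= 0,
    length(targets_per_drug) %in% c(1, 2),
    all(targets_per_drug >= 1), all(diff(targets_per_drug) >= 0)
  )
  fracs <- c(target_sharing, confounding, frac_no_mendelian, frac_no_gwas)
  if (any(fracs < 0 | fracs > 1)) abort("Probabilities must lie in [0, 1]")
  if (!length(baseline_logit) %in% c(1, 21)) {
    abort("baseline_logit must have length 1 or 21")
  }
  cov_names <- c(
    "modality_biological", paste0("route_", drug_routes()),
    paste0("expr_", c("all", "mixed", "enriched")), "constrained"
  )
  effects <- setNames(numeric(length(cov_names)), cov_names)
  if (!is.null(covariate_effects)) {
    bad <- setdiff(names(covariate_effects), cov_names)
    if (length(bad) > 0) abort(paste("Unknown covariate effect:", paste(bad, collapse = ", ")))
    effects[names(covariate_effects)] <- covariate_effects
  }
  structure(
    list(
      n_drugs = as.integer(n_drugs), n_genes = as.integer(n_genes),
      targets_per_drug = as.integer(rep_len(targets_per_drug, 2)),
      target_sharing = target_sharing,
      baseline_logit = rep_len(baseline_logit, 21),
      beta_genetic = beta_genetic, beta_indication = beta_indication,
      confounding = confounding,
      frac_no_mendelian = frac_no_mendelian, frac_no_gwas = frac_no_gwas,
      covariate_effects = effects, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Generate synthetic gene and drug catalogs
#'
#' Draws catalogs under the generative model described in [sim_config()].
#' One global random stream is consumed in a documented order - genes,
#' then drugs (targets, covariates, indications), then side effects - so
#' the same seed always yields byte-identical catalogs.
#'
#' @param config A `sim_config`.
#' @return A list with elements `genes` (a `gene_catalog`), `drugs` (a
#'   `drug_catalog`), and `config`.
#' @export
simulate_catalogs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  socs <- soc_categories()
  withr::with_seed(config$seed, {
    ## --- genes ---
    n_g <- config$n_genes
    gene_id <- sprintf("g%04d", seq_len(n_g))
    draw_sets <- function(frac_no) {
      informative <- runif(n_g) >= frac_no
      map(informative, function(on) {
        if (!on) return(character(0))
        sort(sample(socs, sample.int(4, 1)))
      })
    }
    mendelian_socs <- draw_sets(config$frac_no_mendelian)
    gwas_socs <- draw_sets(config$frac_no_gwas)
    constrained <- runif(n_g) < 0.3
    expression_breadth <- sample(
      expression_breadth_levels(), n_g,
      replace = TRUE, prob = c(0.35, 0.30, 0.25, 0.10)
    )
    genes <- gene_catalog(gene_id, mendelian_socs, gwas_socs, constrained, expression_breadth)

    ## --- drugs ---
    n_d <- config$n_drugs
    if (n_d == 0) {
      out <- list(genes = genes, drugs = drug_catalog(character(0), list()), config = config)
    } else {
    if (n_g == 0) abort("Cannot simulate drugs without genes")
    usage <- rep(1, n_g)
    targets <- vector("list", n_d)
    k_range <- config$targets_per_drug
    for (i in seq_len(n_d)) {
      if (i > 1 && runif(1) < config$target_sharing) {
        targets[[i]] <- targets[[sample.int(i - 1, 1)]]
      } else {
        k <- if (k_range[1] == k_range[2]) k_range[1] else sample(seq(k_range[1], k_range[2]), 1)
        k <- min(k, n_g)
        idx <- sample.int(n_g, k, prob = usage)
        targets[[i]] <- gene_id[sort(idx)]
      }
      usage[match(targets[[i]], gene_id)] <- usage[match(targets[[i]], gene_id)] + 1
    }
    modality <- ifelse(runif(n_d) < 0.2, "biological", "small_molecule")
    routes <- map(seq_len(n_d), function(i) {
      sort(sample(drug_routes(), sample.int(2, 1)))
    })
    phenos_of <- function(tg) {
      gi <- match(tg, gene_id)
      unique(c(unlist(mendelian_socs[gi]), unlist(gwas_socs[gi])))
    }
    indications <- map(seq_len(n_d), function(i) {
      n_ind <- sample.int(2, 1)
      pool <- phenos_of(targets[[i]])
      unique(map_chr(seq_len(n_ind), function(j) {
        if (length(pool) > 0 && runif(1) < config$confounding) {
          sample(pool, 1)
        } else {
          sample(socs, 1)
        }
      }))
    })
    drugs <- drug_catalog(
      drug_id = sprintf("d%04d", seq_len(n_d)),
      targets = targets, modality = modality, routes = routes,
      indications = indications,
      side_effects = rep(list(character(0)), n_d),
      genes = genes
    )

    ## --- side effects ---
    mats <- catalog_matrices(drugs, genes)
    sup <- support_from_matrices(mats)
    any_support <- sup$mendelian == "MATCH" | sup$gwas == "MATCH"
    eff <- config$covariate_effects
    route_mat <- vapply(drug_routes(), function(r) map_lgl(routes, ~ r %in% .x), logical(n_d))
    expr_drug <- vapply(c("all", "mixed", "enriched"), function(lv) {
      as.vector(mats$Tm %*% (expression_breadth == lv)) > 0
    }, logical(n_d))
    constr_drug <- as.vector(mats$Tm %*% constrained) > 0
    cov_eta <- eff[["modality_biological"]] * (modality == "biological") +
      route_mat %*% eff[paste0("route_", drug_routes())] +
      expr_mat_eta(expr_drug, eff) +
      eff[["constrained"]] * constr_drug
    eta <- matrix(config$baseline_logit, n_d, 21, byrow = TRUE) +
      config$beta_genetic * any_support +
      config$beta_indication * mats$ind +
      as.vector(cov_eta)
    se_mat <- matrix(rbinom(n_d * 21, 1, plogis(as.vector(eta))), n_d, 21)
    drugs$side_effects <- map(seq_len(n_d), function(i) socs[se_mat[i, ] == 1])
    out <- list(genes = genes, drugs = drugs, config = config)
    }
    out
  })
}

expr_mat_eta <- function(expr_drug, eff) {
  expr_drug %*% eff[paste0("expr_", c("all", "mixed", "enriched"))]
}

#' Hand-written six-drug fixture
#'
#' A small catalog pair whose observation flags can be enumerated by hand,
#' used across the package tests: five genes (one with no genetic
#' information), six drugs, two of which share an identical target set.
#'
#' @return A list with `genes` and `drugs` catalogs.
#' @examples
#' fx <- fixture_small()
#' build_observations(fx$drugs, fx$genes)
#' @export
fixture_small <- function() {
  genes <- gene_catalog(
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    mendelian_socs = list(
      c("Heart", "Blood"), character(0), "Skin", character(0), "Endocrine"
    ),
    gwas_socs = list(
      character(0), "Nervous", "Skin", character(0), "Heart"
    ),
    constrained = c(TRUE, FALSE, FALSE, TRUE, FALSE),
    expression_breadth = c("all", "mixed", "enriched", "none_detected", "all")
  )
  drugs <- drug_catalog(
    drug_id = c("d1", "d2", "d3", "d4", "d5", "d6"),
    targets = list("g1", "g1", c("g2", "g3"), "g4", c("g1", "g5"), "g3"),
    modality = c(
      "small_molecule", "biological", "small_molecule",
      "small_molecule", "biological", "small_molecule"
    ),
    routes = list(
      "enteral", "parenteral", c("enteral", "topical"),
      "other", "parenteral", "topical"
    ),
    indications = list("Heart", "Vascular", "Skin", "Mental", "Endocrine", "Skin"),
    side_effects = list(
      c("Heart", "Skin"), "Blood", "Nervous", character(0), "Heart", "Skin"
    ),
    genes = genes
  )
  list(genes = genes, drugs = drugs)
}
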