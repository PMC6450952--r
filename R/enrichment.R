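# Normalise a 2x2 contingency input to a named numeric vector (a, b, c, d):
# a = support & side effect, b = support & none,
# c = no support & side effect, d = neither.
as_contingency <- function(x) {
  if (is.list(x) && !is.data.frame(x)) x <- unlist(x)
  if (length(x) != 4 || anyNA(x) || any(x < 0) || any(x != round(x))) {
    abort("A contingency table must be four nonnegative integer counts (a, b, c, d)")
  }
  setNames(as.numeric(x), c("a", "b", "c", "d"))
}

#' Fisher's exact test for a 2x2 table
#'
#' `fisher_exact_two_tailed()` computes the two-sided p-value by the
#' probability-mass rule: the sum, over all tables with the observed
#' margins, of hypergeometric point probabilities no greater than that of
#' the observed table (within a relative tolerance of 1e-7, the standard
#' convention). `fisher_exact_one_tailed_greater()` is the upper tail
#' P(A >= a), used for the treatment-versus-placebo arm comparison. Both
#' return 1 when any margin is zero.
#'
#' @param table Counts `c(a, b, c, d)`: support-and-side-effect,
#'   support-only, side-effect-only, neither.
#' @return A p-value in \[0, 1\].
#' @examples
#' fisher_exact_two_tailed(c(145, 176, 451, 1047))
#' fisher_exact_one_tailed_greater(c(8, 2, 2, 8))
#' @export
fisher_exact_two_tailed <- function(table) {
  tab <- as_contingency(table)
  a <- tab[["a"]]
  m <- tab[["a"]] + tab[["b"]]
  n <- tab[["c"]] + tab[["d"]]
  k <- tab[["a"]] + tab[["c"]]
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  support <- max(0, k - n):min(k, m)
  dens <- dhyper(support, m, n, k)
  d_obs <- dhyper(a, m, n, k)
  min(1, sum(dens[dens <= d_obs * (1 + 1e-7)]))
}

#' @rdname fisher_exact_two_tailed
#' @export
fisher_exact_one_tailed_greater <- function(table) {
  tab <- as_contingency(table)
  m <- tab[["a"]] + tab[["b"]]
  n <- tab[["c"]] + tab[["d"]]
  k <- tab[["a"]] + tab[["c"]]
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  phyper(tab[["a"]] - 1, m, n, k, lower.tail = FALSE)
}

#' Odds ratio with Woolf confidence interval
#'
#' The unconditional cross-product odds ratio (a*d)/(b*c) with the Woolf
#' normal interval on the log scale:
#' exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d)). With a zero cell the
#' raw estimator is reported as `Inf`, 0, or `NA` (both diagonals zero) and
#' the interval is `NA`, unless `haldane = TRUE`, which adds 0.5 to every
#' cell for the interval (display only; the point estimate stays raw).
#'
#' @inheritParams fisher_exact_two_tailed
#' @param z Normal quantile for the interval; default 1.959964 (95%).
#' @param haldane Use the Haldane-Anscombe +0.5 correction for the CI when
#'   a cell is zero. Default `FALSE`.
#' @return A list with `odds_ratio`, `ci_low`, `ci_high`.
#' @examples
#' odds_ratio_ci(c(2512, 5862, 5729, 24096))
#' @export
odds_ratio_ci <- function(table, z = 1.959964, haldane = FALSE) {
  tab <- as_contingency(table)
  a <- tab[["a"]]; b <- tab[["b"]]; c <- tab[["c"]]; d <- tab[["d"]]
  num <- a * d
  den <- b * c
  or <- if (num == 0 && den == 0) NA_real_ else if (den == 0) Inf else num / den
  if (all(tab > 0)) {
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    return(list(
      odds_ratio = or,
      ci_low = exp(log(or) - z * se),
      ci_high = exp(log(or) + z * se)
    ))
  }
  if (haldane) {
    ah <- a + 0.5; bh <- b + 0.5; ch <- c + 0.5; dh <- d + 0.5
    se <- sqrt(1 / ah + 1 / bh + 1 / ch + 1 / dh)
    lor <- log(ah * dh / (bh * ch))
    return(list(odds_ratio = or, ci_low = exp(lor - z * se), ci_high = exp(lor + z * se)))
  }
  list(odds_ratio = or, ci_low = NA_real_, ci_high = NA_real_)
}

#' Cross-classify observations into a 2x2 contingency table
#'
#' Counts drug x SOC observations by (genetic support, side effect):
#' `a` supported with side effect, `b` supported without, `c` unsupported
#' with, `d` unsupported without.
#'
#' @param observations Observation tibble from [build_observations()].
#' @param support `"any"` (MATCH from either source), `"mendelian"`,
#'   `"gwas"`, or a predicate function taking the observation tibble and
#'   returning a logical vector.
#' @param soc Optional single SOC label restricting the count.
#' @return Named integer vector `c(a, b, c, d)`.
#' @export
tabulate_observations <- function(observations, support = "any", soc = NULL) {
  if (!is.null(soc)) {
    soc <- validate_socs(soc, "soc filter")
    observations <- observations[observations$soc == soc, ]
  }
  sup <- support_predicate(support)(observations)
  stopifnot(length(sup) == nrow(observations), !anyNA(sup))
  se <- observations$side_effect
  c(
    a = sum(sup & se), b = sum(sup & !se),
    c = sum(!sup & se), d = sum(!sup & !se)
  )
}

support_predicate <- function(support) {
  if (is.function(support)) return(support)
  switch(support,
    any = function(obs) obs$any_support,
    mendelian = function(obs) obs$mendelian == "MATCH",
    gwas = function(obs) obs$gwas == "MATCH",
    abort(sprintf("Unknown support source '%s'", support))
  )
}

enrichment_row <- function(tab, soc_label) {
  or <- odds_ratio_ci(tab)
  tibble(
    soc = soc_label,
    a = tab[["a"]], b = tab[["b"]], c = tab[["c"]], d = tab[["d"]],
    rate_support = if (tab[["a"]] + tab[["b"]] > 0) tab[["a"]] / (tab[["a"]] + tab[["b"]]) else NA_real_,
    rate_no_support = if (tab[["c"]] + tab[["d"]] > 0) tab[["c"]] / (tab[["c"]] + tab[["d"]]) else NA_real_,
    odds_ratio = or$odds_ratio, ci_low = or$ci_low, ci_high = or$ci_high,
    p_two_tailed = fisher_exact_two_tailed(tab)
  )
}

#' Enrichment of side effects among genetically supported drug-organ pairs
#'
#' Tests whether side effects are more frequent in organ systems where a
#' drug's targets have genetic phenotypes than where they do not. In pooled
#' mode all observations form a single 2x2 table; in per-SOC mode each of
#' the 21 organ systems gets its own table and test (no multiplicity
#' adjustment, matching the raw per-category report convention).
#'
#' @inheritParams tabulate_observations
#' @param per_soc Return one row per SOC instead of the pooled row.
#' @param support_source `"any"`, `"mendelian"`, or `"gwas"`.
#' @return A tibble of class `enrichment_tbl` with columns `soc`, counts
#'   `a`-`d`, the two side-effect rates, `odds_ratio`, `ci_low`, `ci_high`,
#'   `p_two_tailed`. Pooled mode yields a single row with `soc = "Total"`.
#' @examples
#' fx <- fixture_small()
#' build_observations(fx$drugs, fx$genes) |> enrichment_analysis()
#' @export
enrichment_analysis <- function(observations, per_soc = FALSE,
                                support_source = c("any", "mendelian", "gwas")) {
  support_source <- match.arg(support_source)
  if (!per_soc && nrow(observations) == 0) abort("No observations to analyse")
  if (per_soc) {
    out <- bind_rows(map(
      soc_categories(),
      ~ enrichment_row(tabulate_observations(observations, support_source, soc = .x), .x)
    ))
  } else {
    out <- enrichment_row(tabulate_observations(observations, support_source), "Total")
  }
  class(out) <- unique(c("enrichment_tbl", class(out)))
  attr(out, "support_source") <- support_source
  attr(out, "mode") <- attr(observations, "mode") %||% "all"
  out
}

#' De-risk split: mismatched genetics versus missing genetics
#'
#' Among drug-organ pairs with no genetic support for the queried organ
#' system, compares side-effect rates between pairs where every target gene
#' carries some genetic information (so the absence of a matching phenotype
#' is informative - a mismatch) and pairs where at least one target has no
#' genetic data at all (the absence may just be missing information). An
#' odds ratio below 1 supports using absent phenotypes as target de-risking
#' evidence.
#'
#' @inheritParams tabulate_observations
#' @return A one-row `enrichment_tbl`; `a`-`d` count (informative, side
#'   effect), (informative, none), (uninformative, side effect),
#'   (uninformative, none).
#' @export
derisk_analysis <- function(observations) {
  unsupported <- observations[!observations$any_support, ]
  exposed <- unsupported$all_targets_informative
  if (!any(exposed)) abort("Empty stratum: no unsupported pair has all targets informative")
  if (all(exposed)) abort("Empty stratum: no unsupported pair has an uninformative target")
  se <- unsupported$side_effect
  tab <- c(
    a = sum(exposed & se), b = sum(exposed & !se),
    c = sum(!exposed & se), d = sum(!exposed & !se)
  )
  out <- enrichment_row(tab, "derisk")
  class(out) <- unique(c("enrichment_tbl", class(out)))
  out
}

#' Diagnostic accuracy of genetic support as a side-effect test
#'
#' Treats genetic support as a diagnostic test for whether a side effect
#' manifests: sensitivity a/(a+c), specificity d/(b+d), positive likelihood
#' ratio LR+ = sensitivity/(1-specificity), and the inverse negative
#' likelihood ratio iLR- = specificity/(1-sensitivity), so that values
#' above 1 read as predictive for both positive and negative findings.
#' Undefined ratios (zero denominators) are returned as `NA`.
#'
#' @inheritParams fisher_exact_two_tailed
#' @return A one-row tibble with `sensitivity`, `specificity`, `lr_plus`,
#'   `ilr_minus`.
#' @examples
#' diagnostic_metrics(c(2512, 5862, 5729, 24096))
#' @export
diagnostic_metrics <- function(table) {
  tab <- as_contingency(table)
  if (tab[["a"]] + tab[["c"]] == 0 || tab[["b"]] + tab[["d"]] == 0) {
    abort("Diagnostic metrics need at least one positive and one negative case")
  }
  sens <- tab[["a"]] / (tab[["a"]] + tab[["c"]])
  spec <- tab[["d"]] / (tab[["b"]] + tab[["d"]])
  tibble(
    sensitivity = sens,
    specificity = spec,
    lr_plus = if (spec < 1) sens / (1 - spec) else NA_real_,
    ilr_minus = if (sens < 1) spec / (1 - sens) else NA_real_
  )
}

#' Flag adverse events more common in the treatment arm than placebo
#'
#' One-tailed Fisher comparison of event rates between the treatment and
#' placebo arms of a trial; an event is considered drug-related (kept) when
#' the treatment-arm rate exceeds the placebo rate with p below `alpha`.
#'
#' @param treatment,placebo Integer pairs `c(events, n)` for each arm.
#' @param alpha Significance level; default 0.05.
#' @return A list with `keep` (logical) and `p`.
#' @examples
#' arm_association_filter(c(8, 10), c(2, 10))
#' @export
arm_association_filter <- function(treatment, placebo, alpha = 0.05) {
  stopifnot(length(treatment) == 2, length(placebo) == 2)
  if (treatment[2] == 0 || placebo[2] == 0) abort("Arm with zero participants")
  if (treatment[1] > treatment[2] || placebo[1] > placebo[2]) {
    abort("Arm events exceed arm size")
  }
  tab <- c(
    a = treatment[1], b = treatment[2] - treatment[1],
    c = placebo[1], d = placebo[2] - placebo[1]
  )
  p <- fisher_exact_one_tailed_greater(tab)
  rate_gt <- treatment[1] / treatment[2] > placebo[1] / placebo[2]
  list(keep = unname(p < alpha && rate_gt), p = unname(p))
}
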