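#' Organ systems eligible for regression modelling
#'
#' Per-organ side-effect models are only fit where enough drugs elicit a
#' side effect in that organ system: categories with at least `min_count`
#' affected drugs (default 100, about 5% of the reference dataset) are
#' modelled; the rest are too sparse for stable multivariate fits.
#'
#' @param x Either a `drug_catalog` (affected drugs counted from its
#'   `side_effects` sets), a tibble with columns `soc`, `a`, `c` (per-SOC
#'   contingency counts, affected = `a + c`, as in
#'   [reference_soc_counts()]), or a named numeric vector of per-SOC
#'   counts.
#' @param min_count Minimum number of affected drugs. Default 100.
#' @return Character vector of eligible SOC labels, in canonical order.
#' @examples
#' eligible_categories(reference_soc_counts())
#' @export
eligible_categories <- function(x, min_count = 100) {
  socs <- soc_categories()
  counts <- if (is.data.frame(x) && all(c("a", "c") %in% names(x))) {
    setNames(x$a + x$c, x$soc)
  } else if (is.data.frame(x)) {
    se <- unlist(validate_drug_catalog(x)$side_effects)
    table(factor(se, levels = socs))
  } else {
    x
  }
  counts <- counts[match(socs, names(counts))]
  counts[is.na(counts)] <- 0
  socs[counts >= min_count]
}

# Drug-level covariates derived from the catalogs: indication indicators
# (20 SOCs, Neoplasm excluded as in the reference analysis), modality,
# non-exclusive route flags, expression breadth and constraint aggregated
# over targets, plus the four genetic-support indicators for the modeled
# SOC (baseline NO_INFO).
design_columns <- function(drugs, genes, soc, expression_matrix = NULL) {
  socs <- soc_categories()
  mats <- catalog_matrices(drugs, genes)
  sup <- support_from_matrices(mats)
  ind_socs <- setdiff(socs, "Neoplasm")
  pred <- as_tibble(setNames(
    map(ind_socs, ~ as.integer(mats$ind[, .x])),
    paste0("ind_", ind_socs)
  ))
  pred$modality_biological <- as.integer(drugs$modality == "biological")
  for (r in drug_routes()) {
    pred[[paste0("route_", r)]] <- map_int(drugs$routes, ~ as.integer(r %in% .x))
  }
  if (is.null(expression_matrix)) {
    for (lv in c("all", "mixed", "enriched")) {
      pred[[paste0("expr_", lv)]] <-
        as.integer(as.vector(mats$Tm %*% (genes$expression_breadth == lv)) > 0)
    }
  } else {
    idx <- match(genes$gene_id, rownames(expression_matrix))
    if (anyNA(idx)) abort("expression_matrix must have a row for every gene")
    n_targets <- rowSums(mats$Tm)
    avg <- (mats$Tm %*% expression_matrix[idx, , drop = FALSE]) / n_targets
    for (j in seq_len(ncol(avg))) {
      pred[[paste0("expr_", colnames(expression_matrix)[j])]] <- as.vector(avg[, j])
    }
  }
  pred$constrained <- as.integer(as.vector(mats$Tm %*% genes$constrained) > 0)
  pred$mend_match <- as.integer(sup$mendelian[, soc] == "MATCH")
  pred$mend_mismatch <- as.integer(sup$mendelian[, soc] == "MISMATCH")
  pred$gwas_match <- as.integer(sup$gwas[, soc] == "MATCH")
  pred$gwas_mismatch <- as.integer(sup$gwas[, soc] == "MISMATCH")
  list(pred = pred, se = mats$se, ind = mats$ind)
}

#' Build the regression design for one organ-system model
#'
#' One row per drug; the response is whether the drug elicited a side
#' effect in the modeled organ system. Predictors: 20 indication
#' indicators (all SOCs except Neoplasm), modality (biological vs the
#' small-molecule baseline), four non-exclusive delivery-route indicators,
#' three expression-breadth indicators (baseline `none_detected`) or - when
#' `expression_matrix` is supplied - per-tissue mean expression of the
#' targets, a constraint indicator, and MATCH/MISMATCH indicators for
#' Mendelian and GWAS support (baseline NO_INFO). With
#' `exclude_on_indication = TRUE`, drugs pursued for an indication in the
#' modeled organ system are dropped.
#'
#' @param drugs,genes The catalogs.
#' @param soc The modeled SOC label.
#' @param exclude_on_indication Drop drugs indicated in `soc`.
#' @param expression_matrix Optional numeric matrix (genes x tissues,
#'   rownames = gene ids, e.g. log2(TPM+1)) replacing the breadth
#'   indicators with per-tissue target means.
#' @return An object of class `ts_design`: list with `response` (0/1
#'   integer vector), `predictors` (tibble), `drug_id`, `soc`,
#'   `off_indication`.
#' @export
build_design <- function(drugs, genes, soc, exclude_on_indication = FALSE,
                         expression_matrix = NULL) {
  soc <- validate_socs(soc, "modeled SOC")
  stopifnot(length(soc) == 1)
  cols <- design_columns(drugs, genes, soc, expression_matrix)
  keep <- if (exclude_on_indication) !cols$ind[, soc] else rep(TRUE, nrow(drugs))
  response <- as.integer(cols$se[keep, soc])
  if (length(response) == 0) abort(sprintf("No drugs left for SOC %s after exclusion", soc))
  if (length(unique(response)) < 2) {
    abort(sprintf("Constant response for SOC %s: %d rows, all %d", soc, length(response), response[1]))
  }
  structure(
    list(
      response = response,
      predictors = cols$pred[keep, ],
      drug_id = drugs$drug_id[keep],
      soc = soc, off_indication = exclude_on_indication
    ),
    class = "ts_design"
  )
}

#' Pooled observation-level design across all organ systems
#'
#' Stacks every drug x SOC observation into one logistic design with
#' per-SOC intercept offsets (20 indicators, first category baseline),
#' the four genetic-support indicators, and the on-indication flag. This
#' is the generative model of the synthetic-data module, so fitting it
#' with [fit_logistic()] on simulated data recovers the generator's
#' genetic log odds ratio directly (parameter-recovery check).
#'
#' @param observations An observation tibble from [build_observations()].
#' @return A `ts_design` (with `soc = "pooled"`).
#' @export
build_pooled_design <- function(observations) {
  socs <- soc_categories()
  pred <- as_tibble(setNames(
    map(socs[-1], ~ as.integer(observations$soc == .x)),
    paste0("soc_", socs[-1])
  ))
  pred$mend_match <- as.integer(observations$mendelian == "MATCH")
  pred$mend_mismatch <- as.integer(observations$mendelian == "MISMATCH")
  pred$gwas_match <- as.integer(observations$gwas == "MATCH")
  pred$gwas_mismatch <- as.integer(observations$gwas == "MISMATCH")
  pred$on_indication <- as.integer(observations$on_indication)
  keep <- map_lgl(pred, ~ length(unique(.x)) > 1)
  structure(
    list(
      response = as.integer(observations$side_effect),
      predictors = pred[keep],
      drug_id = observations$drug_id,
      soc = "pooled", off_indication = FALSE
    ),
    class = "ts_design"
  )
}

ts_fit <- function(terms, converged, method, lambda = NA_real_, n = NA_integer_,
                   loglik = NA_real_) {
  structure(
    list(terms = terms, converged = converged, method = method,
         lambda = lambda, n = n, loglik = loglik),
    class = "ts_fit"
  )
}

#' Fit the multivariate logistic side-effect model
#'
#' Maximum-likelihood logistic regression of the side-effect response on
#' the full predictor set, with Wald standard errors, p-values, and 95%
#' confidence intervals; coefficients are exponentiated to odds ratios.
#' Perfect separation is reported via `converged = FALSE` (with a warning)
#' rather than an error, with coefficients still returned. Aliased
#' (collinear) columns get `NA` coefficients; a condition-number warning
#' flags near-collinear designs.
#'
#' @param design A `ts_design` from [build_design()], or any list with
#'   `response` and `predictors`.
#' @return A `ts_fit`; inspect with [tidy()] / [glance()].
#' @export
fit_logistic <- function(design) {
  y <- design$response
  X <- as.matrix(design$predictors)
  if (length(unique(y)) < 2) abort("Response is constant")
  if (nrow(X) <= ncol(X) + 1) warn("Fewer rows than predictors; estimates will be unstable")
  dat <- data.frame(.y = y, X, check.names = FALSE)
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = dat, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (separated) warn("Possible perfect separation; coefficients reported but not converged")
  sm <- summary(fit)$coefficients
  cn <- kappa(qr.R(fit$qr))
  if (is.finite(cn) && cn > 1e8) warn(sprintf("Ill-conditioned design (condition number %.3g)", cn))
  all_terms <- c("(Intercept)", colnames(X))
  idx <- match(all_terms, rownames(sm))
  z <- qnorm(0.975)
  est <- sm[, "Estimate"][idx]
  se <- sm[, "Std. Error"][idx]
  terms <- tibble(
    term = all_terms,
    estimate = unname(est),
    std_error = unname(se),
    p_value = unname(sm[, "Pr(>|z|)"][idx]),
    odds_ratio = exp(unname(est)),
    ci_low = exp(unname(est - z * se)),
    ci_high = exp(unname(est + z * se)),
    selected = NA
  )
  ts_fit(terms,
    converged = fit$converged && !separated, method = "glm",
    n = length(y), loglik = as.numeric(stats::logLik(fit))
  )
}

# Bare-matrix IRLS fit used in the cross-validation hot path; the same
# maximum-likelihood logistic model as fit_logistic without the inference
# bookkeeping. A lean Newton iteration on the cross-product matrices (with
# a vanishing ridge for rank-deficient training subsets, e.g. constant
# columns); falls back to glm.fit on numerical failure. Returns
# coefficients (aliased/degenerate directions as 0) for an
# intercept-first design. `start` warm-starts the iteration (fold models
# differ little from the all-data fit).
fit_logistic_fast <- function(X, y, start = NULL) {
  X1 <- cbind(1, X)
  p <- ncol(X1)
  beta <- if (!is.null(start) && length(start) == p) start else numeric(p)
  dev_old <- Inf
  ok <- FALSE
  for (iter in 1:30) {
    eta <- drop(X1 %*% beta)
    mu <- plogis(eta)
    dev <- -2 * sum(y * log(pmax(mu, 1e-12)) + (1 - y) * log(pmax(1 - mu, 1e-12)))
    if (abs(dev_old - dev) / (abs(dev) + 0.1) < 1e-9) { ok <- TRUE; break }
    dev_old <- dev
    w <- pmax(mu * (1 - mu), 1e-10)
    XtWX <- crossprod(X1 * w, X1)
    diag(XtWX) <- diag(XtWX) + 1e-10
    step <- tryCatch(
      solve(XtWX, crossprod(X1, y - mu)),
      error = function(e) NULL
    )
    if (is.null(step) || anyNA(step)) break
    beta <- beta + drop(step)
  }
  if (!ok) {
    fit <- suppressWarnings(glm.fit(X1, y, family = binomial(), start = start))
    beta <- coef(fit)
    beta[is.na(beta)] <- 0
  }
  names(beta) <- c("(Intercept)", colnames(X))
  beta
}

#' Fit the lasso-penalised logistic model at a given penalty
#'
#' L1-penalised logistic regression (intercept unpenalised, predictors
#' standardised internally as is conventional); predictors with nonzero
#' coefficients at the chosen penalty are flagged as selected. At
#' `lam = 0` the fit coincides with the unpenalised maximum-likelihood
#' solution.
#'
#' @inheritParams fit_logistic
#' @param lam Nonnegative penalty.
#' @param standardize Standardise predictors internally before penalising
#'   (the conventional default).
#' @return A `ts_fit` with `selected` flags and no Wald inference (the
#'   penalised estimator has no standard errors).
#' @export
fit_lasso <- function(design, lam, standardize = TRUE) {
  stopifnot(lam >= 0)
  y <- design$response
  X <- as.matrix(design$predictors)
  if (length(unique(y)) < 2) abort("Response is constant")
  fit <- glmnet::glmnet(X, y, family = "binomial", thresh = 1e-12,
                        standardize = standardize)
  cf <- as.matrix(coef(fit, s = lam, exact = TRUE, x = X, y = y, thresh = 1e-12,
                       standardize = standardize))[, 1]
  terms <- tibble(
    term = names(cf),
    estimate = unname(cf),
    std_error = NA_real_,
    p_value = NA_real_,
    odds_ratio = exp(unname(cf)),
    ci_low = NA_real_,
    ci_high = NA_real_,
    selected = names(cf) != "(Intercept)" & cf != 0
  )
  ts_fit(terms, converged = TRUE, method = "glmnet", lambda = lam, n = length(y))
}

# Stratified fold labels: each response class is split as evenly as
# possible across folds.
stratified_foldid <- function(y, n_folds) {
  foldid <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  foldid
}

#' Select the lasso penalty by repeated cross-validated AUC
#'
#' Runs `n_folds`-fold cross-validation `n_repeats` times over a fixed
#' 100-point log-spaced lambda grid (from the smallest all-zeroing penalty
#' down by a factor of 1e-4). Each repeat records `lambda.min` (highest
#' cross-validated AUC) and `lambda.1se` (largest lambda with AUC within
#' one standard error of the maximum, SE taken across folds within the
#' repeat); the final penalty is the average of the two means. Folds are
#' stratified by response; a repeat whose folds degenerate to a single
#' class is refolded from a fresh substream.
#'
#' @inheritParams fit_logistic
#' @param n_repeats Number of CV repetitions. Default 100.
#' @param n_folds Folds per repetition. Default 10.
#' @param seed Master seed; the procedure is deterministic given it.
#' @return A list with `lambda_star`, `lambda_min_mean`, `lambda_1se_mean`,
#'   and `runs` (tibble of per-repeat `lambda_min`, `lambda_1se`).
#' @export
select_lambda <- function(design, n_repeats = 100, n_folds = 10, seed = 1L) {
  y <- design$response
  X <- as.matrix(design$predictors)
  if (min(table(y)) < n_folds) {
    abort("Too few observations in the rarer class for stratified folds")
  }
  fit0 <- glmnet::glmnet(X, y, family = "binomial")
  lmax <- max(fit0$lambda)
  grid <- exp(seq(log(lmax), log(lmax * 1e-4), length.out = 100))
  run_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n_repeats))
  one_run <- function(s) {
    for (attempt in 1:5) {
      foldid <- withr::with_seed(s + attempt - 1L, stratified_foldid(y, n_folds))
      res <- tryCatch(
        glmnet::cv.glmnet(X, y, family = "binomial", type.measure = "auc",
                          foldid = foldid, lambda = grid),
        error = function(e) NULL
      )
      if (!is.null(res)) {
        return(tibble(lambda_min = res$lambda.min, lambda_1se = res$lambda.1se))
      }
      warn(sprintf("Degenerate folds in CV repeat (seed %d); refolding", s))
    }
    abort("Repeated fold degeneracy in lambda selection")
  }
  runs <- bind_rows(map(run_seeds, one_run))
  lambda_min_mean <- mean(runs$lambda_min)
  lambda_1se_mean <- mean(runs$lambda_1se)
  list(
    lambda_star = (lambda_min_mean + lambda_1se_mean) / 2,
    lambda_min_mean = lambda_min_mean,
    lambda_1se_mean = lambda_1se_mean,
    runs = runs
  )
}

#' @export
print.ts_fit <- function(x, ...) {
  cat(sprintf(
    "Logistic side-effect model (%s)%s: %d rows, %d terms, converged: %s\n",
    x$method,
    if (!is.na(x$lambda)) sprintf(", lambda = %.4g", x$lambda) else "",
    x$n, nrow(x$terms), x$converged
  ))
  print(x$terms, n = 8)
  invisible(x)
}

#' Broom-style accessors for side-effect model fits
#'
#' `tidy()` returns the per-term coefficient table (log-odds estimate,
#' Wald SE/p/CI where available, exponentiated odds ratio, and the lasso
#' selection flag); `glance()` returns a one-row model summary.
#'
#' @param x A `ts_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ts_fit <- function(x, ...) x$terms

#' @rdname tidy.ts_fit
#' @export
glance.ts_fit <- function(x, ...) {
  tibble(
    method = x$method, n = x$n, n_terms = nrow(x$terms),
    n_selected = sum(x$terms$selected, na.rm = TRUE),
    lambda = x$lambda, loglik = x$loglik, converged = x$converged
  )
}
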