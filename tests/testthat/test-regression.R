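# slow independent oracle: proximal-gradient (ISTA) solver for the
# unstandardised lasso logistic objective (1/n) * deviance/2 + lam * |beta|
ista_lasso <- function(X, y, lam, iters = 60000, step = NULL) {
  X1 <- cbind(1, X)
  n <- nrow(X1)
  p <- ncol(X1)
  if (is.null(step)) step <- 4 / max(eigen(crossprod(X1) / n, only.values = TRUE)$values)
  beta <- numeric(p)
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  for (i in seq_len(iters)) {
    mu <- plogis(drop(X1 %*% beta))
    grad <- drop(crossprod(X1, mu - y)) / n
    beta_new <- beta - step * grad
    beta_new[-1] <- soft(beta_new[-1], step * lam)
    if (max(abs(beta_new - beta)) < 1e-10) { beta <- beta_new; break }
    beta <- beta_new
  }
  beta
}

test_that("category eligibility follows the minimum affected-drug count", {
  counts <- setNames(rep(5, 21), soc_categories())
  expect_equal(eligible_categories(counts, min_count = 1), soc_categories())
  expect_equal(eligible_categories(counts, min_count = 6), character(0))
  empty <- drug_catalog(character(0), list())
  expect_equal(eligible_categories(empty), character(0))
  fx <- fixture_small()
  expect_setequal(
    eligible_categories(fx$drugs, min_count = 2),
    c("Heart", "Skin")  # Heart: d1, d5; Skin: d1, d6
  )
})

test_that("design matrices carry the documented predictor encoding", {
  fx <- fixture_small()
  d <- build_design(fx$drugs, fx$genes, "Heart")
  expect_equal(length(d$response), 6)
  expect_equal(d$response, as.integer(c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE)))
  expect_equal(sum(startsWith(names(d$predictors), "ind_")), 20)
  expect_false("ind_Neoplasm" %in% names(d$predictors))
  expect_equal(d$predictors$mend_match, c(1, 1, 0, 0, 1, 0))
  expect_equal(d$predictors$mend_mismatch, c(0, 0, 1, 0, 0, 1))
  expect_equal(d$predictors$gwas_match, c(0, 0, 0, 0, 1, 0))
  expect_equal(d$predictors$modality_biological, c(0, 1, 0, 0, 1, 0))
  expect_equal(d$predictors$route_topical, c(0, 0, 1, 0, 0, 1))
  expect_equal(d$predictors$constrained, c(1, 1, 0, 1, 1, 0))
  # excluding on-indication drugs drops the Heart-indicated d1
  d_off <- build_design(fx$drugs, fx$genes, "Heart", exclude_on_indication = TRUE)
  expect_false("d1" %in% d_off$drug_id)
  expect_equal(length(d_off$response), 5)
  # constant response is refused with a diagnostic
  expect_error(build_design(fx$drugs, fx$genes, "Ear"), "Constant response")
})

test_that("continuous expression columns replace the breadth indicators", {
  fx <- fixture_small()
  em <- matrix(rnorm(10), 5, 2, dimnames = list(fx$genes$gene_id, c("liver", "brain")))
  d <- build_design(fx$drugs, fx$genes, "Heart", expression_matrix = em)
  expect_true(all(c("expr_liver", "expr_brain") %in% names(d$predictors)))
  expect_false("expr_all" %in% names(d$predictors))
  # d3 targets g2 and g3: column is the mean over targets
  expect_equal(d$predictors$expr_liver[3], mean(em[c("g2", "g3"), "liver"]))
})

test_that("logistic fit matches the closed-form saturated 2x2 solution", {
  a <- 2512; b <- 5862; c <- 5729; d <- 24096
  design <- list(
    response = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)),
    predictors = tibble::tibble(support = c(rep(1, a + b), rep(0, c + d)))
  )
  fit <- fit_logistic(design)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "support"], log(a * d / (b * c)), tolerance = 1e-8)
  expect_equal(td$estimate[td$term == "(Intercept)"], log(c / d), tolerance = 1e-8)
  expect_equal(td$odds_ratio, exp(td$estimate), tolerance = 1e-12)
  expect_true(glance(fit)$converged)
  expect_error(fit_logistic(list(response = rep(1, 5), predictors = tibble::tibble(x = 1:5))),
               "constant")
})

test_that("logistic log-likelihood matches a generic convex optimiser", {
  set.seed(21)
  n <- 300
  X <- cbind(x1 = rbinom(n, 1, 0.4), x2 = rnorm(n), x3 = rbinom(n, 1, 0.2))
  y <- rbinom(n, 1, plogis(-0.3 + 0.8 * X[, 1] - 0.5 * X[, 3]))
  fit <- fit_logistic(list(response = y, predictors = tibble::as_tibble(X)))
  nll <- function(beta) {
    eta <- drop(cbind(1, X) %*% beta)
    -sum(y * eta - log1p(exp(eta)))
  }
  opt <- optim(numeric(4), nll, method = "BFGS", control = list(maxit = 500, reltol = 1e-14))
  expect_equal(fit$loglik, -opt$value, tolerance = 1e-6)
})

test_that("lasso limits recover the unpenalised fit and the null model", {
  set.seed(22)
  n <- 400
  X <- cbind(x1 = rbinom(n, 1, 0.4), x2 = rbinom(n, 1, 0.3), x3 = rnorm(n))
  y <- rbinom(n, 1, plogis(-0.5 + X[, 1]))
  design <- list(response = y, predictors = tibble::as_tibble(X))
  glm_est <- tidy(fit_logistic(design))$estimate
  lasso0 <- tidy(fit_lasso(design, 0))$estimate
  expect_equal(lasso0, glm_est, tolerance = 1e-4)
  heavy <- tidy(fit_lasso(design, 5))
  expect_true(all(heavy$estimate[heavy$term != "(Intercept)"] == 0))
  expect_false(any(heavy$selected[heavy$term != "(Intercept)"]))
})

test_that("mid-path lasso coefficients match a proximal-gradient oracle", {
  set.seed(23)
  n <- 250
  X <- cbind(x1 = rbinom(n, 1, 0.5), x2 = rbinom(n, 1, 0.3), x3 = rnorm(n))
  y <- rbinom(n, 1, plogis(-0.2 + 0.9 * X[, 1] - 0.6 * X[, 3]))
  lam <- 0.02
  fit <- fit_lasso(list(response = y, predictors = tibble::as_tibble(X)), lam,
                   standardize = FALSE)
  oracle <- ista_lasso(X, y, lam)
  expect_equal(tidy(fit)$estimate, unname(oracle), tolerance = 1e-5)
})

test_that("the number of selected predictors shrinks along the penalty path", {
  set.seed(24)
  n <- 300
  X <- matrix(rbinom(n * 8, 1, 0.3), n, 8, dimnames = list(NULL, paste0("x", 1:8)))
  y <- rbinom(n, 1, plogis(-0.4 + X[, 1] - 0.8 * X[, 2] + 0.5 * X[, 3]))
  design <- list(response = y, predictors = tibble::as_tibble(X))
  grid <- exp(seq(log(0.2), log(1e-4), length.out = 10))
  n_sel <- vapply(grid, function(l) {
    sum(tidy(fit_lasso(design, l))$selected, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(rev(n_sel)) <= 0))  # non-increasing in lambda
})

test_that("repeated-CV lambda selection is deterministic and averages the two rules", {
  set.seed(25)
  n <- 240
  X <- cbind(x1 = rbinom(n, 1, 0.4), x2 = rbinom(n, 1, 0.3), x3 = rnorm(n),
             x4 = rbinom(n, 1, 0.2))
  y <- rbinom(n, 1, plogis(-0.3 + 1.2 * X[, 1] - X[, 4]))
  design <- list(response = y, predictors = tibble::as_tibble(X))
  s1 <- select_lambda(design, n_repeats = 4, n_folds = 5, seed = 9)
  s2 <- select_lambda(design, n_repeats = 4, n_folds = 5, seed = 9)
  expect_identical(s1, s2)
  expect_equal(s1$lambda_star,
               (mean(s1$runs$lambda_min) + mean(s1$runs$lambda_1se)) / 2)
  expect_true(all(s1$runs$lambda_1se >= s1$runs$lambda_min))
})

test_that("a strong genetic signal is selected at the chosen penalty", {
  hits <- vapply(1:8, function(s) {
    sim <- simulate_catalogs(sim_config(
      n_drugs = 1000, n_genes = 300, targets_per_drug = c(1, 2),
      frac_no_mendelian = 0.3, frac_no_gwas = 0.5,
      beta_genetic = log(3), confounding = 0, seed = s
    ))
    design <- build_design(sim$drugs, sim$genes, "Nervous")
    lam <- select_lambda(design, n_repeats = 2, n_folds = 5, seed = s)$lambda_star
    sel <- tidy(fit_lasso(design, lam))
    any(sel$selected[sel$term %in% c("mend_match", "gwas_match")])
  }, logical(1))
  expect_gte(mean(hits), 7 / 8)
})
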