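test_that("phenotype eligibility requires two levels with more than four observations", {
  expect_true(phenotype_eligible(rep(c("A", "B"), c(5, 5)))$eligible)
  expect_false(phenotype_eligible(rep(c("A", "B"), c(5, 4)))$eligible)
  expect_false(phenotype_eligible(rep("A", 10))$eligible)
  # missing values are dropped before counting, never forming a level
  expect_true(phenotype_eligible(c(rep(c("A", "B"), c(5, 5)),
                                   NA, ""))$eligible)
  expect_false(phenotype_eligible(c(rep("A", 5), rep("B", 4),
                                    rep(NA, 6)))$eligible)
  # numeric covariates follow the same rule on distinct values
  expect_true(phenotype_eligible(rep(c(0, 1), c(6, 7)))$eligible)
  expect_false(phenotype_eligible(rnorm(20))$eligible)
})

test_that("logistic fit recovers the closed-form log odds ratio on a 2x2 table", {
  # cells (a, b, c, d) = (10, 5, 5, 10): coefficient = ln(ad / bc) = ln 4
  y <- c(rep(1, 10), rep(0, 5), rep(1, 5), rep(0, 10))
  x <- c(rep(1, 15), rep(0, 15))
  fit <- fit_logistic(y, cbind(1, x = x))
  expect_equal(unname(fit$coefficients["x"]), log(4), tolerance = 1e-4)
  expect_true(fit$converged)
  expect_false(fit$separation_flag)
  # closed-form SE for the saturated 2x2 model: sqrt(sum of 1/cells)
  expect_equal(unname(fit$std_errors["x"]),
               sqrt(1 / 10 + 1 / 5 + 1 / 5 + 1 / 10), tolerance = 1e-4)
})

test_that("symmetric data force a zero covariate coefficient", {
  y <- c(1, 0, 1, 0)
  x <- c(1, 1, 0, 0)
  fit <- fit_logistic(y, cbind(1, x = x))
  expect_equal(unname(fit$coefficients["x"]), 0, tolerance = 1e-8)
})

test_that("logistic fit matches a brute-force grid maximum-likelihood search", {
  set.seed(51)
  for (rep in 1:5) {
    n <- 40
    x <- rnorm(n)
    eta <- runif(1, -1, 1) + runif(1, -1.5, 1.5) * x
    y <- as.numeric(runif(n) < plogis(eta))
    if (length(unique(y)) < 2) next
    fit <- fit_logistic(y, cbind(1, x = x))
    grid <- grid_mle_logistic(y, x)
    expect_equal(unname(fit$coefficients), grid, tolerance = 1e-3)
  }
})

test_that("degenerate, collinear and separated inputs are refused or flagged", {
  expect_error(fit_logistic(rep(1, 10), cbind(1, x = rnorm(10))),
               "single-class")
  x <- rnorm(12)
  y <- rep(c(0, 1), 6)
  expect_error(fit_logistic(y, cbind(1, a = x, b = 2 * x)), "collinear")
  # perfect separation: x fully predicts y
  xs <- c(-(5:1), 1:5)
  ys <- c(rep(0, 5), rep(1, 5))
  fit <- fit_logistic(ys, cbind(1, x = xs))
  expect_true(fit$separation_flag)
  expect_error(wald_tests(fit), "separated")
})

test_that("Wald t-tests use the t distribution with n - p degrees of freedom", {
  fit <- structure(list(coefficients = c(a = 2), std_errors = c(a = 1),
                        converged = TRUE, separation_flag = FALSE,
                        n_obs = 12L, df_residual = 10L),
                   class = "logistic_fit")
  w <- wald_tests(fit)
  expect_equal(w$t_stat, 2)
  expect_equal(w$p_value, 2 * pt(2, df = 10, lower.tail = FALSE))
  expect_equal(w$p_value, 0.0734, tolerance = 1e-3)

  fit$coefficients <- c(a = 0)
  expect_equal(wald_tests(fit)$p_value, 1)
  fit$coefficients <- c(a = -2)
  expect_equal(wald_tests(fit)$p_value, w$p_value)  # two-sided symmetry
  fit$std_errors <- c(a = 0)
  expect_error(wald_tests(fit), "zero standard error")
})

test_that("BH correction reproduces the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
  set.seed(52)
  for (rep in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_stepup(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in sorted order
  }
})

test_that("a planted strong effect is the unique discovery in its stratum", {
  sim <- simulate_presence(n_families = 60, n_samples = 100,
                           effect = list(family_index = 3L,
                                         covariate = "group", beta = 3),
                           seed = 53)
  res <- run_association(sim$presence, sim$samples,
                         covariates = c("group", "exposure"))
  hits <- res[res$significant & !is.na(res$q_value), ]
  expect_equal(unique(hits$family_id), sim$effect$family_id)
  expect_equal(unique(hits$covariate), "group")
  row <- hits[hits$term == sim$effect$term, ]
  expect_equal(sign(row$coefficient), sim$effect$sign)
})

test_that("ineligible covariates are skipped wholesale", {
  sim <- simulate_presence(n_families = 10, n_samples = 30, seed = 54)
  sim$samples$rare <- c("Z", rep("W", 29))  # one level with > 4 observations
  res <- run_association(sim$presence, sim$samples, covariates = "rare")
  expect_true(all(res$status == "SKIPPED_INELIGIBLE"))
  expect_equal(nrow(res), 10L)
  expect_true(all(is.na(res$q_value)))
})

test_that("adjustment terms are fit but not reported or pooled", {
  sim <- simulate_presence(n_families = 12, n_samples = 80, seed = 55)
  res <- run_association(sim$presence, sim$samples, covariates = "group",
                         adjustment = "exposure")
  ok <- res[res$status == "OK", ]
  expect_true(all(grepl("^group", ok$term)))
  expect_false(any(ok$term == "exposure"))
})

test_that("global FDR pooling is available as an alternative", {
  sim <- simulate_presence(n_families = 20, n_samples = 60, seed = 56)
  a <- run_association(sim$presence, sim$samples,
                       covariates = c("group", "exposure"))
  b <- run_association(sim$presence, sim$samples,
                       covariates = c("group", "exposure"),
                       fdr_pool = "global")
  ok <- a$status == "OK"
  expect_identical(a$p_value, b$p_value)
  expect_equal(b$q_value[ok], bh_stepup(b$p_value[ok]), tolerance = 1e-12)
})
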