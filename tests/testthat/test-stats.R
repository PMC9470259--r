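test_that("scale_log standardizes the log and rejects invalid input", {
  x <- c(1, exp(1), exp(2))
  z <- scale_log(x)
  expect_equal(z, c(-1, 0, 1), tolerance = 1e-10)
  set.seed(1)
  y <- rpois(500, 20) + 1
  z <- scale_log(y)
  expect_lt(abs(mean(z)), 1e-10)
  expect_lt(abs(sd(z) - 1), 1e-10)
  expect_error(scale_log(c(1, 0, 2)), "positive")
  expect_error(scale_log(rep(4, 10)), "constant")
})

test_that("inverse links reproduce their closed forms", {
  expect_equal(inverse_logit(0), 0.5)
  expect_equal(inverse_log(0), 1)
  expect_equal(round(inverse_logit(-0.56 + 2.21), 2), 0.84)
  expect_equal(round(inverse_log(1.04), 1), 2.8)
  expect_equal(round(inverse_log(2.15), 1), 8.6)
  x <- seq(-5, 5, by = 0.5)
  expect_equal(inverse_logit(x), 1 / (1 + exp(-x)))
})

test_that("intercept-only GLMs recover the closed-form estimates", {
  set.seed(2)
  y <- rbinom(400, 1, 0.3)
  fit <- fit_plasticity_glm(y ~ 1, data.frame(y = y), "binomial")
  expect_equal(unname(coef(fit)), log(mean(y) / (1 - mean(y))),
               tolerance = 1e-8)
  y <- rpois(400, 3.7)
  fit <- fit_plasticity_glm(y ~ 1, data.frame(y = y), "poisson")
  expect_equal(unname(coef(fit)), log(mean(y)), tolerance = 1e-8)
})

test_that("logistic IRLS agrees with a direct Newton optimization", {
  set.seed(3)
  n <- 300
  x <- rnorm(n)
  y <- rbinom(n, 1, 1 / (1 + exp(-(0.4 - 1.1 * x))))
  d <- data.frame(y = y, x = x)
  fit <- fit_plasticity_glm(y ~ x, d, "binomial")
  # independent Newton iteration on the log-likelihood
  X <- cbind(1, x)
  beta <- c(0, 0)
  for (i in 1:50) {
    p <- 1 / (1 + exp(-drop(X %*% beta)))
    W <- p * (1 - p)
    beta <- beta + solve(t(X) %*% (W * X), t(X) %*% (y - p))
  }
  expect_equal(unname(coef(fit)), unname(drop(beta)), tolerance = 1e-6)
})

test_that("logistic simulation recovers the generating coefficients", {
  set.seed(4)
  n <- 20000
  x <- rnorm(n)
  beta <- c(-0.5, 2.0)
  y <- rbinom(n, 1, 1 / (1 + exp(-(beta[1] + beta[2] * x))))
  fit <- fit_plasticity_glm(y ~ x, data.frame(y = y, x = x), "binomial")
  se <- sqrt(diag(vcov(fit)))
  expect_true(all(abs(coef(fit) - beta) < 3 * se))
})

test_that("quasibinomial point estimates equal binomial ones", {
  set.seed(5)
  n <- 500
  x <- rbinom(n, 1, 0.5)
  y <- pmin(1, pmax(0, 0.4 + 0.2 * x + rnorm(n, 0, 0.1)))
  d <- data.frame(y = y, x = x)
  f1 <- suppressWarnings(fit_plasticity_glm(y ~ x, d, "binomial"))
  f2 <- fit_plasticity_glm(y ~ x, d, "quasibinomial")
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)
  # dispersion scales the standard errors
  disp <- summary(f2)$dispersion
  expect_equal(vcov(f2), vcov(f1) * disp, tolerance = 1e-6)
})

test_that("wald_table reports estimates with symmetric 95% intervals", {
  set.seed(6)
  d <- data.frame(y = rbinom(200, 1, 0.4), x = rnorm(200))
  fit <- fit_plasticity_glm(y ~ x, d, "binomial")
  wt <- wald_table(fit)
  expect_equal(wt$term, c("(Intercept)", "x"))
  expect_equal(wt$estimate, unname(coef(fit)))
  se <- sqrt(diag(vcov(fit)))
  expect_equal(wt$ci_high - wt$ci_low, unname(2 * qnorm(0.975) * se))
  expect_true(all(wt$p_value >= 0 & wt$p_value <= 1))
})

test_that("reference quantities reproduce the published back-transformations", {
  q <- reference_quantities()
  printed <- c(
    prob_plastic_genetic_pct = 84, prob_plastic_nongenetic_pct = 36,
    n_phenotypes_genetic = 5.5, n_phenotypes_nongenetic = 2.8,
    prob_viable_plastic_pct = 22, prob_viable_single_pct = 29,
    n_phenotypes_no_cost = 8.6, n_phenotypes_cost = 4.9,
    n_phenotypes_no_cost_1sd = 8.2, n_phenotypes_cost_1sd = 6.5,
    io_nongenetic = 33, io_genetic = 65,
    tlen_plastic_sensitive = 1967, tlen_plastic_robust = 986,
    uncertainty_sensitive = 0.7, uncertainty_robust = 0.9)
  whole <- grepl("pct$|^io|^tlen", names(printed))
  expect_true(all(abs(q[names(printed)][whole] - printed[whole]) <= 0.51))
  expect_true(all(abs(q[names(printed)][!whole] - printed[!whole]) <= 0.055))
})
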