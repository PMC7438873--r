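test_that("the Gelman-Rubin diagnostic matches hand computation", {
  # chains (1,2,3,4) and (2,3,4,5): W = 1.667, B = 2, R-hat = 0.75 + 0.3
  expect_equal(round(gelman_rubin(cbind(1:4, 2:5)), 2), 1.05)
  expect_equal(gelman_rubin(list(c(1, 2, 3, 4), c(2, 3, 4, 5))),
               3 / 4 + (1 / 4) * (2 / (5 / 3)), tolerance = 1e-12)
  # identical constant-free chains: B = 0 leaves only (n-1)/n
  expect_equal(gelman_rubin(cbind(1:4, 1:4)), 0.75 + 0)
  # two identical *constant* chains degenerate to (n-1)/n as well
  expect_equal(gelman_rubin(cbind(rep(2, 4), rep(2, 4))), 0.75)
  # degenerate: constant chains at different values
  expect_warning(out <- gelman_rubin(cbind(rep(1, 4), rep(2, 4))),
                 "Degenerate")
  expect_true(is.nan(out))
  expect_equal(gelman_rubin(cbind(1:4, 2:5), psrf_sqrt = TRUE),
               sqrt(gelman_rubin(cbind(1:4, 2:5))))
  expect_error(gelman_rubin(matrix(1:4, ncol = 1)), "2 chains")
})

test_that("i.i.d. chains give R-hat near 1", {
  withr::local_seed(101)
  for (r in 1:5) {
    chains <- matrix(rnorm(3000), ncol = 3)
    expect_true(dplyr::between(gelman_rubin(chains), 0.9, 1.1))
  }
})

test_that("the per-replication convergence rule is max-based", {
  expect_true(replication_converged(c(1.01, 1.05)))
  expect_false(replication_converged(c(1.01, 1.25)))
  expect_true(replication_converged(1.19))
  expect_false(replication_converged(1.21))
  expect_false(replication_converged(c(1.0, NaN)))
  expect_true(replication_converged(c(1.3, 1.4), threshold = 1.5))
  expect_error(replication_converged(numeric(0)), "non-empty")
})

test_that("bias and MSE match direct arithmetic and their identities", {
  expect_equal(bias(c(0.1, 0.2, 0.3), 0.2), 0)
  expect_equal(mse(c(0.1, 0.2, 0.3), 0.2), 0.00667, tolerance = 1e-3)
  expect_equal(bias(c(1, 2), c(1, 2)), 0)
  expect_equal(mse(c(1, 2), c(1, 2)), 0)
  expect_equal(bias(c(1.5, 2.5), c(1, 2)), 0.5)
  expect_equal(mse(c(1.5, 2.5), c(1, 2)), 0.25)
  expect_error(bias(1:3, 1:2), "length")
  # MSE = bias^2 + population variance of the errors
  withr::local_seed(55)
  for (r in 1:10) {
    est <- rnorm(50)
    tru <- rnorm(50)
    e <- est - tru
    expect_equal(mse(est, tru),
                 bias(est, tru)^2 + mean((e - mean(e))^2),
                 tolerance = 1e-12)
  }
})

test_that("Cohen's kappa matches the hand-computed confusion table", {
  # TP = 40, FN = 10, FP = 5, TN = 45: p_o = 0.85, p_e = 0.5, kappa = 0.70
  truth <- rep(c(1, 1, 0, 0), c(40, 10, 5, 45))
  pred <- rep(c(1, 0, 1, 0), c(40, 10, 5, 45))
  expect_equal(cohens_kappa(truth, pred), 0.70)
  expect_equal(cohens_kappa(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1)
  # single observed level on either side: undefined
  expect_true(is.na(cohens_kappa(c(0, 1, 1, 0), c(0, 0, 0, 0))))
  # invariant under simultaneously swapping the 0/1 labels
  withr::local_seed(77)
  for (r in 1:10) {
    t0 <- rbinom(60, 1, 0.4)
    p0 <- rbinom(60, 1, 0.5)
    expect_equal(cohens_kappa(t0, p0), cohens_kappa(1 - t0, 1 - p0))
  }
})

test_that("classification_report conditions rates on true status", {
  df <- tibble::tibble(
    attribute = "A1", occasion = 1,
    alpha = rep(c(1, 1, 0, 0), c(40, 10, 5, 45)),
    probability = rep(c(0.9, 0.1, 0.8, 0.2), c(40, 10, 5, 45)),
    true_probability = 0.5
  )
  rep1 <- classification_report(df, true_prob = true_probability)
  expect_equal(rep1$rate_true_masters, 0.8)
  expect_equal(rep1$rate_true_nonmasters, 0.9)
  expect_equal(rep1$kappa, 0.70)
  expect_equal(rep1$prob_bias, mean(df$probability) - 0.5)
  # all predicted non-mastery with mixed truth: kappa missing, rates 0 and 1
  df2 <- tibble::tibble(attribute = "A1", occasion = 1,
                        alpha = c(1, 1, 0, 0),
                        probability = c(0.4, 0.3, 0.2, 0.1))
  rep2 <- classification_report(df2)
  expect_true(is.na(rep2$kappa))
  expect_equal(rep2$rate_true_masters, 0)
  expect_equal(rep2$rate_true_nonmasters, 1)
  # perfect agreement
  df3 <- tibble::tibble(attribute = "A1", occasion = 1,
                        alpha = c(1, 0), probability = c(0.9, 0.1))
  rep3 <- classification_report(df3)
  expect_equal(rep3$kappa, 1)
  expect_equal(rep3$rate_true_masters, 1)
  expect_equal(rep3$rate_true_nonmasters, 1)
})

test_that("partial eta-squared matches the hand ANOVA and labels correctly", {
  # groups (1,2,3) vs (3,4,5): SS_between = 6, SS_within = 4
  df <- data.frame(y = c(1, 2, 3, 3, 4, 5),
                   f = rep(c("a", "b"), each = 3))
  out <- anova_partial_eta2(df, "y", "f")
  expect_equal(out$partial_eta2, 0.6)
  expect_equal(as.character(out$effect_size), "large")
  # constant outcome: every eta^2 is zero
  df0 <- data.frame(y = rep(1, 8), f = rep(c("a", "b"), 4),
                    g = rep(c("x", "y"), each = 4))
  out0 <- anova_partial_eta2(df0, "y", c("f", "g"))
  expect_true(all(out0$partial_eta2 == 0))
  # label boundaries: 0.05 is small, 0.14 is large (left-closed bins)
  lab <- function(eta) {
    as.character(cut(eta, c(-Inf, 0.01, 0.06, 0.14, Inf),
                     labels = c("negligible", "small", "medium", "large"),
                     right = FALSE))
  }
  expect_equal(lab(0.05), "small")
  expect_equal(lab(0.14), "large")
  out_lab <- anova_partial_eta2(df, "y", "f")
  expect_identical(levels(out_lab$effect_size),
                   c("negligible", "small", "medium", "large"))
  # two factors with interaction terms present
  withr::local_seed(9)
  df2 <- expand.grid(f = c("a", "b"), g = c("x", "y"), rep = 1:5)
  df2$y <- rnorm(nrow(df2)) + (df2$f == "a") * 2
  out2 <- anova_partial_eta2(df2, "y", c("f", "g"))
  expect_setequal(out2$term, c("f", "g", "f:g"))
  expect_gt(out2$partial_eta2[out2$term == "f"], 0.5)
})

test_that("recovery_summary matches manual bias/MSE on a toy fit", {
  des <- simulation_design(n_persons = 10, n_occasions = 2, seed = 61)
  dat <- simulate_ldcm(des)
  fit <- suppressWarnings(fit_ldcm(dat, chains = 2, iter = 40, burnin = 20,
                                   seed = 62))
  rec <- recovery_summary(fit, dat)
  expect_setequal(rec$parameter_set,
                  c("lambda0", "lambda_main", "lambda_interaction",
                    "gamma00", "gamma10", "g_variance", "g_covariance"))
  expect_equal(rec$n_parameters[rec$parameter_set == "lambda0"], 30)
  expect_equal(rec$n_parameters[rec$parameter_set == "g_variance"], 6)
  # cross-check one set manually
  td <- tidy(fit)
  l0 <- td$estimate[td$block == "lambda0"]
  expect_equal(rec$bias[rec$parameter_set == "lambda0"],
               mean(l0 - (-1.5)))
  expect_equal(rec$mse[rec$parameter_set == "lambda0"],
               mean((l0 - (-1.5))^2))
  expect_true(all(rec$mse >= 0))
})
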