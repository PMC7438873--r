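test_that("classify applies a strict cutpoint", {
  expect_identical(classify(c(0.49, 0.50, 0.51)), c(0L, 0L, 1L))
  expect_identical(classify(0.31, cutpoint = 0.3), 1L)
  expect_error(classify(1.2), "\\[0, 1\\]")
  df <- tibble::tibble(probability = c(0.2, 0.9))
  expect_identical(classify(df)$status, c(0L, 1L))
})

test_that("prior specification is validated and G centering resolved", {
  expect_error(prior_spec(main_sd = 0), "> 0")
  p <- prior_spec(g_center = diag(6) * 0.1, g_df = 10)
  expect_s3_class(p, "ldcm_priors")
  expect_error(
    fit_ldcm(simulate_ldcm(simulation_design(n_persons = 3, n_occasions = 2,
                                             seed = 1)),
             priors = prior_spec(g_df = 2), iter = 2, burnin = 1),
    "exceed"
  )
})

small_fit <- local({
  des <- simulation_design(n_persons = 12, n_occasions = 3, seed = 8)
  dat <- simulate_ldcm(des)
  list(data = dat,
       fit = suppressWarnings(
         fit_ldcm(dat, chains = 2, iter = 60, burnin = 30, seed = 9)
       ))
})

test_that("a degenerate run returns exactly one sample with correct shapes", {
  des <- simulation_design(n_persons = 5, n_occasions = 2, seed = 3)
  dat <- simulate_ldcm(des)
  fit <- suppressWarnings(
    fit_ldcm(dat, chains = 2, iter = 3, burnin = 2, seed = 4, init = "truth")
  )
  expect_equal(dim(fit$draws$lambda0), c(2, 1, 30))
  expect_equal(dim(fit$draws$gamma), c(2, 1, 6))
  expect_equal(dim(fit$draws$g), c(2, 1, 21))
  expect_equal(dim(fit$draws$alpha), c(2, 1, 5 * 2 * 3))
  expect_true(all(fit$draws$alpha %in% 0:1))
  expect_equal(dim(fit$draws$interaction)[3], 15)
})

test_that("posterior mastery probability is the mean of the stored draws", {
  fit <- small_fit$fit
  p <- posterior_mastery_probability(fit)
  expect_true(all(p$probability >= 0 & p$probability <= 1))
  expect_equal(nrow(p), 12 * 3 * 3)
  # brute-force recount from the raw array for a handful of cells
  a <- fit$draws$alpha
  flat <- colMeans(matrix(as.numeric(a), prod(dim(a)[1:2]), dim(a)[3]))
  m <- fit$meta
  for (j in c(1, 17, 50, 100)) {
    k <- ceiling(j / (m$N * m$T))
    rt <- j - (k - 1) * m$N * m$T
    row <- p[p$person == m$persons[m$person[rt]] &
               p$occasion == m$occasions[m$occasion[rt]] &
               p$attribute == m$attrs[k], ]
    expect_equal(row$probability, flat[j])
  }
})

test_that("the mastery full conditional matches the exact hand oracle", {
  # one attribute, two items, growth parameters fixed at truth: the sampled
  # posterior must match the closed-form Bernoulli probability
  q1 <- tibble::tibble(item = 1:2, A1 = 1L)
  ip1 <- item_parameters(q1, intercept = -1.5, main = 1.5)
  fixed <- tibble::tibble(attribute = "A1", gamma00 = 0.4, gamma10 = 0)
  # hand-build a 1-person data set with both items correct at both occasions
  responses <- tidyr::expand_grid(person = 1L, occasion = 1:2,
                                  item = 1:2) |>
    dplyr::mutate(time = (occasion - 1) * 8, response = 1L)
  g0 <- matrix(0, 2, 2, dimnames = rep(list(c("u0_A1", "u1_A1")), 2))
  des <- simulation_design(
    n_persons = 1, n_occasions = 2, qmatrix = q1, item_params = ip1,
    fixed = fixed, g = g0, seed = 1
  )
  dat <- simulate_ldcm(des)
  dat$responses <- responses[names(dat$responses)]
  dat$mastery$alpha <- 1L
  fit <- fit_ldcm(dat, chains = 2, iter = 4000, burnin = 500, seed = 2,
                  init = "truth",
                  update = list(items = FALSE, growth = FALSE, g = FALSE))
  p <- posterior_mastery_probability(fit)
  oracle <- alpha_full_conditional(
    responses = c(1, 1), intercepts = c(-1.5, -1.5), mains = c(1.5, 1.5),
    prior_logit = 0.4
  )
  expect_equal(p$probability[p$occasion == 1], oracle, tolerance = 0.03)
})

test_that("a person acing all attribute items is classified a master", {
  # fixed truth for items and growth; 15 items measure A1, all answered
  # correctly at occasion 1 by person 1
  des <- simulation_design(n_persons = 20, n_occasions = 3, seed = 18)
  dat <- simulate_ldcm(des)
  a1_items <- des$qmatrix$item[des$qmatrix$A1 == 1]
  sel <- dat$responses$person == 1 & dat$responses$occasion == 1 &
    dat$responses$item %in% a1_items
  dat$responses$response[sel] <- 1L
  fit <- fit_ldcm(dat, chains = 2, iter = 400, burnin = 100, seed = 19,
                  init = "truth",
                  update = list(items = FALSE, growth = FALSE, g = FALSE))
  p <- posterior_mastery_probability(fit)
  got <- p$probability[p$person == 1 & p$occasion == 1 & p$attribute == "A1"]
  expect_gt(got, 0.99)
})

test_that("tidy and glance summarize the posterior coherently", {
  fit <- small_fit$fit
  td <- tidy(fit)
  expect_true(all(c("term", "block", "estimate", "std.error", "rhat")
                  %in% names(td)))
  expect_equal(sum(td$block == "lambda0"), 30)
  expect_equal(sum(td$block == "gamma"), 6)
  expect_equal(sum(td$block == "g"), 21)
  expect_true(all(td$conf.low <= td$median & td$median <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$n_persons, 12)
  expect_equal(gl$chains, 2)
  expect_true(is.logical(gl$converged))
  expect_equal(gl$max_rhat, max(rhat_summary(fit)$rhat))
})

test_that("fits are reproducible given a seed and data validation fires", {
  des <- simulation_design(n_persons = 6, n_occasions = 2, seed = 20)
  dat <- simulate_ldcm(des)
  f1 <- suppressWarnings(fit_ldcm(dat, chains = 1, iter = 30, burnin = 10,
                                  seed = 21))
  f2 <- suppressWarnings(fit_ldcm(dat, chains = 1, iter = 30, burnin = 10,
                                  seed = 21))
  expect_identical(f1$draws$gamma, f2$draws$gamma)
  expect_identical(f1$draws$alpha, f2$draws$alpha)
  # incomplete data rejected
  expect_error(fit_ldcm(dat$responses[-1, ], des$qmatrix, iter = 5,
                        burnin = 1), "complete")
  expect_error(fit_ldcm(dat, iter = 5, burnin = 5), "burnin")
})

test_that("time-centering shifts the fitted clock to the medial occasion", {
  des <- simulation_design(n_persons = 10, n_occasions = 3, seed = 71)
  dat <- simulate_ldcm(des)
  f_raw <- suppressWarnings(fit_ldcm(dat, chains = 2, iter = 30, burnin = 15,
                                     seed = 72))
  f_ctr <- suppressWarnings(fit_ldcm(dat, chains = 2, iter = 30, burnin = 15,
                                     seed = 72, center_time = TRUE))
  med_mean <- mean(f_raw$meta$time[f_raw$meta$occasion == 2])
  expect_equal(f_ctr$meta$time, f_raw$meta$time - med_mean)
  # the medial occasion now averages time zero
  expect_equal(mean(f_ctr$meta$time[f_ctr$meta$occasion == 2]), 0)
})
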