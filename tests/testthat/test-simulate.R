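test_that("time scores honour the occasion means and spread", {
  des0 <- simulation_design(n_persons = 5, time_sd = 0, seed = 1)
  ts0 <- draw_time_scores(des0, seed = 1)
  expect_equal(ts0$time, rep(c(0, 8, 16, 24, 32), 5))
  # large-N moments under the unbalanced design
  des <- simulation_design(n_persons = 5000, seed = 1)
  ts <- draw_time_scores(des, seed = 99)
  mom <- ts |>
    dplyr::group_by(occasion) |>
    dplyr::summarise(m = mean(time), s = sd(time))
  expect_true(all(abs(mom$m - c(0, 8, 16, 24, 32)) < 0.05))
  expect_true(all(abs(mom$s - 1) < 0.05))
  # reproducibility contract
  expect_identical(draw_time_scores(des, seed = 5), draw_time_scores(des, seed = 5))
})

test_that("random effects reproduce G and its correlations at large N", {
  g <- g_matrix("equal")
  re0 <- draw_random_effects(matrix(0, 6, 6,
                                    dimnames = dimnames(g)), 10, seed = 1)
  expect_true(all(as.matrix(re0[-1]) == 0))
  re <- draw_random_effects(g, 20000, seed = 7)
  emp <- cov(as.matrix(re[-1]))
  expect_lt(max(abs(emp - g)), 0.01)
  expect_equal(cor(re$u0_A1, re$u0_A2), 0.90, tolerance = 0.025)
  expect_error(draw_random_effects(diag(c(1, -1)), 5), "positive semi-definite")
})

test_that("mastery marginals match the logistic-normal quadrature oracle", {
  des <- simulation_design(n_persons = 20000, growth_pattern = "even",
                           g_condition = "equal", seed = 2)
  dat <- withr::with_seed(11, {
    re <- draw_random_effects(des$g, des$n_persons)
    times <- draw_time_scores(des)
    simulate_mastery(des$fixed, re, times)
  })
  g <- des$g
  for (k in 1:3) {
    for (occ in c(1, 5)) {
      sel <- dat$attribute == paste0("A", k) & dat$occasion == occ
      oracle <- marginal_mastery_oracle(
        des$fixed$gamma00[k], des$fixed$gamma10[k],
        des$time_means[occ], g_block_for(g, k)
      )
      expect_lt(abs(mean(dat$alpha[sel]) - oracle), 0.01)
    }
  }
  # occasion 1, attribute 1: the marginal is ~0.206, not the at-mean 0.20
  sel <- dat$attribute == "A1" & dat$occasion == 1
  expect_lt(abs(mean(dat$alpha[sel]) - 0.206), 0.01)
})

test_that("an uneven design keeps attribute 1's average-person trajectory flat", {
  des <- simulation_design(n_persons = 20000, growth_pattern = "uneven",
                           seed = 3)
  # the conditional-at-mean trajectory is exactly flat (zero fixed slope) ...
  tr <- mean_trajectory(des$fixed, des$time_means)
  expect_equal(tr$probability[tr$attribute == "A1"], rep(plogis(-1.38), 5))
  # ... while the population marginal drifts toward 0.5 with the accumulating
  # slope-variance attenuation, exactly as the quadrature oracle predicts
  dat <- withr::with_seed(13, {
    re <- draw_random_effects(des$g, des$n_persons)
    times <- draw_time_scores(des)
    simulate_mastery(des$fixed, re, times)
  })
  for (occ in c(1, 3, 5)) {
    sel <- dat$attribute == "A1" & dat$occasion == occ
    oracle <- marginal_mastery_oracle(-1.38, 0, des$time_means[occ],
                                      g_block_for(des$g, 1))
    expect_lt(abs(mean(dat$alpha[sel]) - oracle), 0.01)
  }
})

test_that("forced-certain mastery yields all-ones", {
  des <- simulation_design(n_persons = 50, n_occasions = 3, seed = 1)
  fixed_sure <- tibble::tibble(attribute = paste0("A", 1:3),
                               gamma00 = 50, gamma10 = 0)
  dat <- withr::with_seed(1, {
    re <- draw_random_effects(matrix(0, 6, 6, dimnames = dimnames(des$g)), 50)
    times <- draw_time_scores(des)
    simulate_mastery(fixed_sure, re, times)
  })
  expect_true(all(dat$alpha == 1))
})

test_that("response marginals reproduce the three canonical probabilities", {
  q <- qmatrix_design()
  ip <- item_parameters(q)
  n <- 20000
  base <- tibble::tibble(person = seq_len(n), occasion = 1, time = 0)
  make_mastery <- function(alpha) {
    tidyr::expand_grid(base, tibble::tibble(attribute = paste0("A", 1:3))) |>
      dplyr::mutate(probability = alpha, alpha = alpha)
  }
  resp0 <- simulate_responses(make_mastery(0), q, ip, seed = 21)
  props0 <- resp0 |> dplyr::group_by(item) |>
    dplyr::summarise(p = mean(response))
  expect_true(all(abs(props0$p - 0.18) < 0.012))
  resp1 <- simulate_responses(make_mastery(1), q, ip, seed = 22)
  props1 <- resp1 |> dplyr::group_by(item) |>
    dplyr::summarise(p = mean(response))
  single <- q$item[rowSums(as.matrix(q[-1])) == 1]
  expect_true(all(abs(props1$p[props1$item %in% single] - 0.50) < 0.012))
  expect_true(all(abs(props1$p[!props1$item %in% single] - 0.88) < 0.012))
})

test_that("the composed generator is seed-deterministic with correct shapes", {
  des <- simulation_design(n_persons = 100, n_occasions = 5, seed = 31)
  d1 <- simulate_ldcm(des)
  d2 <- simulate_ldcm(des)
  expect_identical(d1$responses, d2$responses)
  expect_identical(d1$mastery, d2$mastery)
  expect_equal(nrow(d1$responses), 100 * 5 * 30)
  expect_equal(nrow(d1$mastery), 100 * 5 * 3)
  expect_true(all(d1$responses$response %in% 0:1))
  d3 <- simulate_ldcm(des, seed = 32)
  expect_false(identical(d1$responses$response, d3$responses$response))
})

test_that("a degenerate design recovers the at-mean trajectory exactly", {
  # sigma_time = 0 and G = 0: the only randomness left is the Bernoulli draw,
  # so empirical mastery proportions converge on mean_trajectory itself
  g0 <- matrix(0, 6, 6, dimnames = dimnames(g_matrix("equal")))
  des <- simulation_design(n_persons = 8000, n_occasions = 5, time_sd = 0,
                           g = g0, seed = 41)
  d <- simulate_ldcm(des)
  emp <- d$mastery |>
    dplyr::group_by(attribute, occasion) |>
    dplyr::summarise(p = mean(alpha), .groups = "drop") |>
    dplyr::arrange(attribute, occasion)
  tr <- mean_trajectory(des$fixed, des$time_means) |>
    dplyr::arrange(attribute, occasion)
  expect_lt(max(abs(emp$p - tr$probability)), 0.02)
  # and the generating probabilities equal the trajectory exactly
  probs <- d$mastery |>
    dplyr::distinct(attribute, occasion, probability) |>
    dplyr::arrange(attribute, occasion)
  expect_equal(probs$probability, tr$probability, tolerance = 1e-12)
})

test_that("data sets round-trip to disk with a manifest", {
  dir <- withr::local_tempdir()
  des <- simulation_design(n_persons = 10, n_occasions = 3, seed = 5)
  d <- simulate_ldcm(des)
  write_ldcm_data(d, dir)
  expect_error(write_ldcm_data(d, dir), "overwrite")
  back <- readr::read_csv(file.path(dir, "responses.csv"),
                          show_col_types = FALSE)
  expect_equal(nrow(back), nrow(d$responses))
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE)
  expect_true("seed" %in% manifest$key)
})
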