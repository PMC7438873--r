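#' Specify a longitudinal simulation design
#'
#' Collects every ingredient of the data-generating process: sample size,
#' growth pattern, random-effect covariance condition, number of occasions,
#' occasion-mean time scores and their person-level spread, the Q-matrix and
#' item parameters, and a seed. Defaults are the packaged study conditions
#' (the `full` study preset): 3 attributes, 30 items, occasion means
#' 0, 8, 16, 24, 32 weeks with SD 1 (unbalanced design), intercept variance
#' 0.15 and slope variance 0.05, item parameters (-1.5, 1.5, 0.5).
#'
#' @param n_persons Sample size (>= 1).
#' @param growth_pattern `"even"` or `"uneven"` (see [growth_fixed_effects()]),
#'   or a custom fixed-effects tibble via `fixed`.
#' @param g_condition `"equal"` or `"unequal"` (see [g_matrix()]), or a custom
#'   covariance matrix via `g`.
#' @param n_occasions Number of measurement occasions (>= 2); occasion means
#'   are truncated to the first `n_occasions` entries of `time_means`.
#' @param time_means Occasion-mean time scores in weeks.
#' @param time_sd Person-level SD of time scores around the occasion mean
#'   (0 gives the balanced design).
#' @param qmatrix Q-matrix tibble.
#' @param item_params Item-parameter tibble.
#' @param fixed Optional custom fixed-effects tibble (overrides
#'   `growth_pattern`).
#' @param g Optional custom G covariance matrix (overrides `g_condition`).
#' @param seed Integer seed; every random draw of [simulate_ldcm()] flows from
#'   it.
#' @return An object of class `ldcm_design`.
#' @export
#' @examples
#' simulation_design(n_persons = 100, seed = 1)
simulation_design <- function(n_persons = 200,
                              growth_pattern = c("even", "uneven"),
                              g_condition = c("equal", "unequal"),
                              n_occasions = 5,
                              time_means = c(0, 8, 16, 24, 32),
                              time_sd = 1,
                              qmatrix = qmatrix_design(),
                              item_params = NULL,
                              fixed = NULL,
                              g = NULL,
                              seed = 1L) {
  growth_pattern <- match.arg(growth_pattern)
  g_condition <- match.arg(g_condition)
  if (n_persons < 1) abort("`n_persons` must be >= 1.")
  if (n_occasions < 2) abort("`n_occasions` must be >= 2.")
  if (time_sd < 0) abort("`time_sd` must be >= 0.")
  if (length(time_means) < n_occasions) {
    abort("`time_means` must supply at least `n_occasions` occasion means.")
  }
  validate_qmatrix(qmatrix)
  if (is.null(item_params)) item_params <- item_parameters(qmatrix)
  validate_item_parameters(item_params, qmatrix)
  if (is.null(fixed)) fixed <- growth_fixed_effects(growth_pattern)
  if (!setequal(fixed$attribute, q_attr_names(qmatrix))) {
    abort("Fixed-effects attributes must match the Q-matrix attribute columns.")
  }
  if (is.null(g)) g <- g_matrix(g_condition)
  if (nrow(g) != 2 * nrow(fixed)) {
    abort("`g` must be a 2K x 2K covariance matrix (intercept and slope per attribute).")
  }
  ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) abort("`g` must be positive semi-definite.")
  structure(
    list(
      n_persons = as.integer(n_persons),
      growth_pattern = growth_pattern,
      g_condition = g_condition,
      n_occasions = as.integer(n_occasions),
      time_means = time_means[seq_len(n_occasions)],
      time_sd = time_sd,
      qmatrix = qmatrix,
      item_params = item_params,
      fixed = fixed,
      g = g,
      seed = as.integer(seed)
    ),
    class = "ldcm_design"
  )
}

#' @export
print.ldcm_design <- function(x, ...) {
  cat("<ldcm_design>\n")
  cat(sprintf("  persons: %d, occasions: %d, items: %d, attributes: %d\n",
              x$n_persons, x$n_occasions, nrow(x$qmatrix), nrow(x$fixed)))
  cat(sprintf("  growth pattern: %s, G condition: %s, time SD: %g, seed: %d\n",
              x$growth_pattern, x$g_condition, x$time_sd, x$seed))
  invisible(x)
}

with_optional_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Draw person-specific time scores
#'
#' Each person's time score at occasion `t` is drawn independently from
#' `Normal(mu_t, sd^2)` around the occasion mean, emulating interim
#' assessments taken at slightly different weeks; `time_sd = 0` returns the
#' balanced design exactly. Occasions are far enough apart (8 weeks vs SD 1)
#' that non-monotone person timelines are vanishingly rare; a warning fires if
#' one occurs.
#'
#' @param design An `ldcm_design`.
#' @param seed Optional seed (`NULL` uses the current RNG state).
#' @return A tibble with columns `person`, `occasion`, `time`, ordered by
#'   person then occasion.
#' @export
draw_time_scores <- function(design, seed = NULL) {
  with_optional_seed(seed, {
    N <- design$n_persons
    T_ <- design$n_occasions
    mu <- design$time_means
    times <- rep(mu, times = N) + rnorm(N * T_, 0, design$time_sd)
    out <- tibble::tibble(
      person = rep(seq_len(N), each = T_),
      occasion = rep(seq_len(T_), times = N),
      time = times
    )
    mono <- tapply(out$time, out$person, function(x) all(diff(x) > 0))
    if (!all(mono)) {
      warn("Some persons have non-monotone time scores across occasions.")
    }
    out
  })
}

#' Draw person random effects from G
#'
#' i.i.d. multivariate-normal draws `MVN(0, G)` of the `2K` random intercepts
#' and slopes per person.
#'
#' @param g Positive semi-definite covariance matrix with effect labels.
#' @param n_persons Number of persons.
#' @param seed Optional seed.
#' @return A tibble with columns `person`, one column per effect label.
#' @export
draw_random_effects <- function(g, n_persons, seed = NULL) {
  ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) abort("`g` must be positive semi-definite.")
  with_optional_seed(seed, {
    u <- MASS::mvrnorm(n_persons, mu = rep(0, nrow(g)), Sigma = g)
    u <- matrix(u, nrow = n_persons)
    colnames(u) <- rownames(g) %||% paste0("re", seq_len(ncol(u)))
    dplyr::bind_cols(tibble::tibble(person = seq_len(n_persons)),
                     tibble::as_tibble(u))
  })
}

# wide random-effects tibble -> list of N x K matrices u0, u1
split_random_effects <- function(re, attrs) {
  u0 <- as.matrix(re[paste0("u0_", attrs)])
  u1 <- as.matrix(re[paste0("u1_", attrs)])
  list(u0 = u0, u1 = u1)
}

#' Simulate true mastery statuses
#'
#' For each person, occasion and attribute, computes the growth-model logit
#' `(gamma00k + u0rk) + (gamma10k + u1rk) * time_rt` and draws the mastery
#' indicator from `Bernoulli(logistic(logit))`. The Bernoulli-with-logit draw
#' *is* the latent-logistic residual of the model; no explicit residual is
#' added (adding one would double-count the level-2 variance).
#'
#' @param fixed Fixed-effects tibble.
#' @param random_effects Wide random-effects tibble from
#'   [draw_random_effects()].
#' @param times Time-score tibble from [draw_time_scores()].
#' @param seed Optional seed.
#' @param explicit_residual Experimental: add an explicit `Normal(0, pi^2/3)`
#'   residual to the logit before the Bernoulli draw (sensitivity analysis
#'   only; doubles the implied residual variance).
#' @return A tibble with columns `person`, `occasion`, `time`, `attribute`,
#'   `probability` (the true generating probability) and `alpha` (0/1).
#' @export
simulate_mastery <- function(fixed, random_effects, times, seed = NULL,
                             explicit_residual = FALSE) {
  attrs <- fixed$attribute
  u <- split_random_effects(random_effects, attrs)
  with_optional_seed(seed, {
    out <- tidyr::expand_grid(times, tibble::tibble(attribute = attrs)) |>
      dplyr::mutate(k = match(.data$attribute, attrs))
    idx <- cbind(out$person, out$k)
    eta <- (fixed$gamma00[out$k] + u$u0[idx]) +
      (fixed$gamma10[out$k] + u$u1[idx]) * out$time
    if (explicit_residual) {
      eta <- eta + rnorm(length(eta), 0, pi / sqrt(3))
    }
    out |>
      dplyr::mutate(
        probability = plogis(eta),
        alpha = rbinom(dplyr::n(), 1, .data$probability)
      ) |>
      dplyr::select("person", "occasion", "time", "attribute",
                    "probability", "alpha")
  })
}

#' Simulate item responses given true mastery
#'
#' For each person-occasion, evaluates the LCDM response probability of every
#' item under the true attribute profile and draws the binary response from
#' `Bernoulli(probability)`.
#'
#' @param mastery Mastery tibble from [simulate_mastery()].
#' @param qmatrix Q-matrix tibble.
#' @param item_params Item-parameter tibble.
#' @param seed Optional seed.
#' @return A tibble with columns `person`, `occasion`, `time`, `item`,
#'   `response`.
#' @export
simulate_responses <- function(mastery, qmatrix, item_params, seed = NULL) {
  ipm <- ip_compile(item_params, qmatrix)
  wide <- mastery |>
    dplyr::select("person", "occasion", "time", "attribute", "alpha") |>
    tidyr::pivot_wider(names_from = "attribute", values_from = "alpha")
  alpha <- as.matrix(wide[ipm$attrs])
  with_optional_seed(seed, {
    p <- plogis(lcdm_eta(alpha, ipm))  # (person-occasion) x I
    x <- matrix(rbinom(length(p), 1, p), nrow = nrow(p))
    tidyr::expand_grid(
      wide[c("person", "occasion", "time")],
      tibble::tibble(item = ipm$items)
    ) |>
      dplyr::mutate(response = as.integer(t(x)[seq_len(length(x))]))
  })
}

#' Generate a longitudinal response set
#'
#' Composes the full five-step generating recipe under a single seed: (1) draw
#' person random effects from G; (2) draw person-specific time scores; (3)
#' compute mastery probabilities from the growth model and draw true mastery
#' statuses; (4) compute LCDM response probabilities from the Q-matrix, item
#' parameters and true profiles; (5) draw binary responses. The truth block
#' (true mastery, generating probabilities, random effects) is kept alongside
#' the responses so evaluation never re-derives it.
#'
#' @param design An `ldcm_design`.
#' @param seed Seed override (defaults to `design$seed`).
#' @return An object of class `ldcm_data`: a list with tibbles `responses`
#'   (`person`, `occasion`, `time`, `item`, `response`), `mastery` (truth),
#'   `random_effects` (truth), and the `design`.
#' @export
#' @examples
#' d <- simulate_ldcm(simulation_design(n_persons = 20, seed = 7))
#' d
simulate_ldcm <- function(design, seed = design$seed) {
  withr::with_seed(seed, {
    re <- draw_random_effects(design$g, design$n_persons)
    times <- draw_time_scores(design)
    mastery <- simulate_mastery(design$fixed, re, times)
    responses <- simulate_responses(mastery, design$qmatrix, design$item_params)
    structure(
      list(responses = responses, mastery = mastery, random_effects = re,
           design = design, seed = as.integer(seed)),
      class = "ldcm_data"
    )
  })
}

#' @export
print.ldcm_data <- function(x, ...) {
  cat("<ldcm_data>\n")
  cat(sprintf("  %d persons x %d occasions x %d items (%d responses)\n",
              x$design$n_persons, x$design$n_occasions,
              nrow(x$design$qmatrix), nrow(x$responses)))
  cat(sprintf("  growth: %s, G: %s, seed: %d\n",
              x$design$growth_pattern, x$design$g_condition, x$seed))
  cat("  truth block: $mastery, $random_effects\n")
  invisible(x)
}

#' Write a simulated data set to CSV files
#'
#' Writes `responses.csv` (long format), `mastery.csv` and
#' `random_effects.csv` (truth sidecars) and a `manifest.csv` recording the
#' design factors and seed into `dir`.
#'
#' @param data An `ldcm_data`.
#' @param dir Output directory (created if needed).
#' @param overwrite Refuse to overwrite an existing manifest unless `TRUE`.
#' @return `dir`, invisibly.
#' @export
write_ldcm_data <- function(data, dir, overwrite = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest_path <- file.path(dir, "manifest.csv")
  if (file.exists(manifest_path) && !overwrite) {
    abort("Output directory already holds a data set; use `overwrite = TRUE`.")
  }
  d <- data$design
  manifest <- tibble::tibble(
    key = c("n_persons", "growth_pattern", "g_condition", "n_occasions",
            "time_sd", "seed"),
    value = as.character(c(d$n_persons, d$growth_pattern, d$g_condition,
                           d$n_occasions, d$time_sd, data$seed))
  )
  readr::write_csv(data$responses, file.path(dir, "responses.csv"))
  effects_long <- data$random_effects |>
    tidyr::pivot_longer(-"person", names_to = "effect", values_to = "value")
  readr::write_csv(data$mastery, file.path(dir, "mastery.csv"))
  readr::write_csv(effects_long, file.path(dir, "random_effects.csv"))
  readr::write_csv(manifest, manifest_path)
  invisible(dir)
}
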