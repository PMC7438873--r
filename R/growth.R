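#' Fixed effects of the packaged growth conditions
#'
#' Average initial levels (`gamma00`, log-odds of mastery at time 0) and
#' average weekly growth rates (`gamma10`, log-odds per week) for the three
#' attributes, under two growth patterns: `"even"` (all attributes improve at
#' similar rates) and `"uneven"` (attribute 1 stays flat while attributes 2 and
#' 3 improve). Initial levels correspond to base-rates of roughly 0.20, 0.25
#' and 0.30.
#'
#' @param pattern `"even"` or `"uneven"`.
#' @return A tibble with columns `attribute`, `gamma00`, `gamma10`.
#' @export
#' @examples
#' growth_fixed_effects("even")
growth_fixed_effects <- function(pattern = c("even", "uneven")) {
  pattern <- match.arg(pattern)
  tibble::tibble(
    attribute = paste0("A", 1:3),
    gamma00 = c(-1.38, -1.10, -0.85),
    gamma10 = if (pattern == "even") c(0.05, 0.04, 0.05) else c(0, 0.04, 0.05)
  )
}

#' Read or write fixed effects as CSV
#'
#' CSV keyed by attribute with columns `attribute`, `gamma00`, `gamma10`.
#'
#' @param path File path.
#' @param fixed A fixed-effects tibble.
#' @export
read_fixed_effects <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname read_fixed_effects
#' @export
write_fixed_effects <- function(fixed, path) {
  readr::write_csv(fixed, path)
  invisible(fixed)
}

# canonical random-effect labels: (intercept, slope) nested within attribute
re_labels <- function(attrs) {
  as.vector(rbind(paste0("u0_", attrs), paste0("u1_", attrs)))
}

#' Random-effect correlation structure of the packaged conditions
#'
#' The correlation matrix of the `2K` person-level random effects (intercept
#' `u0` and slope `u1` nested within attribute, attributes `A1`-`A3`), under
#' two conditions: `"equal"`, where all attributes are equally correlated
#' (intercept-intercept 0.90, slope-slope 0.25, within-attribute
#' intercept-slope 0.20, cross intercept-slope 0.10), and `"unequal"`, where
#' attribute 1 is only weakly related to attributes 2 and 3.
#'
#' @param condition `"equal"` or `"unequal"`.
#' @return A symmetric correlation matrix with effect labels
#'   (`u0_A1`, `u1_A1`, ...).
#' @export
g_correlation <- function(condition = c("equal", "unequal")) {
  condition <- match.arg(condition)
  labels <- re_labels(paste0("A", 1:3))
  r <- if (condition == "equal") {
    c(1,    0.20, 0.90, 0.10, 0.90, 0.10,
      0.20, 1,    0.10, 0.25, 0.10, 0.25,
      0.90, 0.10, 1,    0.20, 0.90, 0.10,
      0.10, 0.25, 0.20, 1,    0.10, 0.25,
      0.90, 0.10, 0.90, 0.10, 1,    0.20,
      0.10, 0.25, 0.10, 0.25, 0.20, 1)
  } else {
    c(1,    0.10, 0.90, 0.01, 0.10, 0.01,
      0.10, 1,    0.01, 0.01, 0.01, 0.01,
      0.90, 0.01, 1,    0.20, 0.90, 0.10,
      0.01, 0.01, 0.20, 1,    0.10, 0.25,
      0.10, 0.01, 0.90, 0.10, 1,    0.20,
      0.01, 0.01, 0.10, 0.25, 0.20, 1)
  }
  matrix(r, 6, 6, dimnames = list(labels, labels))
}

#' Random-effect covariance matrix (G) of the packaged conditions
#'
#' The `KP x KP` covariance matrix of the person-level random intercepts and
#' slopes, built from [g_correlation()] with intercept variance 0.15 and slope
#' variance 0.05 for every attribute.
#'
#' @inheritParams g_correlation
#' @return A symmetric positive semi-definite covariance matrix with effect
#'   labels.
#' @export
#' @examples
#' round(g_matrix("equal"), 4)
g_matrix <- function(condition = c("equal", "unequal")) {
  corr <- g_correlation(condition)
  variances <- rep(c(0.15, 0.05), 3)
  corr_to_cov(corr, variances)
}

#' Convert between correlation and covariance parameterizations of G
#'
#' `corr_to_cov()` scales a correlation matrix by standard deviations
#' (`cov_ij = r_ij * sqrt(var_i * var_j)`); `cov_to_corr()` inverts it. The two
#' round-trip to machine precision.
#'
#' @param corr Symmetric correlation matrix with unit diagonal, entries in
#'   \[-1, 1\].
#' @param variances Nonnegative variances, one per row of `corr`.
#' @param g Covariance matrix with strictly positive diagonal.
#' @return A covariance (resp. correlation) matrix, labels preserved.
#' @export
#' @examples
#' corr_to_cov(matrix(c(1, 0.2, 0.2, 1), 2), c(0.15, 0.05))
corr_to_cov <- function(corr, variances) {
  if (!isSymmetric(unname(corr), tol = 1e-8)) abort("`corr` must be symmetric.")
  if (any(abs(diag(corr) - 1) > 1e-8)) abort("`corr` must have unit diagonal.")
  if (any(abs(corr) > 1 + 1e-8)) abort("Correlations must lie in [-1, 1].")
  if (length(variances) != nrow(corr)) {
    abort("`variances` must have one entry per row of `corr`.")
  }
  if (any(variances < 0)) abort("Variances must be >= 0.")
  s <- sqrt(variances)
  out <- corr * tcrossprod(s)
  dimnames(out) <- dimnames(corr)
  out
}

#' @rdname corr_to_cov
#' @export
cov_to_corr <- function(g) {
  if (!isSymmetric(unname(g), tol = 1e-8)) abort("`g` must be symmetric.")
  if (any(diag(g) <= 0)) {
    abort("`g` must have strictly positive diagonal variances.")
  }
  s <- sqrt(diag(g))
  out <- g / tcrossprod(s)
  dimnames(out) <- dimnames(g)
  out
}

#' Read or write a G (or correlation) matrix as CSV
#'
#' Square CSV with a header row and leading `effect` column of random-effect
#' labels (`u0_A1`, `u1_A1`, ...).
#'
#' @param path File path.
#' @param g A labelled square matrix.
#' @export
read_g_matrix <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_g_matrix
#' @export
write_g_matrix <- function(g, path) {
  df <- dplyr::bind_cols(tibble::tibble(effect = rownames(g)),
                         tibble::as_tibble(g))
  readr::write_csv(df, path)
  invisible(g)
}

#' Person-specific mastery logit
#'
#' The linear predictor of the growth model for one attribute:
#' `(gamma00 + u0) + (gamma10 + u1) * time`, i.e. the person-specific intercept
#' plus the person-specific slope times the time score (in weeks).
#'
#' @param fixed Fixed-effects tibble (columns `attribute`, `gamma00`,
#'   `gamma10`).
#' @param u0,u1 Person deviations from the average initial level and slope for
#'   the chosen attribute (vectors recycle against `time`).
#' @param attribute Attribute identifier (name in `fixed$attribute`) or index.
#' @param time Time score(s), in weeks.
#' @return Numeric logit(s) of the mastery probability.
#' @export
#' @examples
#' fe <- growth_fixed_effects("even")
#' mastery_logit(fe, attribute = "A1", time = 0)  # -1.38
mastery_logit <- function(fixed, attribute, time, u0 = 0, u1 = 0) {
  k <- if (is.numeric(attribute)) attribute else match(attribute, fixed$attribute)
  if (is.na(k) || k < 1 || k > nrow(fixed)) {
    abort("Unknown attribute.")
  }
  (fixed$gamma00[k] + u0) + (fixed$gamma10[k] + u1) * time
}

#' Mastery probability from a logit
#'
#' The logistic transform `1 / (1 + exp(-logit))`; strictly increasing.
#'
#' @param logit Numeric logit(s).
#' @return Probabilities in (0, 1).
#' @export
#' @examples
#' mastery_probability(-1.38)  # ~0.20
mastery_probability <- function(logit) plogis(logit)

#' Conditional-at-mean mastery trajectory
#'
#' The mastery probability at the occasion-mean time scores with random effects
#' set to zero: `logistic(gamma00 + gamma10 * mu_t)` per attribute and
#' occasion. This is the trajectory of the *average person*, not the
#' population-marginal mastery proportion; integrating the logistic over the
#' random effects shrinks probabilities toward 0.5 (logistic-normal
#' attenuation), so simulated marginal proportions sit slightly closer to 0.5
#' than these values.
#'
#' @param fixed Fixed-effects tibble.
#' @param times Occasion-mean time scores (default `c(0, 8, 16, 24, 32)`).
#' @return A tibble with columns `attribute`, `occasion`, `time`, `logit`,
#'   `probability`.
#' @export
#' @examples
#' mean_trajectory(growth_fixed_effects("even"))
mean_trajectory <- function(fixed, times = c(0, 8, 16, 24, 32)) {
  tidyr::expand_grid(
    fixed,
    tibble::tibble(occasion = seq_along(times), time = times)
  ) |>
    dplyr::mutate(
      logit = .data$gamma00 + .data$gamma10 * .data$time,
      probability = plogis(.data$logit)
    ) |>
    dplyr::select("attribute", "occasion", "time", "logit", "probability")
}

#' Stacked dummy-variable form of the growth predictor
#'
#' Evaluates the single-equation formulation in which the mastery indicators of
#' all attributes are stacked into one synthesized outcome and attribute
#' dummies select which intercept/slope pair applies:
#' `sum_j A_j * [(gamma00j + u0j) + (gamma10j + u1j) * time]` with
#' `A_j = 1` iff `j` is the requested attribute. Algebraically identical to
#' [mastery_logit()]; provided because the stacked form is how the model is fit
#' as a single regression.
#'
#' @param fixed Fixed-effects tibble.
#' @param attribute Attribute identifier or index.
#' @param time Time score(s) in weeks.
#' @param u0,u1 Length-K vectors of person deviations (one per attribute);
#'   scalars recycle.
#' @return Numeric logit(s).
#' @export
stacked_dummy_predictor <- function(fixed, attribute, time, u0 = 0, u1 = 0) {
  K <- nrow(fixed)
  k <- if (is.numeric(attribute)) attribute else match(attribute, fixed$attribute)
  if (is.na(k) || k < 1 || k > K) abort("Unknown attribute.")
  u0 <- rep_len(u0, K)
  u1 <- rep_len(u1, K)
  dummies <- as.numeric(seq_len(K) == k)
  out <- 0
  for (j in seq_len(K)) {
    out <- out + dummies[j] *
      ((fixed$gamma00[j] + u0[j]) + (fixed$gamma10[j] + u1[j]) * time)
  }
  out
}
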