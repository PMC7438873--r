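#' Gelman-Rubin convergence diagnostic
#'
#' For `m >= 2` chains of length `n`, computes `W`, the mean of the
#' within-chain sample variances, and `B = n * var(chain means)`, the
#' between-chain variance, and returns
#' `R-hat = (n - 1) / n + (1 / n) * (B / W)`. This is the variance-ratio form
#' of the potential scale reduction factor; `psrf_sqrt = TRUE` returns its
#' square root instead. Values near 1 indicate that the chains have mixed;
#' the conventional cutoff used throughout this package is 1.2.
#'
#' @param chains A numeric matrix with one column per chain (iterations in
#'   rows), or a list of equal-length numeric vectors.
#' @param psrf_sqrt Return the square-root convention.
#' @return A single numeric value; `NaN` (with a warning) when the chains are
#'   degenerate (`W = 0` with `B > 0`).
#' @export
#' @examples
#' gelman_rubin(cbind(c(1, 2, 3, 4), c(2, 3, 4, 5)))  # 1.05
gelman_rubin <- function(chains, psrf_sqrt = FALSE) {
  if (is.list(chains)) {
    if (length(unique(lengths(chains))) != 1) {
      abort("All chains must have the same length.")
    }
    chains <- do.call(cbind, chains)
  }
  chains <- as.matrix(chains)
  m <- ncol(chains)
  n <- nrow(chains)
  if (m < 2) abort("At least 2 chains are required.")
  if (n < 2) abort("At least 2 iterations per chain are required.")
  W <- mean(apply(chains, 2, var))
  B <- n * var(colMeans(chains))
  if (W == 0) {
    if (B > 0) {
      warn("Degenerate chains: zero within-chain variance with between-chain spread.")
      return(NaN)
    }
    # all chains constant and identical: only the (n-1)/n term remains
    rhat <- (n - 1) / n
  } else {
    rhat <- (n - 1) / n + B / (n * W)
  }
  if (psrf_sqrt) sqrt(rhat) else rhat
}

#' Convergence verdict for a replication
#'
#' A replication counts as converged only if *every* monitored parameter has
#' an R-hat below the threshold.
#'
#' @param rhats Non-empty numeric vector of R-hat values.
#' @param threshold Convergence cutoff (default 1.2).
#' @return `TRUE` iff `max(rhats) < threshold` (non-finite values fail).
#' @export
#' @examples
#' replication_converged(c(1.01, 1.05))  # TRUE
#' replication_converged(c(1.01, 1.25))  # FALSE
replication_converged <- function(rhats, threshold = 1.2) {
  if (length(rhats) == 0) abort("`rhats` must be non-empty.")
  all(is.finite(rhats)) && max(rhats) < threshold
}

#' Bias and mean squared error of estimates
#'
#' `bias()` is the mean of `estimate - truth`, `mse()` the mean of
#' `(estimate - truth)^2`, pooling over replications and over the elements of
#' a parameter set; `truth` recycles against `estimates`.
#'
#' @param estimates Numeric vector of estimates.
#' @param truths Numeric vector of true values (length 1 or
#'   `length(estimates)`).
#' @return A single numeric value.
#' @export
#' @examples
#' bias(c(0.1, 0.2, 0.3), 0.2)  # 0
#' mse(c(0.1, 0.2, 0.3), 0.2)   # 0.00667
bias <- function(estimates, truths) {
  if (!length(truths) %in% c(1L, length(estimates))) {
    abort("`truths` must have length 1 or length(estimates).")
  }
  mean(estimates - truths)
}

#' @rdname bias
#' @export
mse <- function(estimates, truths) {
  if (!length(truths) %in% c(1L, length(estimates))) {
    abort("`truths` must have length 1 or length(estimates).")
  }
  mean((estimates - truths)^2)
}

#' Cohen's kappa for binary agreement
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with expected
#' agreement computed from the marginals. Returns `NA` when either the truth
#' or the prediction has a single observed level (kappa is then undefined).
#'
#' @param truth,prediction 0/1 vectors of equal length.
#' @return Kappa in \[-1, 1\], or `NA_real_` when undefined.
#' @export
#' @examples
#' cohens_kappa(rep(c(1, 0), c(50, 50)), rep(c(1, 0, 1, 0), c(40, 10, 5, 45)))
cohens_kappa <- function(truth, prediction) {
  if (length(truth) != length(prediction)) {
    abort("`truth` and `prediction` must have equal length.")
  }
  if (length(unique(truth)) < 2 || length(unique(prediction)) < 2) {
    return(NA_real_)
  }
  po <- mean(truth == prediction)
  pe <- mean(truth == 1) * mean(prediction == 1) +
    mean(truth == 0) * mean(prediction == 0)
  if (pe == 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Classification-accuracy report
#'
#' Summarizes the accuracy of estimated mastery per attribute and occasion:
#' the bias of the estimated mastery probability against the true *generating*
#' probability (when available), the correct classification rates conditional
#' on true status (among true masters and among true non-masters), and Cohen's
#' kappa between true and estimated status at the given cutpoint. Kappa is
#' reported as `NA` where either status has a single level.
#'
#' @param data A data frame holding, per person/occasion/attribute, the true
#'   status, the estimated probability, and optionally the true generating
#'   probability.
#' @param truth,prob,true_prob Columns of `data` (unquoted) giving the true
#'   0/1 status, the estimated mastery probability, and (optionally) the true
#'   generating probability.
#' @param by Character vector of grouping columns (default
#'   `c("attribute", "occasion")`, intersected with what is present).
#' @param cutpoint Classification cutpoint (strict `>`).
#' @return A tibble with one row per group: `n`, `prob_bias`,
#'   `rate_true_masters`, `rate_true_nonmasters`, `kappa`.
#' @export
classification_report <- function(data, truth = alpha, prob = probability,
                                  true_prob = NULL,
                                  by = c("attribute", "occasion"),
                                  cutpoint = 0.5) {
  truth_q <- rlang::enquo(truth)
  prob_q <- rlang::enquo(prob)
  tp_q <- rlang::enquo(true_prob)
  by <- intersect(by, names(data))
  has_tp <- !rlang::quo_is_null(tp_q)
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      prob_bias = if (has_tp) mean(!!prob_q - !!tp_q) else NA_real_,
      rate_true_masters = {
        sel <- !!truth_q == 1
        if (any(sel)) mean(classify(!!prob_q, cutpoint)[sel] == 1) else NA_real_
      },
      rate_true_nonmasters = {
        sel <- !!truth_q == 0
        if (any(sel)) mean(classify(!!prob_q, cutpoint)[sel] == 0) else NA_real_
      },
      kappa = cohens_kappa(!!truth_q, classify(!!prob_q, cutpoint)),
      .groups = "drop"
    )
}

#' Partial eta-squared from a factorial ANOVA
#'
#' Fits a factorial ANOVA of `outcome` on the supplied design factors (main
#' effects and, optionally, all two-way interactions) and reports
#' `partial eta^2 = SS_effect / (SS_effect + SS_residual)` per term, labelled
#' small / medium / large at the conventional 0.01 / 0.06 / 0.14 cutoffs.
#'
#' @param data A data frame of simulation outcomes.
#' @param outcome Name of the numeric outcome column.
#' @param factors Character vector of factor columns (>= 2 observed levels
#'   each unless the term drops out).
#' @param interactions Include all two-way interactions (default `TRUE`;
#'   automatically dropped for a single factor).
#' @return A tibble with columns `term`, `df`, `sum_sq`, `partial_eta2`,
#'   `effect_size` (`"negligible"` below 0.01).
#' @export
#' @examples
#' df <- data.frame(y = c(1, 2, 3, 3, 4, 5), f = rep(c("a", "b"), each = 3))
#' anova_partial_eta2(df, "y", "f")  # partial eta^2 = 0.60
anova_partial_eta2 <- function(data, outcome, factors, interactions = TRUE) {
  stopifnot(outcome %in% names(data), all(factors %in% names(data)))
  data <- dplyr::mutate(data,
                        dplyr::across(dplyr::all_of(factors), as.factor))
  factors <- factors[vapply(data[factors], function(f) nlevels(f) >= 2, TRUE)]
  if (length(factors) == 0) abort("No factor has >= 2 observed levels.")
  rhs <- if (interactions && length(factors) >= 2) {
    paste0("(", paste(factors, collapse = " + "), ")^2")
  } else {
    paste(factors, collapse = " + ")
  }
  fml <- stats::as.formula(paste(outcome, "~", rhs))
  # only sums of squares are consumed; suppress the F-test reliability
  # warning a perfectly fitting (e.g. constant-outcome) model triggers
  tab <- suppressWarnings(stats::anova(aov(fml, data = data)))
  terms <- rownames(tab)
  resid_ss <- tab["Residuals", "Sum Sq"]
  keep <- terms != "Residuals"
  ss <- tab[keep, "Sum Sq"]
  eta <- if (var(data[[outcome]]) == 0) {
    # constant outcome: every effect explains nothing (guard against the
    # 0/0 floating fuzz aov leaves behind)
    rep(0, sum(keep))
  } else {
    ifelse(ss + resid_ss == 0, 0, ss / (ss + resid_ss))
  }
  tibble::tibble(
    term = trimws(terms[keep]),
    df = tab[keep, "Df"],
    sum_sq = ss,
    partial_eta2 = eta,
    effect_size = cut(eta, c(-Inf, 0.01, 0.06, 0.14, Inf),
                      labels = c("negligible", "small", "medium", "large"),
                      right = FALSE)
  )
}

#' Recovery summary against the generating truth
#'
#' Bias and MSE of posterior means per parameter set, matched to the
#' generating values of a simulated data set: LCDM intercepts, main effects
#' and interactions; growth intercepts (`gamma00`) and slopes (`gamma10`); and
#' the variances/covariances of G (split into variance and covariance sets).
#'
#' @param fit An `ldcm_fit`.
#' @param data The `ldcm_data` the fit was run on (supplies the truth).
#' @return A tibble with columns `parameter_set`, `n_parameters`, `bias`,
#'   `mse`.
#' @export
recovery_summary <- function(fit, data) {
  if (!inherits(data, "ldcm_data")) abort("`data` must be an `ldcm_data`.")
  est <- tidy(fit)
  truth <- truth_values(data, fit)
  joined <- dplyr::inner_join(est, truth, by = "term")
  joined |>
    dplyr::group_by(.data$parameter_set) |>
    dplyr::summarise(
      n_parameters = dplyr::n(),
      bias = bias(.data$estimate, .data$truth),
      mse = mse(.data$estimate, .data$truth),
      .groups = "drop"
    )
}

# generating values labelled like the sampler output
truth_values <- function(data, fit) {
  qs <- q_structure(data$design$qmatrix)
  ipm <- ip_compile(data$design$item_params, data$design$qmatrix)
  lab <- fit$labels
  g <- data$design$g
  gl <- lab$g
  tibble::tibble(
    term = c(lab$lambda0, lab$main, lab$interaction, lab$gamma, gl$labels),
    truth = c(
      ipm$lambda0,
      ipm$Lmain[cbind(lab$main_items, lab$main_attrs)],
      ipm$int_val[qs$two],
      data$design$fixed$gamma00, data$design$fixed$gamma10,
      g[cbind(gl$row, gl$col)]
    ),
    parameter_set = c(
      rep("lambda0", length(lab$lambda0)),
      rep("lambda_main", length(lab$main)),
      rep("lambda_interaction", length(lab$interaction)),
      rep("gamma00", nrow(data$design$fixed)),
      rep("gamma10", nrow(data$design$fixed)),
      ifelse(gl$row == gl$col, "g_variance", "g_covariance")
    )
  )
}
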