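#' Plot mastery trajectories implied by fixed effects
#'
#' Conditional-at-mean mastery probability curves per attribute over time (see
#' [mean_trajectory()]).
#'
#' @param fixed Fixed-effects tibble.
#' @param times Time grid in weeks.
#' @return A ggplot.
#' @export
plot_mean_trajectory <- function(fixed, times = seq(0, 32, by = 2)) {
  mean_trajectory(fixed, times) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$time, y = .data$probability,
                                 colour = .data$attribute)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (weeks)", y = "Mastery probability",
                  colour = "Attribute") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @describeIn simulate_ldcm Plot empirical mastery proportions per attribute
#'   and occasion against the conditional-at-mean trajectory (dashed).
#' @param object An `ldcm_data`.
#' @param ... Unused.
#' @export
autoplot.ldcm_data <- function(object, ...) {
  emp <- object$mastery |>
    dplyr::group_by(.data$attribute, .data$occasion) |>
    dplyr::summarise(proportion = mean(.data$alpha),
                     time = mean(.data$time), .groups = "drop")
  traj <- mean_trajectory(object$design$fixed, object$design$time_means) |>
    dplyr::rename(proportion = "probability")
  ggplot2::ggplot(emp, ggplot2::aes(x = .data$time, y = .data$proportion,
                                    colour = .data$attribute)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = traj, linetype = "dashed") +
    ggplot2::labs(x = "Time (weeks)", y = "Mastery proportion",
                  colour = "Attribute",
                  caption = "points: simulated data; dashed: average-person trajectory") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_ldcm Trace plot of selected parameters (defaults to the
#'   growth fixed effects) across chains.
#' @param object An `ldcm_fit`.
#' @param terms Parameter labels to trace (default: the `gamma` block).
#' @export
autoplot.ldcm_fit <- function(object, terms = NULL, ...) {
  blocks <- c("lambda0", "main", "interaction", "gamma", "g")
  all_labs <- list(lambda0 = object$labels$lambda0,
                   main = object$labels$main,
                   interaction = object$labels$interaction,
                   gamma = object$labels$gamma,
                   g = object$labels$g$labels)
  terms <- terms %||% object$labels$gamma
  df <- purrr::map(blocks, function(bl) {
    sel <- which(all_labs[[bl]] %in% terms)
    if (length(sel) == 0) return(NULL)
    arr <- object$draws[[bl]]
    purrr::map(sel, function(j) {
      m <- draw_matrix(arr, j)  # nkeep x chains
      tibble::tibble(
        term = all_labs[[bl]][j],
        chain = factor(rep(seq_len(ncol(m)), each = nrow(m))),
        iteration = rep(seq_len(nrow(m)), times = ncol(m)),
        value = as.vector(m)
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  if (nrow(df) == 0) abort("No matching parameter labels.")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value,
                                   colour = .data$chain)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "Post-burn-in iteration", y = "Draw", colour = "Chain") +
    ggplot2::theme_minimal()
}

#' Plot a classification-accuracy summary
#'
#' Correct classification rates by true status, and kappa, per attribute over
#' occasions, from a [run_condition()] result.
#'
#' @param object An `ldcm_condition`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ldcm_condition <- function(object, ...) {
  if (nrow(object$classification) == 0) {
    abort("No converged replications to plot.")
  }
  df <- object$classification |>
    tidyr::pivot_longer(c("rate_true_masters", "rate_true_nonmasters",
                          "kappa"),
                        names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$occasion, y = .data$value,
                                   colour = .data$attribute)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "Measurement occasion", y = "Value",
                  colour = "Attribute") +
    ggplot2::theme_minimal()
}
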