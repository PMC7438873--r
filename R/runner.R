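#' Derive a replication seed
#'
#' Seeds for individual replications are a pure function of the base seed and
#' the (cell, replication) coordinates, so any replication can be re-run in
#' isolation and execution order never changes results.
#'
#' @param base_seed Integer base seed.
#' @param cell Cell index within a study grid (1-based).
#' @param replication Replication index (1-based).
#' @return An integer seed below `2^31`.
#' @export
derive_seed <- function(base_seed, cell = 1L, replication = 1L) {
  as.integer((as.double(base_seed) * 1009 + cell * 10007 + replication * 101) %%
               .Machine$integer.max)
}

#' Define a factorial study grid
#'
#' The cross of the design factors: sample size, growth pattern, G condition
#' and number of measurement occasions. The full packaged grid is
#' `2 x 2 x 3 x 2` with 100 replications per cell; the `desk` preset keeps the
#' grid arguments but drops to 3 replications and short chains for desk-scale
#' runs.
#'
#' @param sample_sizes Integer vector of sample sizes.
#' @param growth_patterns Subset of `c("even", "uneven")`.
#' @param g_conditions Subset of `c("equal", "unequal")`.
#' @param n_occasions Integer vector of occasion counts.
#' @param replications Replications per cell.
#' @param base_seed Base seed (see [derive_seed()]).
#' @return A tibble with one row per cell, columns for each factor plus
#'   `cell`, `replications`, `base_seed`.
#' @export
#' @examples
#' study_grid(sample_sizes = 100, n_occasions = 5, replications = 2)
study_grid <- function(sample_sizes = c(100, 200, 300),
                       growth_patterns = c("even", "uneven"),
                       g_conditions = c("equal", "unequal"),
                       n_occasions = c(3, 5),
                       replications = 100,
                       base_seed = 1L) {
  grid <- tidyr::expand_grid(
    g_condition = g_conditions,
    growth_pattern = growth_patterns,
    n_persons = sample_sizes,
    n_occasions = n_occasions
  )
  grid |>
    dplyr::mutate(cell = dplyr::row_number(),
                  replications = replications,
                  base_seed = as.integer(base_seed)) |>
    dplyr::relocate("cell")
}

#' Run one simulation condition
#'
#' For each replication: generate a data set from the condition's design, fit
#' the model, compute convergence diagnostics, and — for converged
#' replications only — the classification report and recovery summary.
#' Non-converged replications are counted toward the convergence rate but
#' excluded from the summaries.
#'
#' @param n_persons,growth_pattern,g_condition,n_occasions Design factors
#'   (see [simulation_design()]).
#' @param replications Number of replications.
#' @param base_seed Base seed; replication seeds come from [derive_seed()].
#' @param cell Cell index used in seed derivation (default 1).
#' @param chains,iter,burnin MCMC settings passed to [fit_ldcm()].
#' @param priors Priors; default centers the G prior on the generating
#'   covariance (`g_df = KP + 20`), mirroring informative replication runs.
#' @param init Initialization mode for [fit_ldcm()].
#' @param rhat_threshold Convergence cutoff applied to every parameter.
#' @return A list of class `ldcm_condition`: tibbles `classification`
#'   (per attribute x occasion, averaged over converged replications),
#'   `recovery` (per parameter set), `replicates` (per-replication log:
#'   seed, max R-hat, converged, wall-clock seconds), and the scalar
#'   `convergence_rate`.
#' @export
run_condition <- function(n_persons = 200,
                          growth_pattern = "even",
                          g_condition = "equal",
                          n_occasions = 5,
                          replications = 3,
                          base_seed = 1L,
                          cell = 1L,
                          chains = 2, iter = 1500, burnin = 750,
                          priors = NULL,
                          init = "heuristic",
                          rhat_threshold = 1.2) {
  if (replications < 1) abort("`replications` must be >= 1.")
  if (chains < 2) abort("Convergence diagnostics require `chains` >= 2.")
  cls <- list()
  rec <- list()
  log <- list()
  for (r in seq_len(replications)) {
    seed_r <- derive_seed(base_seed, cell, r)
    design <- simulation_design(
      n_persons = n_persons, growth_pattern = growth_pattern,
      g_condition = g_condition, n_occasions = n_occasions, seed = seed_r
    )
    pr <- priors %||% prior_spec(g_center = design$g,
                                 g_df = nrow(design$g) + 20)
    t0 <- proc.time()[["elapsed"]]
    data <- simulate_ldcm(design)
    fit <- fit_ldcm(data, chains = chains, iter = iter, burnin = burnin,
                    priors = pr, seed = seed_r, init = init)
    rh <- rhat_summary(fit)
    conv <- replication_converged(rh$rhat, rhat_threshold)
    elapsed <- proc.time()[["elapsed"]] - t0
    log[[r]] <- tibble::tibble(
      replication = r, seed = seed_r, max_rhat = max(rh$rhat),
      converged = conv, seconds = elapsed
    )
    if (conv) {
      est <- posterior_mastery_probability(fit) |>
        dplyr::inner_join(
          data$mastery |>
            dplyr::select("person", "occasion", "attribute", "alpha",
                          true_probability = "probability"),
          by = c("person", "occasion", "attribute")
        )
      cls[[r]] <- classification_report(
        est, truth = alpha, prob = probability,
        true_prob = true_probability
      ) |> dplyr::mutate(replication = r)
      rec[[r]] <- recovery_summary(fit, data) |>
        dplyr::mutate(replication = r)
    }
  }
  log <- dplyr::bind_rows(log)
  conv_rate <- mean(log$converged)
  classification <- if (length(cls) > 0) {
    dplyr::bind_rows(cls) |>
      dplyr::group_by(.data$attribute, .data$occasion) |>
      dplyr::summarise(
        dplyr::across(c("prob_bias", "rate_true_masters",
                        "rate_true_nonmasters", "kappa"),
                      ~ mean(.x, na.rm = TRUE)),
        replications = dplyr::n(), .groups = "drop"
      )
  } else {
    tibble::tibble()
  }
  recovery <- if (length(rec) > 0) {
    dplyr::bind_rows(rec) |>
      dplyr::group_by(.data$parameter_set) |>
      dplyr::summarise(bias = mean(.data$bias), mse = mean(.data$mse),
                       replications = dplyr::n(), .groups = "drop")
  } else {
    tibble::tibble()
  }
  structure(
    list(
      classification = classification, recovery = recovery,
      recovery_replicates = if (length(rec) > 0) dplyr::bind_rows(rec)
                            else tibble::tibble(),
      replicates = log, convergence_rate = conv_rate,
      condition = tibble::tibble(
        n_persons = n_persons, growth_pattern = growth_pattern,
        g_condition = g_condition, n_occasions = n_occasions
      ),
      status = if (any(log$converged)) "ok" else "no_converged_replications"
    ),
    class = "ldcm_condition"
  )
}

#' @export
print.ldcm_condition <- function(x, ...) {
  cat("<ldcm_condition>\n")
  print(x$condition)
  cat(sprintf("  convergence rate: %.2f (%d replications)\n",
              x$convergence_rate, nrow(x$replicates)))
  invisible(x)
}

#' Run a factorial study
#'
#' Runs every cell of a [study_grid()], concatenates the per-cell summaries,
#' and — when the grid varies at least one factor — assesses the impact of the
#' design factors (G condition, growth pattern, sample size and their two-way
#' interactions) on the recovery outcomes with a factorial ANOVA per
#' measurement-occasion stratum, reporting partial eta-squared effect sizes.
#' Cells that error are recorded and skipped; the study continues.
#'
#' @param grid A [study_grid()] tibble.
#' @param ... MCMC settings forwarded to [run_condition()].
#' @return A list of class `ldcm_study`: `classification` and `recovery`
#'   summaries keyed by the design factors, `convergence` (rate per cell),
#'   `anova` (partial eta-squared per outcome and term, per occasion
#'   stratum), and `failures`.
#' @export
run_study <- function(grid, ...) {
  cells <- purrr::map(seq_len(nrow(grid)), function(i) {
    row <- grid[i, ]
    tryCatch(
      run_condition(
        n_persons = row$n_persons, growth_pattern = row$growth_pattern,
        g_condition = row$g_condition, n_occasions = row$n_occasions,
        replications = row$replications, base_seed = row$base_seed,
        cell = row$cell, ...
      ),
      error = function(e) e
    )
  })
  ok <- !vapply(cells, inherits, TRUE, what = "error")
  failures <- tibble::tibble(
    cell = grid$cell[!ok],
    message = vapply(cells[!ok], conditionMessage, "")
  )
  key <- function(i, tbl) {
    if (nrow(tbl) == 0) return(tbl)
    dplyr::bind_cols(grid[i, c("g_condition", "growth_pattern", "n_persons",
                               "n_occasions")], tbl)
  }
  classification <- purrr::map2(which(ok), cells[ok],
                                ~ key(.x, .y$classification)) |>
    dplyr::bind_rows()
  recovery <- purrr::map2(which(ok), cells[ok], ~ key(.x, .y$recovery)) |>
    dplyr::bind_rows()
  recovery_reps <- purrr::map2(which(ok), cells[ok],
                               ~ key(.x, .y$recovery_replicates)) |>
    dplyr::bind_rows()
  convergence <- purrr::map2(
    which(ok), cells[ok],
    ~ dplyr::bind_cols(grid[.x, ], tibble::tibble(
      convergence_rate = .y$convergence_rate))
  ) |> dplyr::bind_rows()

  # the factorial ANOVA runs on replication-level outcomes, one observation
  # per (cell, replication), as the evaluation design prescribes
  anova_tbl <- study_anova(recovery_reps)
  structure(
    list(classification = classification, recovery = recovery,
         convergence = convergence, anova = anova_tbl, failures = failures,
         grid = grid),
    class = "ldcm_study"
  )
}

# factorial ANOVA of recovery outcomes on the design factors, within each
# measurement-occasion stratum (factors: G, SZ = sample size, GP = growth)
study_anova <- function(recovery) {
  if (nrow(recovery) == 0) return(tibble::tibble())
  rec <- recovery |>
    dplyr::rename(G = "g_condition", GP = "growth_pattern", SZ = "n_persons")
  factors <- c("G", "GP", "SZ")
  factors <- factors[vapply(rec[factors],
                            function(f) length(unique(f)) >= 2, TRUE)]
  if (length(factors) == 0) return(tibble::tibble())
  rec |>
    tidyr::pivot_longer(c("bias", "mse"), names_to = "outcome") |>
    dplyr::group_by(.data$n_occasions, .data$parameter_set, .data$outcome) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < length(factors) + 2 || var(d$value) == 0) {
        return(tibble::tibble())
      }
      tryCatch(anova_partial_eta2(d, "value", factors),
               error = function(e) tibble::tibble())
    }) |>
    dplyr::ungroup()
}

#' @export
print.ldcm_study <- function(x, ...) {
  cat("<ldcm_study>\n")
  cat(sprintf("  %d cells, %d failed\n", nrow(x$grid), nrow(x$failures)))
  if (nrow(x$convergence) > 0) {
    cat(sprintf("  mean convergence rate: %.2f\n",
                mean(x$convergence$convergence_rate)))
  }
  invisible(x)
}

#' Write condition or study summaries to CSV
#'
#' Writes the summary tibbles of a [run_condition()] or [run_study()] result
#' into a directory (`classification.csv`, `recovery.csv`, `replicates.csv` /
#' `convergence.csv`, `anova.csv`), refusing to overwrite unless forced.
#'
#' @param x An `ldcm_condition` or `ldcm_study`.
#' @param dir Output directory.
#' @param overwrite Overwrite existing summaries.
#' @return `dir`, invisibly.
#' @export
write_summaries <- function(x, dir, overwrite = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- if (inherits(x, "ldcm_condition")) {
    list(classification = x$classification, recovery = x$recovery,
         replicates = x$replicates)
  } else if (inherits(x, "ldcm_study")) {
    list(classification = x$classification, recovery = x$recovery,
         convergence = x$convergence, anova = x$anova)
  } else {
    abort("`x` must be an `ldcm_condition` or `ldcm_study`.")
  }
  for (nm in names(tables)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (file.exists(path) && !overwrite) {
      abort(sprintf("`%s` exists; use `overwrite = TRUE`.", path))
    }
    readr::write_csv(tables[[nm]], path)
  }
  invisible(dir)
}
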