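#' Prior specification for the Bayesian fit
#'
#' Priors for every sampled block: normal priors for item intercepts, normal
#' priors truncated to the monotonicity region for main effects (`>= 0`) and
#' interactions (`>= -min(main effects of the pair)`), diffuse normal priors
#' for the growth fixed effects, and an inverse-Wishart prior for the
#' random-effect covariance G. Supplying `g_center` centers the
#' inverse-Wishart *mean* on a known matrix (scale is then
#' `g_center * (g_df - KP - 1)`), reproducing informative replication runs in
#' which the generating covariance is used as prior information; the default
#' (no center) is the weakly informative `IW(KP + 2, I)`.
#'
#' @param intercept_mean,intercept_sd Normal prior for item intercepts.
#' @param main_sd SD of the half-normal (truncated-at-zero) main-effect prior.
#' @param interaction_sd SD of the truncated-normal interaction prior.
#' @param gamma_sd SD of the zero-mean normal prior on growth fixed effects.
#' @param g_df Inverse-Wishart degrees of freedom (default `KP + 2`, resolved
#'   at fit time; must exceed `KP - 1`).
#' @param g_center Optional `KP x KP` matrix on which to center the prior mean
#'   of G.
#' @return An object of class `ldcm_priors`.
#' @export
prior_spec <- function(intercept_mean = 0, intercept_sd = 2,
                       main_sd = 2, interaction_sd = 2,
                       gamma_sd = 10, g_df = NULL, g_center = NULL) {
  if (intercept_sd <= 0 || main_sd <= 0 || interaction_sd <= 0 || gamma_sd <= 0) {
    abort("Prior standard deviations must be > 0.")
  }
  structure(
    list(intercept_mean = intercept_mean, intercept_sd = intercept_sd,
         main_sd = main_sd, interaction_sd = interaction_sd,
         gamma_sd = gamma_sd, g_df = g_df, g_center = g_center),
    class = "ldcm_priors"
  )
}

resolve_g_prior <- function(priors, kp) {
  df <- priors$g_df %||% (kp + 2)
  if (df <= kp - 1) abort("Inverse-Wishart `g_df` must exceed KP - 1.")
  scale <- if (is.null(priors$g_center)) {
    diag(kp)
  } else {
    if (df - kp - 1 <= 0) {
      abort("Centering the G prior requires `g_df` > KP + 1.")
    }
    priors$g_center * (df - kp - 1)
  }
  list(df = df, scale = scale)
}

# Assemble long responses into the dense structures the sampler uses. Rows are
# ordered occasion-within-person so per-person sums are colSums of a T x N
# reshape.
prep_fit_data <- function(responses, qmatrix) {
  validate_qmatrix(qmatrix)
  need <- c("person", "occasion", "time", "item", "response")
  if (!all(need %in% names(responses))) {
    abort(paste0("`responses` must have columns ",
                 paste(need, collapse = ", "), "."))
  }
  persons <- sort(unique(responses$person))
  occasions <- sort(unique(responses$occasion))
  items <- qmatrix$item
  N <- length(persons)
  T_ <- length(occasions)
  I <- length(items)
  if (T_ < 2) abort("At least two measurement occasions are required.")
  if (nrow(responses) != N * T_ * I) {
    abort("`responses` must be complete: one row per person x occasion x item.")
  }
  ord <- order(match(responses$person, persons),
               match(responses$occasion, occasions),
               match(responses$item, items))
  resp <- responses[ord, ]
  X <- matrix(resp$response, nrow = N * T_, ncol = I, byrow = TRUE)
  if (!all(X %in% c(0, 1))) abort("Responses must be 0/1.")
  first <- resp[seq(1, nrow(resp), by = I), ]
  list(
    X = X,
    time = first$time,
    person = match(first$person, persons),
    occasion = match(first$occasion, occasions),
    persons = persons, occasions = occasions, items = items,
    N = N, T = T_, I = I
  )
}

# Q-matrix bookkeeping shared by all updates.
q_structure <- function(qmatrix) {
  m <- q_matrix(qmatrix)
  attrs <- q_attr_names(qmatrix)
  K <- ncol(m)
  I <- nrow(m)
  meas <- lapply(seq_len(I), function(i) which(m[i, ] == 1))
  k1 <- vapply(meas, function(x) if (length(x) >= 2) x[1] else NA_integer_, 1L)
  k2 <- vapply(meas, function(x) if (length(x) >= 2) x[2] else NA_integer_, 1L)
  slot1 <- vapply(meas, function(x) x[1], 1L)
  slot2 <- vapply(meas, function(x) if (length(x) >= 2) x[2] else NA_integer_, 1L)
  list(m = m, attrs = attrs, K = K, I = I, meas = meas,
       k1 = k1, k2 = k2, slot1 = slot1, slot2 = slot2,
       two = which(!is.na(k1)),
       items_by_attr = lapply(seq_len(K), function(k) which(m[, k] == 1)))
}

# eta for the current item parameters/alpha, given q_structure qs
state_eta <- function(alpha, st, qs) {
  eta <- alpha %*% t(st$Lmain)
  eta <- sweep(eta, 2, st$lambda0, "+")
  if (length(qs$two) > 0) {
    eta[, qs$two] <- eta[, qs$two] +
      (alpha[, qs$k1[qs$two], drop = FALSE] *
         alpha[, qs$k2[qs$two], drop = FALSE]) *
      rep(st$int_val[qs$two], each = nrow(alpha))
  }
  eta
}

#' Fit the multivariate longitudinal DCM by MCMC
#'
#' Runs a blocked Metropolis-within-Gibbs sampler for the joint model:
#' \enumerate{
#'   \item latent mastery indicators by their exact Bernoulli full
#'     conditionals, combining the LCDM likelihood of the occasion's responses
#'     with the growth-model prior logit;
#'   \item item parameters by per-item random-walk Metropolis steps restricted
#'     to the monotonicity region (vectorized across items, which are
#'     conditionally independent given mastery);
#'   \item growth fixed effects and person random effects by random-walk
#'     Metropolis on the Bernoulli mastery likelihood (random effects
#'     coordinate-wise, vectorized across persons);
#'   \item G by its conjugate inverse-Wishart full conditional given the
#'     random effects.
#' }
#' Random-walk step sizes adapt during burn-in toward a 20-45% acceptance rate
#' and are frozen afterwards. Logits are clipped at +/-35 before Bernoulli
#' draws; a warning reports if clipping ever fired.
#'
#' @param data An `ldcm_data` from [simulate_ldcm()], or a long response
#'   tibble with columns `person`, `occasion`, `time`, `item`, `response`.
#' @param qmatrix Q-matrix; defaults to the one in `data$design`.
#' @param priors A [prior_spec()].
#' @param chains Number of chains (>= 2 for convergence diagnostics).
#' @param iter Total iterations per chain.
#' @param burnin Burn-in iterations discarded (`iter > burnin >= 0`).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer seed; the whole run is reproducible given it.
#' @param init `"heuristic"` (response-score start, chains jittered),
#'   `"random"` (dispersed random start), or `"truth"` (generating values;
#'   requires an `ldcm_data` with its truth block — sanity runs only).
#' @param update Named list of logicals switching sampling blocks on/off
#'   (`alpha`, `items`, `growth`, `g`); fixing a block holds it at its
#'   initial value, which with `init = "truth"` gives oracle conditionals.
#' @param store_alpha Keep the full array of sampled mastery indicators
#'   (needed by [posterior_mastery_probability()]; default `TRUE`).
#' @param u_sweeps Coordinate sweeps of the random-effect block per iteration
#'   (default 3; the binary mastery data identify the random effects weakly,
#'   and extra sweeps speed up the mixing of G at little cost).
#' @param center_time Subtract the mean time score of the medial occasion
#'   from every time score before fitting (default `FALSE`). Centering moves
#'   the intercept to the middle of the study, where the data carry the most
#'   information about it — recommended when intercept recovery matters; the
#'   reported `gamma00` then refers to the medial occasion, not time 0.
#' @return An object of class `ldcm_fit` holding post-burn-in draws of every
#'   block, parameter labels, acceptance rates and the configuration.
#' @export
fit_ldcm <- function(data, qmatrix = NULL, priors = prior_spec(),
                     chains = 2, iter = 2000, burnin = 1000, thin = 1,
                     seed = 1L, init = c("heuristic", "random", "truth"),
                     update = list(), store_alpha = TRUE, u_sweeps = 3,
                     center_time = FALSE) {
  init <- match.arg(init)
  upd <- utils::modifyList(
    list(alpha = TRUE, items = TRUE, growth = TRUE, g = TRUE), update)
  if (iter <= burnin || burnin < 0) abort("Need `iter` > `burnin` >= 0.")
  if (chains < 1) abort("`chains` must be >= 1.")
  is_sim <- inherits(data, "ldcm_data")
  if (is.null(qmatrix)) {
    if (!is_sim) abort("`qmatrix` is required when `data` is a plain tibble.")
    qmatrix <- data$design$qmatrix
  }
  responses <- if (is_sim) data$responses else data
  dat <- prep_fit_data(responses, qmatrix)
  if (center_time) {
    med_idx <- ceiling(dat$T / 2)
    dat$time <- dat$time - mean(dat$time[dat$occasion == med_idx])
  }
  qs <- q_structure(qmatrix)
  kp <- 2 * qs$K
  gp <- resolve_g_prior(priors, kp)
  if (init == "truth" && !is_sim) {
    abort("`init = \"truth\"` requires an `ldcm_data` with its truth block.")
  }

  keep_idx <- seq(burnin + 1, iter, by = thin)
  nkeep <- length(keep_idx)
  labels <- sampler_labels(qs, dat)
  draws <- allocate_draws(chains, nkeep, qs, dat, labels, store_alpha)
  accept <- NULL
  clip_count <- 0

  withr::with_seed(seed, {
    for (ch in seq_len(chains)) {
      st <- init_state(init, ch, dat, qs, gp, data, qmatrix)
      res <- run_chain(st, dat, qs, priors, gp, iter, burnin, keep_idx, upd,
                       store_alpha, u_sweeps)
      store_chain(draws, ch, res, store_alpha)
      accept <- res$accept
      clip_count <- clip_count + res$clip_count
    }
  })
  if (clip_count > 0) {
    warn(sprintf("Logits clipped at +/-%d in %d draws (overflow guard).",
                 LOGIT_CLIP, clip_count))
  }

  structure(
    list(
      draws = as.list(draws), labels = labels,
      meta = list(persons = dat$persons, occasions = dat$occasions,
                  items = dat$items, attrs = qs$attrs,
                  person = dat$person, occasion = dat$occasion,
                  time = dat$time, N = dat$N, T = dat$T, I = dat$I,
                  K = qs$K),
      config = list(chains = chains, iter = iter, burnin = burnin,
                    thin = thin, seed = seed, init = init, update = upd,
                    store_alpha = store_alpha),
      priors = priors, accept = accept, qmatrix = qmatrix
    ),
    class = "ldcm_fit"
  )
}

sampler_labels <- function(qs, dat) {
  main_items <- c(seq_len(qs$I), qs$two)
  main_attrs <- c(qs$slot1, qs$slot2[qs$two])
  list(
    lambda0 = paste0("lambda0[", dat$items, "]"),
    main = paste0("lambda1[", dat$items[main_items], ",",
                  qs$attrs[main_attrs], "]"),
    main_items = main_items, main_attrs = main_attrs,
    interaction = paste0("lambda2[", dat$items[qs$two], ",",
                         qs$attrs[qs$k1[qs$two]], ":",
                         qs$attrs[qs$k2[qs$two]], "]"),
    gamma = c(paste0("gamma00_", qs$attrs), paste0("gamma10_", qs$attrs)),
    g = g_label_pairs(re_labels(qs$attrs)),
    u = re_labels(qs$attrs)
  )
}

g_label_pairs <- function(lab) {
  kp <- length(lab)
  idx <- which(lower.tri(diag(kp), diag = TRUE), arr.ind = TRUE)
  list(labels = paste0("g[", lab[idx[, 1]], ",", lab[idx[, 2]], "]"),
       row = idx[, 1], col = idx[, 2])
}

allocate_draws <- function(chains, nkeep, qs, dat, labels, store_alpha) {
  e <- new.env(parent = emptyenv())
  e$lambda0 <- array(NA_real_, c(chains, nkeep, qs$I))
  e$main <- array(NA_real_, c(chains, nkeep, length(labels$main)))
  e$interaction <- array(NA_real_, c(chains, nkeep, length(qs$two)))
  e$gamma <- array(NA_real_, c(chains, nkeep, 2 * qs$K))
  e$g <- array(NA_real_, c(chains, nkeep, length(labels$g$labels)))
  e$u <- array(NA_real_, c(chains, nkeep, dat$N * 2 * qs$K))
  if (store_alpha) {
    e$alpha <- array(NA_integer_, c(chains, nkeep, dat$N * dat$T * qs$K))
  }
  e
}

store_chain <- function(draws, ch, res, store_alpha) {
  draws$lambda0[ch, , ] <- res$lambda0
  draws$main[ch, , ] <- res$main
  draws$interaction[ch, , ] <- res$interaction
  draws$gamma[ch, , ] <- res$gamma
  draws$g[ch, , ] <- res$g
  draws$u[ch, , ] <- res$u
  if (store_alpha) draws$alpha[ch, , ] <- res$alpha
  invisible(draws)
}

init_state <- function(init, chain, dat, qs, gp, data, qmatrix) {
  RT <- dat$N * dat$T
  K <- qs$K
  g_init <- gp$scale / max(gp$df - 2 * K - 1, 1)
  if (init == "truth") {
    ipm <- ip_compile(data$design$item_params, qmatrix)
    mast <- data$mastery
    ord <- order(match(mast$person, dat$persons),
                 match(mast$occasion, dat$occasions),
                 match(mast$attribute, qs$attrs))
    alpha <- matrix(mast$alpha[ord], RT, K, byrow = TRUE)
    u <- split_random_effects(data$random_effects, qs$attrs)
    st <- list(alpha = alpha, lambda0 = ipm$lambda0, Lmain = ipm$Lmain,
               int_val = ipm$int_val,
               gamma0 = data$design$fixed$gamma00,
               gamma1 = data$design$fixed$gamma10,
               u0 = u$u0, u1 = u$u1, G = data$design$g)
  } else if (init == "random") {
    alpha <- matrix(rbinom(RT * K, 1, 0.5), RT, K)
    Lmain <- qs$m * abs(rnorm(1, 1, 0.5))
    st <- list(alpha = alpha,
               lambda0 = rnorm(qs$I, -1, 0.5),
               Lmain = Lmain * matrix(abs(rnorm(qs$I * K, 1, 0.3)), qs$I, K),
               int_val = ifelse(is.na(qs$k1), 0, abs(rnorm(qs$I, 0.2, 0.1))),
               gamma0 = rnorm(K, -1, 0.5), gamma1 = rnorm(K, 0, 0.02),
               u0 = matrix(rnorm(dat$N * K, 0, 0.3), dat$N, K),
               u1 = matrix(rnorm(dat$N * K, 0, 0.05), dat$N, K),
               G = g_init)
  } else {
    # response-score start: mastery guessed from the share of correct answers
    # on the items measuring each attribute, parameters at generic values
    alpha <- sapply(seq_len(K), function(k) {
      as.numeric(rowMeans(dat$X[, qs$items_by_attr[[k]], drop = FALSE]) >= 0.5)
    })
    alpha <- matrix(alpha, RT, K)
    occ_rate <- function(k, occ) {
      r <- alpha[dat$occasion == occ, k]
      min(max(mean(r), 0.03), 0.97)
    }
    g0 <- vapply(seq_len(K), function(k) qlogis(occ_rate(k, 1)), 1)
    gT <- vapply(seq_len(K), function(k) qlogis(occ_rate(k, dat$T)), 1)
    span <- max(mean(dat$time[dat$occasion == dat$T]) -
                  mean(dat$time[dat$occasion == 1]), 1)
    jit <- (chain - 1)  # dispersed starts across chains
    st <- list(alpha = alpha,
               lambda0 = rep(-1, qs$I) + rnorm(qs$I, 0, 0.3 * jit),
               Lmain = qs$m * (1 + if (jit > 0) abs(rnorm(1, 0, 0.3)) else 0),
               int_val = ifelse(is.na(qs$k1), 0, 0.2),
               gamma0 = g0 + rnorm(K, 0, 0.2 * jit),
               gamma1 = (gT - g0) / span + rnorm(K, 0, 0.005 * jit),
               G = g_init)
    # start random effects at a draw from their prior rather than at zero so
    # the G block does not have to climb out of a degenerate start
    U0 <- MASS::mvrnorm(dat$N, rep(0, 2 * K), g_init)
    st$u0 <- U0[, seq(1, 2 * K, by = 2), drop = FALSE]
    st$u1 <- U0[, seq(2, 2 * K, by = 2), drop = FALSE]
  }
  st$Lmain <- pmax(st$Lmain, 0) * qs$m
  # degenerate (e.g. all-zero) G can arise in fixed-growth oracle runs
  st$Ginv <- tryCatch(solve(st$G), error = function(e) MASS::ginv(st$G))
  st
}

run_chain <- function(st, dat, qs, priors, gp, iter, burnin, keep_idx, upd,
                      store_alpha, u_sweeps = 3) {
  RT <- dat$N * dat$T
  K <- qs$K
  I <- qs$I
  nkeep <- length(keep_idx)
  n_main <- I + length(qs$two)
  out <- list(
    lambda0 = matrix(NA_real_, nkeep, I),
    main = matrix(NA_real_, nkeep, n_main),
    interaction = matrix(NA_real_, nkeep, length(qs$two)),
    gamma = matrix(NA_real_, nkeep, 2 * K),
    g = matrix(NA_real_, nkeep, K * (2 * K + 1)),
    u = matrix(NA_real_, nkeep, dat$N * 2 * K),
    alpha = if (store_alpha) matrix(NA_integer_, nkeep, RT * K) else NULL
  )
  glab <- g_label_pairs(re_labels(qs$attrs))

  # random-walk step sizes; adapted during burn-in only
  step <- list(l0 = 0.3, main = 0.3, int = 0.4, g0 = 0.15, g1 = 0.01,
               u = rep(c(0.5, 0.05), K), rc = rep(c(0.1, 0.01), K),
               uj = 0.5)
  acc <- att <- list(l0 = 0, main = 0, int = 0, g0 = 0, g1 = 0,
                     u = rep(0, 2 * K), rc = rep(0, 2 * K), uj = 0)
  clip_count <- 0
  keep_ptr <- 0

  # person-membership map for per-person sums: v -> colSums(matrix(v, T, N))
  psum <- function(v) colSums(matrix(v, dat$T, dat$N))
  lp <- growth_logits(st, dat)

  for (it in seq_len(iter)) {
    ## -- latent mastery: exact Bernoulli full conditionals ----------------
    if (upd$alpha) {
      for (k in seq_len(K)) {
        ik <- qs$items_by_attr[[k]]
        other <- ifelse(qs$k1[ik] == k, qs$k2[ik],
                        ifelse(qs$k2[ik] == k, qs$k1[ik], NA_integer_))
        m <- length(ik)
        Aoth <- matrix(0, RT, m)
        has <- which(!is.na(other))
        if (length(has) > 0) Aoth[, has] <- st$alpha[, other[has], drop = FALSE]
        main_other <- numeric(m)
        main_other[has] <- st$Lmain[cbind(ik[has], other[has])]
        eta0 <- matrix(st$lambda0[ik], RT, m, byrow = TRUE) +
          Aoth * matrix(main_other, RT, m, byrow = TRUE)
        delta <- matrix(st$Lmain[cbind(ik, k)], RT, m, byrow = TRUE) +
          Aoth * matrix(ifelse(is.na(other), 0, st$int_val[ik]),
                        RT, m, byrow = TRUE)
        Xk <- dat$X[, ik, drop = FALSE]
        llr <- rowSums(bern_loglik(Xk, eta0 + delta) - bern_loglik(Xk, eta0))
        logit_full <- lp[, k] + llr
        nclip <- sum(abs(logit_full) > LOGIT_CLIP)
        if (nclip > 0) clip_count <- clip_count + nclip
        st$alpha[, k] <- rbinom(RT, 1, plogis(clip_logit(logit_full)))
      }
    }

    ## -- item parameters: per-item random-walk MH -------------------------
    if (upd$items) {
      eta <- state_eta(st$alpha, st, qs)
      ll_cur <- colSums(bern_loglik(dat$X, eta))

      # intercepts
      d <- rnorm(I, 0, step$l0)
      eta_new <- sweep(eta, 2, d, "+")
      ll_new <- colSums(bern_loglik(dat$X, eta_new))
      lr <- ll_new - ll_cur +
        dnorm_diff(st$lambda0 + d, st$lambda0,
                   priors$intercept_mean, priors$intercept_sd)
      a <- log(runif(I)) < lr
      st$lambda0[a] <- st$lambda0[a] + d[a]
      eta[, a] <- eta_new[, a]
      ll_cur[a] <- ll_new[a]
      acc$l0 <- acc$l0 + mean(a); att$l0 <- att$l0 + 1

      # main effects, one slot per scan so items stay independent
      for (slot in 1:2) {
        sel <- if (slot == 1) seq_len(I) else qs$two
        if (length(sel) == 0) next
        katt <- if (slot == 1) qs$slot1[sel] else qs$slot2[sel]
        cur <- st$Lmain[cbind(sel, katt)]
        d <- rnorm(length(sel), 0, step$main)
        newv <- cur + d
        # monotonicity: mains >= 0, interaction >= -min(mains of pair)
        other_main <- rep(Inf, length(sel))
        intv <- rep(0, length(sel))
        two_here <- which(sel %in% qs$two)
        if (length(two_here) > 0) {
          it2 <- sel[two_here]
          oth <- ifelse(katt[two_here] == qs$k1[it2], qs$k2[it2], qs$k1[it2])
          other_main[two_here] <- st$Lmain[cbind(it2, oth)]
          intv[two_here] <- st$int_val[it2]
        }
        ok <- newv >= 0 & intv >= -pmin(newv, other_main)
        dEta <- st$alpha[, katt, drop = FALSE] *
          matrix(d, RT, length(sel), byrow = TRUE)
        eta_new <- eta[, sel, drop = FALSE] + dEta
        ll_new <- colSums(bern_loglik(dat$X[, sel, drop = FALSE], eta_new))
        lr <- ll_new - ll_cur[sel] + dnorm_diff(newv, cur, 0, priors$main_sd)
        a <- ok & (log(runif(length(sel))) < lr)
        st$Lmain[cbind(sel[a], katt[a])] <- newv[a]
        eta[, sel[a]] <- eta_new[, a, drop = FALSE]
        ll_cur[sel[a]] <- ll_new[a]
        acc$main <- acc$main + mean(a); att$main <- att$main + 1
      }

      # interactions (two-attribute items only)
      if (length(qs$two) > 0) {
        sel <- qs$two
        cur <- st$int_val[sel]
        d <- rnorm(length(sel), 0, step$int)
        newv <- cur + d
        minmain <- pmin(st$Lmain[cbind(sel, qs$k1[sel])],
                        st$Lmain[cbind(sel, qs$k2[sel])])
        ok <- newv >= -minmain
        both <- st$alpha[, qs$k1[sel], drop = FALSE] *
          st$alpha[, qs$k2[sel], drop = FALSE]
        eta_new <- eta[, sel, drop = FALSE] +
          both * matrix(d, RT, length(sel), byrow = TRUE)
        ll_new <- colSums(bern_loglik(dat$X[, sel, drop = FALSE], eta_new))
        lr <- ll_new - ll_cur[sel] +
          dnorm_diff(newv, cur, 0, priors$interaction_sd)
        a <- ok & (log(runif(length(sel))) < lr)
        st$int_val[sel[a]] <- newv[a]
        eta[, sel[a]] <- eta_new[, a, drop = FALSE]
        ll_cur[sel[a]] <- ll_new[a]
        acc$int <- acc$int + mean(a); att$int <- att$int + 1
      }
    }

    ## -- growth model: fixed effects then random effects ------------------
    if (upd$growth) {
      mll_cur <- colSums(bern_loglik(st$alpha, lp))

      d <- rnorm(K, 0, step$g0)
      lp_new <- sweep(lp, 2, d, "+")
      mll_new <- colSums(bern_loglik(st$alpha, lp_new))
      lr <- mll_new - mll_cur +
        dnorm_diff(st$gamma0 + d, st$gamma0, 0, priors$gamma_sd)
      a <- log(runif(K)) < lr
      st$gamma0[a] <- st$gamma0[a] + d[a]
      lp[, a] <- lp_new[, a]
      mll_cur[a] <- mll_new[a]
      acc$g0 <- acc$g0 + mean(a); att$g0 <- att$g0 + 1

      d <- rnorm(K, 0, step$g1)
      lp_new <- lp + dat$time * matrix(d, RT, K, byrow = TRUE)
      mll_new <- colSums(bern_loglik(st$alpha, lp_new))
      lr <- mll_new - mll_cur +
        dnorm_diff(st$gamma1 + d, st$gamma1, 0, priors$gamma_sd)
      a <- log(runif(K)) < lr
      st$gamma1[a] <- st$gamma1[a] + d[a]
      lp[, a] <- lp_new[, a]
      acc$g1 <- acc$g1 + mean(a); att$g1 <- att$g1 + 1

      # random effects: coordinate-wise across the 2K effects, all persons at
      # once (persons are independent given gamma and G); several sweeps per
      # iteration since the binary mastery data identify u only weakly and u
      # drives the mixing of G
      U <- interleave_u(st$u0, st$u1)
      for (j in rep(seq_len(2 * K), u_sweeps)) {
        k <- ceiling(j / 2)
        is_slope <- (j %% 2 == 0)
        d <- rnorm(dat$N, 0, step$u[j])
        drt <- d[dat$person] * (if (is_slope) dat$time else 1)
        ll_diff <- psum(bern_loglik(st$alpha[, k], lp[, k] + drt) -
                          bern_loglik(st$alpha[, k], lp[, k]))
        cvec <- U %*% st$Ginv[, j]
        pr_diff <- -0.5 * (2 * d * cvec + d^2 * st$Ginv[j, j])
        a <- log(runif(dat$N)) < (ll_diff + pr_diff)
        if (any(a)) {
          U[a, j] <- U[a, j] + d[a]
          upd_rt <- a[dat$person]
          lp[upd_rt, k] <- lp[upd_rt, k] + drt[upd_rt]
        }
        acc$u[j] <- acc$u[j] + mean(a); att$u[j] <- att$u[j] + 1
      }
      # joint per-person proposal along the Cholesky directions of G: the
      # posterior of u_r is dominated by the strongly correlated prior, so
      # coordinate moves alone are inefficient
      {
        L <- tryCatch(chol(st$G), error = function(e) NULL)
        if (!is.null(L)) {
          D <- matrix(rnorm(dat$N * 2 * K), dat$N) %*% L * step$uj
          Unew <- U + D
          dll <- numeric(dat$N)
          for (k in seq_len(K)) {
            drt <- D[dat$person, 2 * k - 1] + D[dat$person, 2 * k] * dat$time
            dll <- dll + psum(bern_loglik(st$alpha[, k], lp[, k] + drt) -
                                bern_loglik(st$alpha[, k], lp[, k]))
          }
          qf <- function(M) rowSums((M %*% st$Ginv) * M)
          a <- log(runif(dat$N)) < (dll - 0.5 * (qf(Unew) - qf(U)))
          if (any(a)) {
            for (k in seq_len(K)) {
              drt <- D[dat$person, 2 * k - 1] + D[dat$person, 2 * k] * dat$time
              upd_rt <- a[dat$person]
              lp[upd_rt, k] <- lp[upd_rt, k] + drt[upd_rt]
            }
            U[a, ] <- Unew[a, , drop = FALSE]
          }
          acc$uj <- acc$uj + mean(a); att$uj <- att$uj + 1
        }
      }

      # recentering move: shift gamma_j and every person's u_j in opposite
      # directions. The likelihood is invariant, so acceptance depends on the
      # priors only; this breaks the gamma/mean(u) confounding that otherwise
      # slows both blocks.
      for (j in seq_len(2 * K)) {
        k <- ceiling(j / 2)
        is_slope <- (j %% 2 == 0)
        d <- rnorm(1, 0, step$rc[j])
        gcur <- if (is_slope) st$gamma1[k] else st$gamma0[k]
        pr <- dnorm_diff(gcur + d, gcur, 0, priors$gamma_sd) +
          d * sum(U %*% st$Ginv[, j]) - 0.5 * dat$N * d^2 * st$Ginv[j, j]
        if (log(runif(1)) < pr) {
          if (is_slope) st$gamma1[k] <- gcur + d else st$gamma0[k] <- gcur + d
          U[, j] <- U[, j] - d
          acc$rc[j] <- acc$rc[j] + 1
        }
        att$rc[j] <- att$rc[j] + 1
      }
      st$u0 <- U[, seq(1, 2 * K, by = 2), drop = FALSE]
      st$u1 <- U[, seq(2, 2 * K, by = 2), drop = FALSE]
    }

    ## -- G: conjugate inverse-Wishart --------------------------------------
    if (upd$g) {
      U <- interleave_u(st$u0, st$u1)
      S <- gp$scale + crossprod(U)
      W <- rWishart(1, gp$df + dat$N, solve(S))[, , 1]
      st$Ginv <- (W + t(W)) / 2
      st$G <- solve(st$Ginv)
      st$G <- (st$G + t(st$G)) / 2
    }

    ## -- adaptation (burn-in only) -----------------------------------------
    if (it <= burnin && it %% 50 == 0) {
      tune <- function(s, accn, attn) {
        if (attn == 0) return(s)
        rate <- accn / attn
        if (rate > 0.45) s * 1.2 else if (rate < 0.20) s / 1.2 else s
      }
      step$l0 <- tune(step$l0, acc$l0, att$l0)
      step$main <- tune(step$main, acc$main, att$main)
      step$int <- tune(step$int, acc$int, att$int)
      step$g0 <- tune(step$g0, acc$g0, att$g0)
      step$g1 <- tune(step$g1, acc$g1, att$g1)
      for (j in seq_len(2 * K)) {
        step$u[j] <- tune(step$u[j], acc$u[j], att$u[j])
        step$rc[j] <- tune(step$rc[j], acc$rc[j], att$rc[j])
      }
      step$uj <- tune(step$uj, acc$uj, att$uj)
      acc <- att <- list(l0 = 0, main = 0, int = 0, g0 = 0, g1 = 0,
                         u = rep(0, 2 * K), rc = rep(0, 2 * K), uj = 0)
    }

    ## -- storage ------------------------------------------------------------
    if (keep_ptr < nkeep && it == keep_idx[keep_ptr + 1]) {
      keep_ptr <- keep_ptr + 1
      out$lambda0[keep_ptr, ] <- st$lambda0
      out$main[keep_ptr, ] <- c(st$Lmain[cbind(seq_len(I), qs$slot1)],
                                st$Lmain[cbind(qs$two, qs$slot2[qs$two])])
      out$interaction[keep_ptr, ] <- st$int_val[qs$two]
      out$gamma[keep_ptr, ] <- c(st$gamma0, st$gamma1)
      out$g[keep_ptr, ] <- st$G[cbind(glab$row, glab$col)]
      out$u[keep_ptr, ] <- interleave_u(st$u0, st$u1)
      if (store_alpha) out$alpha[keep_ptr, ] <- as.integer(st$alpha)
    }
  }

  rates <- list(
    l0 = acc$l0 / max(att$l0, 1), main = acc$main / max(att$main, 1),
    int = acc$int / max(att$int, 1), g0 = acc$g0 / max(att$g0, 1),
    g1 = acc$g1 / max(att$g1, 1),
    u = acc$u / pmax(att$u, 1), rc = acc$rc / pmax(att$rc, 1),
    uj = acc$uj / max(att$uj, 1)
  )
  c(out, list(accept = rates, clip_count = clip_count, step = step))
}

# symmetric-proposal MH prior log-ratio under a normal prior
dnorm_diff <- function(new, old, mean, sd) {
  (-(new - mean)^2 + (old - mean)^2) / (2 * sd^2)
}

# N x 2K matrix ordered (u0_A1, u1_A1, u0_A2, ...)
interleave_u <- function(u0, u1) {
  K <- ncol(u0)
  U <- matrix(0, nrow(u0), 2 * K)
  U[, seq(1, 2 * K, by = 2)] <- u0
  U[, seq(2, 2 * K, by = 2)] <- u1
  U
}

growth_logits <- function(st, dat) {
  RT <- dat$N * dat$T
  K <- ncol(st$u0)
  matrix(st$gamma0, RT, K, byrow = TRUE) + st$u0[dat$person, , drop = FALSE] +
    (matrix(st$gamma1, RT, K, byrow = TRUE) +
       st$u1[dat$person, , drop = FALSE]) * dat$time
}

#' @export
print.ldcm_fit <- function(x, ...) {
  cat("<ldcm_fit>\n")
  cat(sprintf("  %d persons x %d occasions x %d items, %d attributes\n",
              x$meta$N, x$meta$T, x$meta$I, x$meta$K))
  cat(sprintf("  %d chain(s) x %d iterations (%d burn-in, thin %d): %d kept draws\n",
              x$config$chains, x$config$iter, x$config$burnin, x$config$thin,
              dim(x$draws$lambda0)[2]))
  invisible(x)
}

#' Posterior mastery probabilities
#'
#' The posterior probability that each person masters each attribute at each
#' occasion: the mean of the sampled mastery indicators across chains and
#' post-burn-in iterations.
#'
#' @param fit An `ldcm_fit` with stored mastery draws.
#' @return A tibble with columns `person`, `occasion`, `attribute`,
#'   `probability`.
#' @export
posterior_mastery_probability <- function(fit) {
  if (is.null(fit$draws$alpha)) {
    abort("Mastery draws were not stored (`store_alpha = FALSE`).")
  }
  a <- fit$draws$alpha
  if (length(a) == 0) abort("Empty sample set.")
  prob <- colMeans(matrix(as.numeric(a), prod(dim(a)[1:2]), dim(a)[3]))
  m <- fit$meta
  tibble::tibble(
    person = rep(m$persons[m$person], times = m$K),
    occasion = rep(m$occasions[m$occasion], times = m$K),
    attribute = rep(m$attrs, each = m$N * m$T),
    probability = prob
  ) |>
    dplyr::arrange(.data$person, .data$occasion, .data$attribute)
}

#' Classify mastery from posterior probabilities
#'
#' A status of 1 (mastery) is assigned when the probability is *strictly*
#' greater than the cutpoint (default 0.5); ties go to non-mastery.
#'
#' @param prob Numeric probabilities in \[0, 1\], or a data frame with a
#'   `probability` column (a `status` column is appended).
#' @param cutpoint Classification cutpoint in \[0, 1\].
#' @return An integer 0/1 vector, or the data frame with `status` added.
#' @export
#' @examples
#' classify(c(0.49, 0.50, 0.51))
classify <- function(prob, cutpoint = 0.5) {
  if (is.data.frame(prob)) {
    prob$status <- classify(prob$probability, cutpoint)
    return(prob)
  }
  if (any(prob < 0 | prob > 1, na.rm = TRUE)) {
    abort("Probabilities must lie in [0, 1].")
  }
  as.integer(prob > cutpoint)
}

draw_matrix <- function(arr, j) {
  # chains x nkeep x P array -> nkeep x chains matrix for parameter j
  m <- arr[, , j, drop = FALSE]
  dim(m) <- dim(arr)[1:2]
  t(m)
}

#' Per-parameter convergence diagnostics for a fit
#'
#' Computes the Gelman-Rubin diagnostic for every item parameter, growth fixed
#' effect and G element (see [gelman_rubin()]).
#'
#' @param fit An `ldcm_fit` with at least two chains.
#' @param psrf_sqrt Use the square-root convention (see [gelman_rubin()]).
#' @return A tibble with columns `term`, `block`, `rhat`.
#' @export
rhat_summary <- function(fit, psrf_sqrt = FALSE) {
  blocks <- list(
    lambda0 = fit$labels$lambda0,
    main = fit$labels$main,
    interaction = fit$labels$interaction,
    gamma = fit$labels$gamma,
    g = fit$labels$g$labels
  )
  purrr::imap(blocks, function(lab, bl) {
    if (length(lab) == 0) return(NULL)
    arr <- fit$draws[[bl]]
    if (dim(arr)[1] == 1) {
      abort("Convergence diagnostics require >= 2 chains.")
    }
    tibble::tibble(
      term = lab, block = bl,
      rhat = vapply(seq_along(lab), function(j) {
        gelman_rubin(draw_matrix(arr, j), psrf_sqrt = psrf_sqrt)
      }, 1)
    )
  }) |> dplyr::bind_rows()
}

#' @describeIn fit_ldcm Tidy posterior summary: one row per model parameter
#'   with posterior mean, SD, central quantiles and (for multi-chain fits) the
#'   Gelman-Rubin diagnostic.
#' @param x An `ldcm_fit`.
#' @param ... Unused.
#' @export
tidy.ldcm_fit <- function(x, ...) {
  blocks <- list(
    lambda0 = x$labels$lambda0,
    main = x$labels$main,
    interaction = x$labels$interaction,
    gamma = x$labels$gamma,
    g = x$labels$g$labels
  )
  multi <- x$config$chains >= 2
  purrr::imap(blocks, function(lab, bl) {
    if (length(lab) == 0) return(NULL)
    arr <- x$draws[[bl]]
    flat <- matrix(arr, prod(dim(arr)[1:2]), dim(arr)[3])
    qs <- t(apply(flat, 2, quantile, probs = c(0.025, 0.5, 0.975)))
    tibble::tibble(
      term = lab, block = bl,
      estimate = colMeans(flat),
      std.error = apply(flat, 2, stats::sd),
      conf.low = qs[, 1], median = qs[, 2], conf.high = qs[, 3],
      rhat = if (multi) {
        vapply(seq_along(lab), function(j) gelman_rubin(draw_matrix(arr, j)), 1)
      } else NA_real_
    )
  }) |> dplyr::bind_rows()
}

#' @describeIn fit_ldcm One-row model-level summary: dimensions, sampler
#'   settings, maximum Gelman-Rubin diagnostic and the convergence verdict at
#'   the 1.2 threshold.
#' @export
glance.ldcm_fit <- function(x, ...) {
  rh <- if (x$config$chains >= 2) rhat_summary(x)$rhat else NA_real_
  tibble::tibble(
    n_persons = x$meta$N, n_occasions = x$meta$T, n_items = x$meta$I,
    n_attributes = x$meta$K, chains = x$config$chains,
    iter = x$config$iter, burnin = x$config$burnin,
    max_rhat = if (all(is.na(rh))) NA_real_ else max(rh),
    converged = if (all(is.na(rh))) NA else replication_converged(rh)
  )
}
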