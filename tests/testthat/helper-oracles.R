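# Independent oracles used across the suite.

# Brute-force LCDM probability for a single item: build the logit term by term
# from the tidy parameter table, without touching the package's compiled path.
brute_force_prob <- function(params, qmatrix, item, profile) {
  attrs <- setdiff(names(qmatrix), "item")
  p <- params[params$item == item, ]
  eta <- p$value[p$parameter_type == "intercept"]
  for (r in which(p$parameter_type == "main")) {
    k <- match(p$attributes[r], attrs)
    eta <- eta + p$value[r] * profile[k]
  }
  for (r in which(p$parameter_type == "interaction")) {
    ks <- match(strsplit(p$attributes[r], ":")[[1]], attrs)
    eta <- eta + p$value[r] * prod(profile[ks])
  }
  1 / (1 + exp(-eta))
}

# Population-marginal mastery proportion at a fixed time: E[logistic(mu + s Z)]
# with Z standard normal, by adaptive quadrature (the 1-D logistic-normal
# integral; the random part u0 + u1 * t is univariate normal).
marginal_mastery_oracle <- function(gamma00, gamma10, time, g_block) {
  mu <- gamma00 + gamma10 * time
  s2 <- g_block[1, 1] + 2 * time * g_block[1, 2] + time^2 * g_block[2, 2]
  if (s2 <= 0) return(plogis(mu))
  s <- sqrt(s2)
  stats::integrate(function(z) plogis(mu + s * z) * dnorm(z),
                   lower = -10, upper = 10, rel.tol = 1e-10)$value
}

# 2x2-attribute block of G for attribute k (intercept & slope rows)
g_block_for <- function(g, k) {
  idx <- c(2 * k - 1, 2 * k)
  g[idx, idx]
}

# Hand-rolled exact Bernoulli full conditional for one person-occasion's
# mastery indicator given fixed item and growth parameters (single attribute).
alpha_full_conditional <- function(responses, intercepts, mains, prior_logit) {
  l1 <- sum(responses * log(plogis(intercepts + mains)) +
              (1 - responses) * log(1 - plogis(intercepts + mains)))
  l0 <- sum(responses * log(plogis(intercepts)) +
              (1 - responses) * log(1 - plogis(intercepts)))
  plogis(prior_logit + (l1 - l0))
}
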