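---
title: "Measuring growth in attribute mastery: model, simulator and sampler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring growth in attribute mastery: model, simulator and sampler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longdcm)
```

## The model

`longdcm` implements a multivariate longitudinal diagnostic classification
model: a measurement model that classifies respondents on `K` binary latent
skills ("attributes") at each of `T` measurement occasions, joined to a
structural model that describes how each attribute's mastery probability
changes over continuous time.

**Measurement level (LCDM).** Given a Q-matrix assigning attributes to items,
the probability that person `r` answers item `i` correctly at occasion `t` is

$$
P(X_{irt}=1 \mid \alpha_{rt}) =
\mathrm{logit}^{-1}\!\Big(\lambda_{i,0}
 + \sum_k \lambda_{i,1,(k)}\, \alpha_{rtk} q_{ik}
 + \sum_{k<k'} \lambda_{i,2,(k,k')}\, \alpha_{rtk}\alpha_{rtk'} q_{ik}q_{ik'}\Big),
$$

the log-linear cognitive diagnosis model: an intercept (the log-odds of a
correct answer with no mastered attribute), main effects for each measured and
mastered attribute, and a two-way interaction when both attributes of a
two-attribute item are mastered. Main effects are constrained nonnegative and
interactions bounded below by `-min` of their pair's main effects, so mastery
never lowers the success probability; these constraints identify the model
(and prevent label switching in estimation), which is why they are imposed at
the type level even though they can be disabled for research use. Setting the
main effects of a multi-attribute item to zero recovers DINA-type all-or-none
behaviour (`reduce_to_dina()`). Items measuring three or more attributes are
out of scope: the packaged Q-matrix caps items at two attributes, and no
three-way interaction terms are implemented.

**Structural level (multivariate logistic growth).** Each attribute's mastery
indicator follows a logistic random-intercept/random-slope trajectory in
continuous time,

$$
\mathrm{logit}\, P(\alpha_{rtk}=1) =
(\gamma_{00k} + u_{0rk}) + (\gamma_{10k} + u_{1rk})\,\mathrm{Time}_{rt},
$$

with the `2K` person-level deviations jointly multivariate normal,
$(u_{0r1}, u_{1r1}, \dots) \sim \mathrm{MVN}(0, G)$. Because each attribute
has its own intercept and slope, attributes may grow at different rates (or
not at all), and because time enters as a per-person continuous score, the
model handles unbalanced designs where people are tested in different weeks.
The equivalent "stacked" single-equation form, in which attribute dummies
select the intercept/slope pair (`stacked_dummy_predictor()`), is provided and
tested to be algebraically identical.

A note on the level-2 residual: in the latent-response formulation of a
logistic model the residual variance is the fixed logistic variance
$\pi^2/3$. We read that as the variance *implied* by the Bernoulli-with-logit
link, so neither the generator nor the likelihood adds an explicit normal
residual — adding one would double-count. An experimental
`explicit_residual` flag on `simulate_mastery()` produces the
double-counting variant for sensitivity analysis only.

Random effects are ordered (intercept, slope) within attribute —
`u0_A1, u1_A1, u0_A2, ...` — everywhere: in `G`, in CSV fixtures, and in
posterior outputs. Latent classes are enumerated with attribute 1 as the
fastest-varying bit, so class 1 is the all-zero profile and class 2 masters
attribute 1 only; fixing this canonical order keeps posterior outputs
comparable across runs.

## What the simulator emulates

`simulation_design()` + `simulate_ldcm()` generate data from the factorial
study the package is built around:

* **Q-matrix** (`qmatrix_design()`): 30 items, 3 attributes, complex
  structure — each attribute measured by 15 items, each item measuring one or
  two attributes.
* **Item parameters**: intercept −1.5, main effects 1.5, interactions 0.5,
  i.e. correct-response probabilities 0.18 / 0.50 / 0.88 for none / one /
  both attributes mastered.
* **Growth**: initial levels −1.38, −1.10, −0.85 (base-rates ≈ 0.20, 0.25,
  0.30, mimicking hard, medium-hard and medium skills) with weekly log-odds
  slopes (0.05, 0.04, 0.05) in the `even` pattern or (0, 0.04, 0.05) in the
  `uneven` pattern.
* **G**: intercept variance 0.15 and slope variance 0.05 per attribute, with
  an `equal`-correlation condition (all attributes correlated alike,
  intercept–intercept 0.90) and an `unequal` condition in which attribute 1
  decouples from the others.
* **Time**: occasion means 0, 8, 16, 24, 32 weeks (interim-assessment
  spacing) with per-person SD 1. The distribution family is not dictated by
  the design, so Normal is assumed and documented here. Time scores are drawn
  independently across occasions without enforcing monotonicity: with 8-week
  gaps and SD 1 a crossing has probability ~1e−8, and a validation warning
  fires if one ever occurs.

Two properties of the generator deserve emphasis because they shape what
passing tests mean:

1. **Conditional-at-mean vs marginal.** `mean_trajectory()` evaluates the
   logistic at the fixed effects with random effects zeroed — the trajectory
   of the *average person*. The population-marginal mastery proportion is the
   integral of the logistic over MVN random effects, which is attenuated
   toward 0.5 (Jensen's inequality). At time 0 the gap is < 0.01; by week 32
   the slope variance contributes `32² × 0.05 ≈ 51` to the logit variance and
   the gap is substantial. Simulator tests therefore validate empirical
   proportions against a 1-D logistic-normal quadrature oracle, *not* against
   the at-mean trajectory; the at-mean table is recovered exactly only in the
   degenerate `G = 0`, `time_sd = 0` design. A corollary: under the `uneven`
   pattern, attribute 1's *average-person* trajectory is flat while its
   marginal proportion still drifts toward 0.5 with time.
2. **What the generator does not emulate.** Responses are complete (no
   dropout or planned missingness), items are conditionally independent given
   mastery (no local dependence from item reuse across occasions), responses
   are binary, and growth is linear in time on the log-odds scale. Good
   simulator fidelity therefore says nothing about robustness to missingness,
   local dependence, polytomous scoring or nonlinear growth in real data.

## Estimation

`fit_ldcm()` runs a blocked Metropolis-within-Gibbs sampler:

1. **Mastery indicators** are drawn from their *exact* Bernoulli full
   conditionals: the LCDM likelihood ratio of the occasion's responses (only
   the items measuring the attribute contribute) plus the growth-model prior
   logit. This block is validated in the tests against a hand-computed
   closed-form oracle on a one-person instance.
2. **Item parameters** take per-item random-walk Metropolis steps inside the
   monotonicity region (proposals outside are rejected, which is valid for a
   truncated target under a symmetric proposal). Given the mastery
   indicators, items are independent, so all 30 items update in one
   vectorized sweep.
3. **Growth fixed effects and random effects** take random-walk steps on the
   Bernoulli mastery likelihood. Random effects update coordinate-wise across
   the `2K` effects (all persons vectorized), plus one joint per-person
   proposal along the Cholesky directions of `G` — the person-level posterior
   is dominated by the strongly correlated prior, so axis-aligned moves alone
   mix slowly — plus a recentering move that shifts a fixed effect and all
   its random effects in opposite directions (likelihood-invariant, accepted
   on the prior ratio) to break the `gamma`–`mean(u)` confounding.
4. **G** is conjugate: an inverse-Wishart full conditional given the random
   effects, sampled via `stats::rWishart` on the precision scale.

Step sizes adapt every 50 burn-in iterations toward a 20–45% acceptance rate
and are frozen at the end of burn-in, preserving detailed balance in the
retained draws. Logits are clipped at ±35 (beyond which the logistic is 1 to
machine precision) before Bernoulli draws, with a warning if clipping fired.
All randomness flows from one `seed`; chains run sequentially from a single
stream, and with `init = "heuristic"` chains beyond the first are jittered
for dispersed starts.

**Priors.** Defaults: intercepts `N(0, 2²)`; main effects `N(0, 2²)`
truncated to ≥ 0; interactions `N(0, 2²)` truncated to the monotonicity
region; fixed effects `N(0, 10²)`; `G ~ IW(KP + 2, I)`. For replication runs
`prior_spec(g_center = ...)` centers the inverse-Wishart *mean* on a supplied
matrix (scale `= center × (df − KP − 1)`); the replication presets use
`df = KP + 20`, chosen once as "worth about 20 pseudo-persons" of prior
information — an informative but not dogmatic rendering of using the known
generating covariance as prior knowledge. Whether `G` should be sampled
freely or partially fixed is genuinely open; both the free default and the
centered mode are provided, and neither is claimed to match any particular
external implementation.

**Initialization.** `"heuristic"` starts mastery at a response-score rule
(share of correct answers on the attribute's items ≥ 0.5), item parameters at
generic values, fixed effects at crude logit-rate estimates, and random
effects at a draw from their prior (a zero start makes the `G` block climb
out of a degenerate corner). `"random"` gives fully dispersed starts;
`"truth"` starts at the generating values and exists for oracle tests and
smoke runs only.

**Known limitation.** At desk-scale chain lengths (2 × 1500) the
slowest-mixing parameters are the covariances of `G`, which the binary
mastery data identify only weakly; their `R-hat` can sit above 1.2 while
every item and fixed-effect parameter is well below it. Longer chains (the
`full` study preset uses 3 × 4000) resolve this; reproducing any
particular convergence *rate* is explicitly not a goal, since it depends on
chain settings and priors.

## Evaluation criteria

`gelman_rubin()` implements the variance-ratio potential scale reduction
factor literally as
$\hat R = (n-1)/n + B/(nW)$ with $B = n \times \mathrm{var}(\text{chain
means})$ and $W$ the mean within-chain variance; a `psrf_sqrt` flag returns
the square-root convention, and the 1.2 threshold applies to whichever
convention is selected. A replication counts as converged only if every
monitored parameter is below the threshold (`replication_converged()`), and
`run_condition()` keeps only converged replications in its summaries while
reporting the convergence rate.

Classification accuracy is summarized per attribute and occasion by
`classification_report()`: the bias of the estimated mastery probability
against the *generating* probability (the logistic of the person's true
linear predictor — the only reading under which near-zero biases are
well-defined), correct classification rates conditional on true status, and
Cohen's kappa, reported as missing whenever either status has a single
observed level. Classification applies a strict `> 0.5` cutpoint to the
posterior mean of the sampled mastery indicators; the boundary value 0.5
classifies as non-mastery.

Parameter recovery uses `bias()` and `mse()` pooled over the elements of a
parameter set and over replications, and the factorial ANOVA
(`anova_partial_eta2()`, built on `stats::aov` with a balanced-design
sum-of-squares decomposition — the simulation grid is balanced, so no
Type-III machinery) reports partial $\eta^2$ per design-factor term at the
conventional 0.01 / 0.06 / 0.14 cutoffs. The ANOVA runs on
replication-level outcomes (one observation per cell × replication), not on
cell means. Summary CSVs keep probability biases at full precision rather
than adopting a print convention that blanks near-zero entries; rounding is
left to presentation.

## Problem sizes and numerical choices

The package's own desk-scale settings, used by its tests and by
`scripts/acceptance.R`, are: 2–3 replications of the `N = 200`, five-occasion,
equal-correlation, even-growth condition with 2 chains × 1500 iterations
(750 burn-in) and the truth-centered `G` prior; recovery checks run two
replications each at `N = 300` and `N = 100` with the same chain settings;
simulator-fidelity checks use 20,000 persons. These sizes were chosen so the
whole evaluation runs on a single CPU in minutes while the Monte-Carlo error
stays well inside the tolerances being asserted; the full factorial grid with
100 replications per cell (`study_grid()` defaults) is the faithful
large-scale configuration.

Other numerical choices: time-centering at the medial occasion is available
via `fit_ldcm(center_time = TRUE)` (off by default to match the simulation
design; recommended when intercept recovery matters, since a small intercept
far from the data's center of mass is harder to pin down — the reported
intercepts then refer to the medial occasion); degenerate inputs are handled
explicitly
(all-constant chains return the `(n−1)/n` floor of $\hat R$; constant-outcome
ANOVAs return all-zero effect sizes; a zero `G` in oracle runs falls back to
a pseudo-inverse); and ties at the classification cutpoint go to non-mastery
by the strict inequality.

## A worked run

```{r example, eval = FALSE}
design <- simulation_design(n_persons = 200, growth_pattern = "even",
                            g_condition = "equal", n_occasions = 5, seed = 1)
data <- simulate_ldcm(design)
autoplot(data)

priors <- prior_spec(g_center = design$g, g_df = nrow(design$g) + 20)
fit <- fit_ldcm(data, chains = 2, iter = 1500, burnin = 750,
                priors = priors, seed = 1)
tidy(fit)
glance(fit)

posterior_mastery_probability(fit) |>
  dplyr::inner_join(data$mastery, by = c("person", "occasion", "attribute"),
                    suffix = c("", "_true")) |>
  classification_report(true_prob = probability_true)
```
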