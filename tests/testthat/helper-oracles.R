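# Independent oracles and tiny fixture builders shared across tests.

# Build a cohort_table from a compact spec; unspecified schema covariates
# default to 0 so tiny fixtures stay readable.
toy_cohort <- function(..., schema = default_schema(), validate = TRUE) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  if (is.null(df$subject_id)) df$subject_id <- sprintf("s%02d", seq_len(nrow(df)))
  if (is.null(df$source)) df$source <- "trial_1"
  if (is.null(df$arm)) df$arm <- "none"
  for (nm in setdiff(schema_names(schema), names(df))) {
    # unspecified covariates default to the bottom of their allowed range
    lo <- schema$covariates$lo[match(nm, schema$covariates$name)]
    df[[nm]] <- max(lo, 0)
  }
  cohort_table(df, schema = schema, validate = validate)
}

# Brute-force logistic MLE: direct minimization of the negative
# log-likelihood, independent of glm's IRLS path.
oracle_logistic_mle <- function(X, y) {
  X <- cbind(1, as.matrix(X))
  nll <- function(b) {
    eta <- as.vector(X %*% b)
    sum(log1p(exp(eta))) - sum(y * eta)
  }
  grad <- function(b) {
    p <- stats::plogis(as.vector(X %*% b))
    as.vector(t(X) %*% (p - y))
  }
  b <- stats::optim(rep(0, ncol(X)), nll, grad, method = "BFGS",
                    control = list(maxit = 2000, reltol = 1e-15))$par
  # Newton polish to machine precision
  for (i in 1:50) {
    p <- stats::plogis(as.vector(X %*% b))
    H <- t(X) %*% (X * (p * (1 - p)))
    step <- solve(H, t(X) %*% (p - y))
    b <- b - as.vector(step)
    if (max(abs(step)) < 1e-13) break
  }
  b
}

# Hand-written weighted Cox log partial likelihood (Breslow form; fixtures
# use distinct event times, where Breslow and Efron coincide), maximized
# by direct search.
oracle_cox_loglik <- function(beta, time, event, x, w = rep(1, length(time))) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + w[i] * (beta * x[i] -
                         log(sum(w[risk] * exp(beta * x[risk]))))
  }
  ll
}

oracle_cox_mle <- function(time, event, x, w = rep(1, length(time))) {
  stats::optimize(function(b) oracle_cox_loglik(b, time, event, x, w),
                  interval = c(-10, 10), maximum = TRUE,
                  tol = 1e-10)$maximum
}

# 2x2 chi-square statistic from first principles (no continuity correction)
oracle_chisq_2x2 <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

# Minimal homogeneous exponential scenario: constant hazard `rate` for
# controls, proportional hazards `hr` for treated, no covariate effects.
exp_scenario <- function(rate = 0.1, hr = 1, horizon = 100,
                         dropout = 0, n = 1000, seed = 1L) {
  m <- paper_like_trial_marginals()
  scenario_spec(
    sources = list(trial_1 = list(marginals = m, corr = paper_like_corr())),
    treatment = list(trial_1 = list(type = "randomized")),
    outcome = list(baseline = list(trial_1 = list(shape = 1, scale = 1 / rate)),
                   beta_treat = log(hr), modifiers = list(),
                   coefficients = list()),
    censoring = list(trial_1 = list(horizon = horizon,
                                    dropout_rate = dropout)),
    n = c(trial_1 = n), seed = seed)
}

# tree mirroring the discovered structure: prior event at the root, then
# age at 71 among subjects without a prior event
fig_tree <- function(schema = default_schema()) {
  reference_subgroup_tree(71, schema)
}

make_exp_cohort <- function(rate = 0.1, hr = 1, horizon = 100, dropout = 0,
                            n = 1000, seed = 1L) {
  sp <- exp_scenario(rate, hr, horizon, dropout, n, seed)
  generate_scenario(sp, seed = seed)$trials$trial_1
}
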