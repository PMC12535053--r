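#' Deterministic seed derivation for named substreams
#'
#' Every random stage of a scenario (covariate sampling per source,
#' treatment assignment, outcome simulation, splitting, bootstrapping)
#' draws its seed from one master seed and a stage label, via a
#' Lehmer-style congruential mix modulo 2^31 - 1. Inserting a stage never
#' reshuffles the streams of other stages.
#'
#' @param master integer master seed.
#' @param label character stage label, e.g. `"trial_1/covariates"`.
#' @return integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(master, label) {
  u <- utf8ToInt(label)
  h <- sum(u * seq_along(u)) %% 2147483647
  as.integer(((as.numeric(master) %% 2147483647) * 16807 + h * 69621) %%
               2147483647)
}

rule_vars_ok <- function(rule, schema) {
  vars <- all.vars(parse(text = rule)[[1]])
  all(vars %in% schema_names(schema))
}

eval_rule <- function(rule, data) {
  v <- eval(parse(text = rule)[[1]], envir = as.data.frame(data))
  as.numeric(v)
}

#' Specify a synthetic multi-source scenario
#'
#' A `scenario_spec` fully determines a reproducible bundle of cohorts:
#' per-source covariate marginals joined by a Gaussian copula, randomized or
#' confounded treatment assignment, a Weibull proportional-hazards outcome
#' with subgroup-specific treatment effects, and administrative plus
#' exponential-dropout censoring.
#'
#' @param sources named list; each element describes one source label and
#'   has `marginals` (data.frame with columns `name`, and `mean`,`sd` for
#'   continuous or `prev` for binary covariates) and optional `corr`
#'   (data.frame `v1`,`v2`,`rho` of latent-scale correlations).
#' @param treatment named list per longitudinal source: either
#'   `list(type = "randomized")` (P(treated) = 0.5) or
#'   `list(type = "confounded", intercept =, coefficients = named numeric)`.
#'   Sources absent from this list stay cross-sectional (arm `"none"`).
#' @param outcome list with `baseline` (named per-source
#'   `list(shape =, scale =)` Weibull parameters), `beta_treat` (log hazard
#'   ratio of treatment), `modifiers` (list of `list(rule =, log_hr =)` extra
#'   treatment log-HRs for subjects satisfying `rule`), `coefficients`
#'   (list of `list(rule =, beta =)` prognostic log-hazard terms). Rules are
#'   R expressions over schema covariates, e.g.
#'   `"(prior_mi_stroke == 0) & (age > 71)"`.
#' @param censoring named per-source `list(horizon =, dropout_rate =)`:
#'   administrative horizon in years and exponential dropout rate per year.
#' @param n named integer vector of default sample sizes per source.
#' @param schema `covariate_schema`; continuous draws are clamped into the
#'   schema's allowed range.
#' @param seed default master seed.
#' @return validated object of class `scenario_spec`.
#' @export
scenario_spec <- function(sources, treatment, outcome, censoring, n,
                          schema = default_schema(), seed = 1L) {
  spec <- structure(list(sources = sources, treatment = treatment,
                         outcome = outcome, censoring = censoring,
                         n = n, schema = schema, seed = seed),
                    class = "scenario_spec")
  validate_scenario_spec(spec)
  spec
}

validate_scenario_spec <- function(spec) {
  schema <- spec$schema
  for (lab in names(spec$sources)) {
    src <- spec$sources[[lab]]
    m <- src$marginals
    stopifnot(is.data.frame(m), all(m$name %in% schema_names(schema)))
    kinds <- schema_kind(schema, m$name)
    bin <- m[kinds == "binary", , drop = FALSE]
    if (nrow(bin) && (any(bin$prev < 0) || any(bin$prev > 1)))
      stop("prevalences must lie in [0,1] (source ", lab, ")")
    cont <- m[kinds == "continuous", , drop = FALSE]
    if (nrow(cont) && any(cont$sd < 0))
      stop("continuous SDs must be >= 0 (source ", lab, ")")
    R <- latent_corr_matrix(src, m$name)
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop("latent correlation matrix for source ", lab,
           " is not positive semi-definite")
  }
  for (b in spec$outcome$baseline)
    if (b$shape <= 0 || b$scale <= 0)
      stop("Weibull shape and scale must be > 0")
  rules <- c(vapply(spec$outcome$modifiers, `[[`, "", "rule"),
             vapply(spec$outcome$coefficients, `[[`, "", "rule"))
  for (r in rules)
    if (!rule_vars_ok(r, schema))
      stop("outcome rule references non-schema covariates: ", r)
  invisible(spec)
}

latent_corr_matrix <- function(src, names) {
  p <- length(names)
  R <- diag(p)
  dimnames(R) <- list(names, names)
  if (!is.null(src$corr) && nrow(src$corr)) {
    for (i in seq_len(nrow(src$corr))) {
      a <- src$corr$v1[i]; b <- src$corr$v2[i]
      if (!(a %in% names && b %in% names))
        stop("correlation entry references unknown covariate: ", a, "/", b)
      R[a, b] <- R[b, a] <- src$corr$rho[i]
    }
  }
  R
}

#' Generate baseline covariates for one source
#'
#' Draws a latent multivariate Gaussian with the source's correlation
#' structure, then maps each coordinate to its marginal: continuous
#' covariates by location-scale (clamped to the schema range), binary flags
#' by thresholding at the normal quantile of the prevalence.
#'
#' @param spec a `scenario_spec`.
#' @param source source label present in `spec$sources`.
#' @param n number of subjects.
#' @param seed integer seed; same seed reproduces the table exactly.
#' @return a cross-sectional `cohort_table` (arm `"none"`, no time/event).
#' @export
generate_covariates <- function(spec, source, n,
                                seed = derive_seed(spec$seed,
                                                   paste0(source, "/covariates"))) {
  if (!source %in% names(spec$sources))
    stop("source '", source, "' has no marginals in the spec")
  schema <- spec$schema
  m <- spec$sources[[source]]$marginals
  R <- latent_corr_matrix(spec$sources[[source]], m$name)
  ev <- eigen(R, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(R))
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * nrow(R)), n) %*% t(L)
  colnames(Z) <- m$name
  df <- data.frame(subject_id = paste0(source, "_", seq_len(n)),
                   source = source, arm = "none",
                   stringsAsFactors = FALSE)
  for (j in seq_len(nrow(m))) {
    nm <- m$name[j]
    k <- schema_kind(schema, nm)
    if (k == "continuous") {
      i <- match(nm, schema_names(schema))
      lo <- schema$covariates$lo[i]; hi <- schema$covariates$hi[i]
      df[[nm]] <- pmin(pmax(m$mean[j] + m$sd[j] * Z[, nm], lo), hi)
    } else {
      df[[nm]] <- as.numeric(Z[, nm] < stats::qnorm(m$prev[j]))
    }
  }
  # schema covariates not mentioned in the marginals default to 0
  for (nm in setdiff(schema_names(schema), m$name)) df[[nm]] <- 0
  cohort_table(df, schema = schema)
}

#' Assign treatment arms
#'
#' Randomized assignment (P(treated) = 0.5, independent of covariates) for
#' trial emulation, or confounded assignment through a logistic model on
#' covariates for new-user cohort emulation.
#'
#' @param cohort a cross-sectional `cohort_table` (arm all `"none"`).
#' @param mode `list(type = "randomized")` or `list(type = "confounded",
#'   intercept =, coefficients = named numeric over schema covariates)`.
#' @param seed integer seed.
#' @return the cohort with `arm` set to `"treated"`/`"control"` (not yet
#'   carrying outcomes, so not validated until outcomes are simulated).
#' @export
assign_treatment <- function(cohort, mode, seed) {
  if (any(cohort$arm != "none"))
    stop("arm already assigned for some subjects")
  schema <- cohort_schema(cohort)
  set.seed(seed)
  n <- nrow(cohort)
  if (identical(mode$type, "randomized")) {
    p <- rep(0.5, n)
  } else if (identical(mode$type, "confounded")) {
    bad <- setdiff(names(mode$coefficients), schema_names(schema))
    if (length(bad))
      stop("confounding coefficients reference unknown covariate(s): ",
           paste(bad, collapse = ", "))
    lp <- rep(mode$intercept, n)
    for (nm in names(mode$coefficients))
      lp <- lp + mode$coefficients[[nm]] * cohort[[nm]]
    p <- stats::plogis(lp)
  } else stop("mode$type must be 'randomized' or 'confounded'")
  cohort$arm <- ifelse(stats::runif(n) < p, "treated", "control")
  cohort
}

#' Simulate Weibull proportional-hazards outcomes
#'
#' Event times are drawn by inverse-transform sampling from
#' S(t | x) = exp(-(t/scale)^shape * m(x)), where the hazard multiplier is
#' m(x) = exp(sum of prognostic rule terms + treated * (beta_treat + sum of
#' modifier rule terms)). Observed time is the minimum of the event time,
#' an exponential dropout time, and the administrative horizon; the event
#' indicator is 1 iff the event time comes first.
#'
#' @param cohort a `cohort_table` with arms assigned.
#' @param spec a `scenario_spec` holding `outcome$baseline[[source]]` and
#'   `censoring[[source]]` for this cohort's source.
#' @param seed integer seed.
#' @return validated `cohort_table` with `time` and `event` filled in.
#' @export
simulate_survival <- function(cohort, spec, seed) {
  if (any(cohort$arm == "none"))
    stop("assign treatment before simulating outcomes")
  src <- cohort$source[1]
  base <- spec$outcome$baseline[[src]]
  cens <- spec$censoring[[src]]
  if (is.null(base) || is.null(cens))
    stop("no outcome/censoring parameters for source '", src, "'")
  n <- nrow(cohort)
  lp <- rep(0, n)
  for (term in spec$outcome$coefficients)
    lp <- lp + term$beta * eval_rule(term$rule, cohort)
  treated <- as.numeric(cohort$arm == "treated")
  eff <- rep(spec$outcome$beta_treat, n)
  for (term in spec$outcome$modifiers)
    eff <- eff + term$log_hr * eval_rule(term$rule, cohort)
  m <- exp(lp + treated * eff)
  set.seed(seed)
  u <- stats::runif(n)
  t_event <- base$scale * (-log(u) / m)^(1 / base$shape)
  t_drop <- if (cens$dropout_rate > 0)
    stats::rexp(n, cens$dropout_rate) else rep(Inf, n)
  t_obs <- pmin(t_event, t_drop, cens$horizon)
  cohort$event <- as.numeric(t_event <= pmin(t_drop, cens$horizon))
  cohort$time <- pmax(t_obs, 1e-8)  # guard against underflow at time 0
  validate_cohort(cohort)
  cohort
}

paper_like_trial_marginals <- function() {
  data.frame(
    name = c("age", "bmi", "hba1c", "diabetes_duration", "egfr",
             "sex_male", "prior_mi_stroke", "prior_cvd", "heart_failure",
             "hypertension", "pad", "metformin", "sulphonylurea", "insulin",
             "statin", "antiplatelet", "ras_blocker", "beta_blocker",
             "diuretic", "ccb", "dpp4i"),
    mean = c(66, 32.5, 8.7, 13, 80, rep(NA, 16)),
    sd   = c(7, 6, 1.5, 5.5, 20, rep(NA, 16)),
    prev = c(rep(NA, 5), 0.64, 0.55, 0.72, 0.17, 0.90, 0.12, 0.76, 0.50,
             0.44, 0.72, 0.65, 0.82, 0.55, 0.40, 0.32, 0.05),
    stringsAsFactors = FALSE)
}

paper_like_target_marginals <- function() {
  data.frame(
    name = c("age", "bmi", "hba1c", "diabetes_duration", "egfr",
             "sex_male", "prior_mi_stroke", "prior_cvd", "heart_failure",
             "hypertension", "pad", "metformin", "sulphonylurea", "insulin",
             "statin", "antiplatelet", "ras_blocker", "beta_blocker",
             "diuretic", "ccb", "dpp4i"),
    mean = c(70.5, 29.5, 7.7, 10, 75, rep(NA, 16)),
    sd   = c(10.7, 5, 1.2, 5.5, 21, rep(NA, 16)),
    prev = c(rep(NA, 5), 0.57, 0.15, 0.25, 0.08, 0.74, 0.07, 0.72, 0.30,
             0.25, 0.55, 0.35, 0.60, 0.35, 0.28, 0.25, 0.12),
    stringsAsFactors = FALSE)
}

paper_like_corr <- function() {
  data.frame(
    v1  = c("prior_mi_stroke", "prior_cvd", "prior_cvd", "age",
            "hypertension", "diabetes_duration", "age"),
    v2  = c("prior_cvd", "statin", "antiplatelet", "egfr",
            "ras_blocker", "insulin", "diabetes_duration"),
    rho = c(0.6, 0.3, 0.4, -0.35, 0.4, 0.35, 0.3),
    stringsAsFactors = FALSE)
}

# Baseline hazards calibrated so the 3.6-year control risks of the three
# subgroups (prior event; no prior event & age > 71; no prior event &
# age <= 71) are 0.16 / 0.096 / 0.054 under a constant hazard (shape 1):
# rate_C = -log(1 - 0.054)/3.6, multipliers log(3.141) and log(1.819).
paper_like_outcome <- function(beta_treat = log(0.85),
                               modifiers = list(
                                 list(rule = "(prior_mi_stroke == 0) & (age > 71)",
                                      log_hr = log(0.55 / 0.85)),
                                 list(rule = "(prior_mi_stroke == 0) & (age <= 71)",
                                      log_hr = log(0.95 / 0.85)))) {
  rate_C <- -log(1 - 0.054) / 3.6
  list(
    baseline = list(trial_1 = list(shape = 1, scale = 1 / rate_C),
                    trial_2 = list(shape = 1, scale = 1 / rate_C),
                    rw      = list(shape = 1, scale = 1 / (1.4 * rate_C))),
    beta_treat = beta_treat,
    modifiers = modifiers,
    coefficients = list(
      list(rule = "prior_mi_stroke",
           beta = log(-log(1 - 0.16) / -log(1 - 0.054))),
      list(rule = "(prior_mi_stroke == 0) & (age > 71)",
           beta = log(-log(1 - 0.096) / -log(1 - 0.054)))))
}

#' Named scenario presets
#'
#' * `"paper_like"`: two trial sources (younger, high prior-CVD prevalence,
#'   higher HbA1c) versus an older real-world target with ~15% prior
#'   MI/stroke; three latent benefit subgroups — A: prior MI/stroke
#'   (HR 0.85), B: no prior event & age > 71 (HR 0.55), C: no prior event &
#'   age <= 71 (HR 0.95) — with 3.6-year control risks 0.16/0.096/0.054, and
#'   a confounded real-world new-user cohort sharing the subgroup structure.
#' * `"no_shift"`: trial and target identically distributed; homogeneous
#'   treatment effect HR 0.85.
#' * `"null_homogeneous"`: covariate shift as in `"paper_like"` but zero
#'   treatment effect and no effect modification.
#' * `"rw_validation"`: a single confounded new-user cohort with homogeneous
#'   true exposure HR 0.70, for matching-pipeline benchmarking.
#'
#' @param name preset name.
#' @param n optional named vector overriding default sample sizes
#'   (names among `trial_1`, `trial_2`, `target`, `rw`).
#' @param seed master seed stored in the spec.
#' @return a `scenario_spec`.
#' @export
scenario_preset <- function(name = c("paper_like", "no_shift",
                                     "null_homogeneous", "rw_validation"),
                            n = NULL, seed = 1L) {
  name <- match.arg(name)
  trial_m <- paper_like_trial_marginals()
  target_m <- paper_like_target_marginals()
  corr <- paper_like_corr()
  n_def <- c(trial_1 = 8800L, trial_2 = 3200L, target = 20000L, rw = 12000L)
  if (!is.null(n)) n_def[names(n)] <- n
  confounded <- list(
    type = "confounded", intercept = -2.27,
    coefficients = c(age = -0.03, prior_mi_stroke = 0.5, hba1c = 0.3,
                     insulin = -0.4, bmi = 0.05))
  cens <- list(trial_1 = list(horizon = 4.5, dropout_rate = 0.02),
               trial_2 = list(horizon = 4.5, dropout_rate = 0.02),
               rw = list(horizon = 8, dropout_rate = 0.33))
  sources <- list(trial_1 = list(marginals = trial_m, corr = corr),
                  trial_2 = list(marginals = trial_m, corr = corr),
                  target = list(marginals = target_m, corr = corr),
                  rw = list(marginals = target_m, corr = corr))
  treatment <- list(trial_1 = list(type = "randomized"),
                    trial_2 = list(type = "randomized"),
                    rw = confounded)
  outcome <- paper_like_outcome()
  if (name == "no_shift") {
    sources$target <- sources$trial_1
    outcome <- paper_like_outcome(beta_treat = log(0.85), modifiers = list())
  } else if (name == "null_homogeneous") {
    outcome <- paper_like_outcome(beta_treat = 0, modifiers = list())
  } else if (name == "rw_validation") {
    sources <- sources["rw"]
    treatment <- treatment["rw"]
    outcome <- paper_like_outcome(beta_treat = log(0.70), modifiers = list())
    outcome$baseline <- outcome$baseline["rw"]
    cens <- cens["rw"]
    n_def <- n_def["rw"]
  }
  scenario_spec(sources = sources, treatment = treatment, outcome = outcome,
                censoring = cens[names(sources)[names(sources) %in% names(cens)]],
                n = n_def, seed = seed)
}

#' Generate a full scenario bundle
#'
#' Runs covariate generation, treatment assignment, and outcome simulation
#' for every source of a spec under one master seed with one named
#' substream per source and stage.
#'
#' @param spec a `scenario_spec` or a preset name accepted by
#'   [scenario_preset()].
#' @param seed master seed (defaults to the spec's own).
#' @param n optional named override of per-source sample sizes.
#' @return list of class `scenario_bundle` with elements `trials` (list of
#'   trial cohorts), `target` (cross-sectional cohort or NULL), `rw`
#'   (longitudinal new-user cohort or NULL), and `spec`.
#' @export
generate_scenario <- function(spec, seed = NULL, n = NULL) {
  if (is.character(spec)) spec <- scenario_preset(spec)
  if (is.null(seed)) seed <- spec$seed
  sizes <- spec$n
  if (!is.null(n)) sizes[names(n)] <- n
  trials <- list(); target <- NULL; rw <- NULL
  for (src in names(spec$sources)) {
    cov <- generate_covariates(spec, src, sizes[[src]],
                               seed = derive_seed(seed, paste0(src, "/covariates")))
    if (src %in% names(spec$treatment)) {
      coh <- assign_treatment(cov, spec$treatment[[src]],
                              seed = derive_seed(seed, paste0(src, "/treatment")))
      coh <- simulate_survival(coh, spec,
                               seed = derive_seed(seed, paste0(src, "/outcome")))
      if (src == "rw") rw <- coh else trials[[src]] <- coh
    } else {
      target <- cov
    }
  }
  structure(list(trials = trials, target = target, rw = rw, spec = spec,
                 seed = seed),
            class = "scenario_bundle")
}

#' Stack the trial cohorts of a bundle into one table
#'
#' @param bundle a `scenario_bundle`.
#' @return a single `cohort_table` with the trial sources stacked.
#' @export
pooled_trials <- function(bundle) {
  stopifnot(length(bundle$trials) >= 1)
  df <- do.call(rbind, lapply(bundle$trials, as.data.frame))
  rownames(df) <- NULL
  cohort_table(df, schema = cohort_schema(bundle$trials[[1]]))
}
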