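#' Logistic-regression membership model
#'
#' Stacks a trial cohort on a target cohort and fits, by maximum
#' likelihood, a logistic regression of the probability of being a trial
#' member given baseline covariates. The fitted membership probabilities
#' for trial subjects feed the inverse-odds-of-sampling weights.
#'
#' @param trial,target `cohort_table`s with complete shared covariates.
#' @param covariates covariate names used in the model (default: every
#'   schema covariate with variation in the stacked data).
#' @return object of class `membership_model` with `method = "LR"`, the
#'   fitted `glm`, `covariates`, the stacked trial fraction, and `p_trial`
#'   (membership probability per trial subject, named by subject_id).
#' @export
fit_membership_lr <- function(trial, target,
                              covariates = schema_names(cohort_schema(trial))) {
  stacked <- stack_membership(trial, target, covariates)
  covariates <- stacked$covariates
  f <- stats::as.formula(paste("in_trial ~", paste(covariates, collapse = " + ")))
  fit <- stats::glm(f, data = stacked$data, family = stats::binomial())
  p <- stats::fitted(fit)
  eps <- 1e-8
  if (any(p > 1 - eps | p < eps)) {
    z <- abs(stats::coef(fit)[-1]) *
      vapply(stacked$data[covariates], stats::sd, 0)
    stop("(near-)perfect separation between trial and target; ",
         "largest standardized coefficient(s): ",
         paste(names(sort(z, decreasing = TRUE))[1:min(3, length(z))],
               collapse = ", "))
  }
  p_trial <- p[stacked$data$in_trial == 1]
  names(p_trial) <- trial$subject_id
  structure(list(method = "LR", fit = fit, covariates = covariates,
                 trial_fraction = mean(stacked$data$in_trial),
                 p_trial = p_trial),
            class = "membership_model")
}

stack_membership <- function(trial, target, covariates) {
  for (nm in covariates) {
    if (anyNA(trial[[nm]]) || anyNA(target[[nm]]))
      stop("covariate '", nm, "' has missing values; apply ",
           "complete_case_filter() first")
  }
  d <- rbind(
    data.frame(in_trial = 1, as.data.frame(trial)[, covariates, drop = FALSE]),
    data.frame(in_trial = 0, as.data.frame(target)[, covariates, drop = FALSE]))
  # drop covariates without variation (single observed level)
  keep <- vapply(d[covariates], function(v) length(unique(v)) > 1, TRUE)
  if (any(!keep))
    warning("dropping covariate(s) without variation: ",
            paste(covariates[!keep], collapse = ", "))
  list(data = d, covariates = covariates[keep])
}

#' Inverse odds of sampling weights
#'
#' For each trial subject with membership probability p = P(trial | X), the
#' transport weight is w = (1 - p) / p, reweighting the trial sample toward
#' the covariate distribution of the target population. Probabilities are
#' clipped into `clip` before inversion to bound the weight tails; weights
#' are not renormalized (the Cox partial likelihood is invariant to a
#' common positive rescaling of the weights).
#'
#' @param model a `membership_model`.
#' @param trial the trial `cohort_table` the model was fitted on.
#' @param clip length-2 probability clipping bounds; `NULL` disables
#'   clipping, in which case any boundary probability is an error.
#' @return object of class `weight_set`: `subject_id`, `p`, `w`, `clip`,
#'   `n_clipped`, and a `summary` (min/max/mean weight, Kish ESS).
#' @export
inverse_odds_weights <- function(model, trial, clip = c(0.005, 0.995)) {
  p <- model$p_trial[trial$subject_id]
  if (anyNA(p))
    stop("membership model does not cover every trial subject")
  if (is.null(clip)) {
    if (any(p <= 0 | p >= 1))
      stop("membership probabilities at 0/1 with clipping disabled")
    n_clipped <- 0L
  } else {
    stopifnot(length(clip) == 2, clip[1] > 0, clip[2] < 1, clip[1] < clip[2])
    n_clipped <- sum(p < clip[1] | p > clip[2])
    p <- pmin(pmax(p, clip[1]), clip[2])
  }
  w <- (1 - p) / p
  structure(list(subject_id = trial$subject_id, p = unname(p), w = unname(w),
                 clip = clip, n_clipped = n_clipped,
                 summary = c(min = min(w), max = max(w), mean = mean(w),
                             ess = effective_sample_size(w))),
            class = "weight_set")
}

#' Kish effective sample size
#'
#' ESS = (sum w)^2 / sum(w^2): the number of equally weighted observations
#' carrying the same information as the weighted sample. Equals n for
#' constant weights and decreases as the weights grow unequal.
#'
#' @param w positive weights.
#' @return a single number in (0, length(w)].
#' @export
effective_sample_size <- function(w) {
  if (inherits(w, "weight_set")) w <- w$w
  if (length(w) == 0) stop("empty weight vector")
  if (any(w <= 0)) stop("weights must be > 0")
  sum(w)^2 / sum(w^2)
}

#' Weighted Cox proportional-hazards treatment effect
#'
#' Fits a Cox model for the treatment contrast (treated vs control), with
#' optional adjustment covariates and strata, maximizing the weighted
#' partial likelihood (Efron tie handling). With weights present the
#' standard error is the robust sandwich estimator, since weights are
#' estimated and model-based variance would be anti-conservative.
#'
#' @param cohort longitudinal `cohort_table`.
#' @param weights a `weight_set`, a numeric vector aligned to rows, or
#'   `NULL` for an unweighted fit.
#' @param covariate_adjustments character vector of adjustment covariates.
#' @param strata optional column name to stratify the baseline hazard on
#'   (e.g. `"source"`).
#' @param method tag recorded on the estimate.
#' @param ties tie-handling method passed to the Cox fit (`"efron"`
#'   default; `"breslow"` makes integer-weighted fits exactly equal to
#'   row-replication fits).
#' @return object of class `effect_estimate`: `log_hr`, `se`, `hr`,
#'   `ci_lower`, `ci_upper`, `n`, `events`, `ess`, `method`.
#' @export
weighted_cox_hr <- function(cohort, weights = NULL,
                            covariate_adjustments = character(),
                            strata = NULL, method = NULL, ties = "efron") {
  if (any(cohort$arm == "none")) stop("cohort has cross-sectional rows")
  if (sum(cohort$event) == 0) stop("no events in cohort")
  d <- as.data.frame(cohort)
  d$.treated <- as.numeric(d$arm == "treated")
  w <- NULL
  if (!is.null(weights)) {
    if (inherits(weights, "weight_set")) {
      w <- weights$w[match(d$subject_id, weights$subject_id)]
      if (anyNA(w)) stop("weight set does not cover every cohort subject")
    } else {
      stopifnot(length(weights) == nrow(d))
      w <- weights
    }
  }
  rhs <- c(".treated", covariate_adjustments,
           if (!is.null(strata)) paste0("strata(", strata, ")"))
  f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                               paste(rhs, collapse = " + ")))
  d$.w <- if (is.null(w)) rep(1, nrow(d)) else w
  fit <- survival::coxph(f, data = d, weights = .w,
                         robust = !is.null(w), ties = ties)
  if (anyNA(stats::coef(fit)))
    stop("Cox fit did not converge; iterations used: ", fit$iter)
  b <- stats::coef(fit)[".treated"]
  se <- sqrt(diag(fit$var)[1])  # robust var when weights were supplied
  est <- effect_estimate(
    log_hr = unname(b), se = unname(se), n = nrow(d),
    events = sum(d$event),
    ess = if (!is.null(w)) effective_sample_size(w) else nrow(d),
    method = method %||% if (is.null(w)) "unweighted" else "weighted")
  est$fit <- fit
  est
}

`%||%` <- function(a, b) if (is.null(a)) b else a

effect_estimate <- function(log_hr, se, n, events, ess = n, method = "cox") {
  structure(list(log_hr = log_hr, se = se, hr = exp(log_hr),
                 ci_lower = exp(log_hr - 1.96 * se),
                 ci_upper = exp(log_hr + 1.96 * se),
                 n = n, events = events, ess = ess, method = method),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("[%s] HR %.3f (95%% CI %.3f-%.3f)  n=%d events=%d ESS=%.0f\n",
              x$method, x$hr, x$ci_lower, x$ci_upper, x$n, x$events, x$ess))
  invisible(x)
}

#' Weight-by-treatment interaction diagnostic
#'
#' Fits a Cox model with treatment, the transport weight entered as a
#' covariate, and their product, and returns the Wald p-value of the
#' product term. A significant interaction indicates that the treatment
#' effect varies with the odds of trial membership, i.e. that transposition
#' by reweighting alone may be misleading.
#'
#' @param cohort longitudinal `cohort_table`.
#' @param weights a `weight_set` aligned to the cohort.
#' @return list with `p_value`, `z`, `degenerate` (TRUE when the weights
#'   are constant, in which case p = 1).
#' @export
weight_treatment_interaction <- function(cohort, weights) {
  w <- if (inherits(weights, "weight_set"))
    weights$w[match(cohort$subject_id, weights$subject_id)] else weights
  if (stats::sd(w) < 1e-12 * max(abs(w)))
    return(list(p_value = 1, z = 0, degenerate = TRUE))
  d <- as.data.frame(cohort)
  d$.treated <- as.numeric(d$arm == "treated")
  d$.w <- w
  fit <- survival::coxph(survival::Surv(time, event) ~ .treated * .w,
                         data = d, ties = "efron")
  z <- stats::coef(fit)[".treated:.w"] / sqrt(diag(fit$var))[3]
  list(p_value = unname(2 * stats::pnorm(-abs(z))), z = unname(z),
       degenerate = FALSE)
}

#' Transpose a trial treatment effect to a target population
#'
#' One-call workflow: fit the membership model (logistic regression or
#' discrete Bayesian network) on the stacked trial + target sample, form
#' inverse odds of sampling weights for trial members, and estimate the
#' unweighted and weighted (transposed) Cox hazard ratios. Target rows
#' carry no outcomes and never enter the Cox fit.
#'
#' @param trial longitudinal trial `cohort_table`.
#' @param target cross-sectional target `cohort_table`.
#' @param method `"LR"` or `"BN"`.
#' @param covariates membership covariates.
#' @param clip membership-probability clipping bounds.
#' @param settings list of BN settings passed to [fit_membership_bn()]
#'   (ignored for LR).
#' @return list of class `transposition_result`: `unweighted`, `transposed`
#'   (both `effect_estimate`s), `weights`, `model`, and `interaction`
#'   (weight-by-treatment diagnostic).
#' @export
transpose <- function(trial, target, method = c("LR", "BN"),
                      covariates = schema_names(cohort_schema(trial)),
                      clip = c(0.005, 0.995), settings = list()) {
  method <- match.arg(method)
  model <- if (method == "LR") {
    fit_membership_lr(trial, target, covariates)
  } else {
    do.call(fit_membership_bn,
            c(list(trial = trial, target = target, covariates = covariates),
              settings))
  }
  ws <- inverse_odds_weights(model, trial, clip = clip)
  unw <- weighted_cox_hr(trial, NULL, method = "unweighted")
  trn <- weighted_cox_hr(trial, ws, method = paste0(method, "-weighted"))
  structure(list(unweighted = unw, transposed = trn, weights = ws,
                 model = model,
                 interaction = weight_treatment_interaction(trial, ws)),
            class = "transposition_result")
}

#' @export
print.transposition_result <- function(x, ...) {
  print(x$unweighted); print(x$transposed)
  cat(sprintf("weight x treatment interaction p = %.3f%s\n",
              x$interaction$p_value,
              if (x$interaction$degenerate) " (degenerate weights)" else ""))
  invisible(x)
}
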