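#' Fit a Cox model for counterfactual risk prediction
#'
#' Cox proportional-hazards fit with the treatment contrast, optional
#' adjustment covariates, and (when several sources are present) a trial
#' identification indicator. The returned handle carries the Breslow
#' baseline cumulative hazard and everything needed to predict per-subject
#' survival S(t | X, arm) and to refit on bootstrap resamples.
#'
#' @param cohort longitudinal `cohort_table`.
#' @param covariates adjustment covariate names (may be empty).
#' @param trial_indicator include a source indicator when the cohort has
#'   more than one source (default TRUE).
#' @return object of class `combined_cox`.
#' @export
fit_combined_cox <- function(cohort, covariates = character(),
                             trial_indicator = TRUE) {
  d <- as.data.frame(cohort)
  d$.treated <- as.numeric(d$arm == "treated")
  multi <- trial_indicator && length(unique(d$source)) > 1
  rhs <- c(".treated", covariates, if (multi) "factor(source)")
  f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                               paste(rhs, collapse = " + ")))
  fit <- survival::coxph(f, data = d, ties = "efron", model = TRUE)
  if (anyNA(stats::coef(fit)))
    stop("Cox fit did not converge; iterations used: ", fit$iter)
  bh <- survival::basehaz(fit, centered = FALSE)
  structure(list(fit = fit, formula = f, data = d, covariates = covariates,
                 trial_indicator = multi, basehaz = bh),
            class = "combined_cox")
}

cumhaz_at <- function(bh, t_star) {
  if (t_star <= 0) return(0)
  i <- findInterval(t_star, bh$time)
  if (i == 0) 0 else bh$hazard[i]
}

#' Predicted survival under a counterfactual arm
#'
#' S(t | X, arm) = exp(-H0(t) exp(lp(X, arm))) with the Breslow baseline
#' cumulative hazard H0 and the uncentered linear predictor.
#'
#' @param model a `combined_cox`.
#' @param newdata data.frame of subjects (schema covariates + `source`).
#' @param t_star landmark time in years.
#' @param arm_counterfactual `"treated"`, `"control"`, or `NULL` to keep
#'   each subject's own arm.
#' @return numeric vector of survival probabilities.
#' @export
predict_survival <- function(model, newdata, t_star,
                             arm_counterfactual = NULL) {
  d <- as.data.frame(newdata)
  if (!is.null(arm_counterfactual)) d$arm <- arm_counterfactual
  d$.treated <- as.numeric(d$arm == "treated")
  if (t_star > max(model$data$time[model$data$event == 1]))
    stop("t_star lies beyond the last observed event time; ",
         "no extrapolation is performed")
  lp <- stats::predict(model$fit, newdata = d, type = "lp",
                       reference = "zero")
  exp(-cumhaz_at(model$basehaz, t_star) * exp(lp))
}

#' G-computation risk at a landmark time
#'
#' Sets every subject of the subset to the counterfactual arm and averages
#' the predicted risk 1 - S(t* | X, arm) over the subset's covariate
#' distribution (direct standardization).
#'
#' @param model a `combined_cox`.
#' @param cohort_subset data.frame/`cohort_table` of subjects to average
#'   over.
#' @param t_star landmark time in years (default 3.6).
#' @param arm_counterfactual `"treated"` or `"control"`.
#' @return a single risk in [0, 1].
#' @export
predicted_risk <- function(model, cohort_subset, t_star = 3.6,
                           arm_counterfactual = c("control", "treated")) {
  arm_counterfactual <- match.arg(arm_counterfactual)
  mean(1 - predict_survival(model, cohort_subset, t_star, arm_counterfactual))
}

#' Bootstrap plan for absolute-benefit confidence intervals
#'
#' @param B number of resamples (default 1000).
#' @param seed integer seed.
#' @return object of class `bootstrap_plan`. Resampling is of subjects,
#'   with replacement, within subgroup-by-arm strata; CIs are percentile.
#' @export
bootstrap_plan <- function(B = 1000, seed = 1L) {
  stopifnot(B >= 2)
  structure(list(B = as.integer(B), seed = seed, ci_type = "percentile"),
            class = "bootstrap_plan")
}

#' Number needed to treat from an absolute risk reduction
#'
#' NNT = 1/ARR, rounded to the nearest integer for reporting (an ARR of
#' 4.0\% gives NNT 25; 3.8\% gives 26). Zero ARR has no defined NNT.
#'
#' @param arr absolute risk reduction (risk_control - risk_treated).
#' @return nearest-integer NNT, or `NA` for `arr = 0`.
#' @export
nnt_from_arr <- function(arr) {
  if (arr == 0) return(NA_real_)
  round(1 / arr)
}

#' Absolute risk reduction and NNT with bootstrap confidence interval
#'
#' Point estimates come from the full-data model: control and treated
#' G-computation risks at the landmark time, ARR = risk_control -
#' risk_treated, NNT = 1/ARR rounded to the nearest integer for reporting
#' (the unrounded value is retained). The CI is the percentile interval of
#' B bootstrap replicates: subjects are resampled with replacement within
#' subset-by-arm strata, the Cox model is refit, and the ARR recomputed.
#' When the ARR CI spans 0 the NNT is flagged "not defined (CI crosses 0)";
#' the numeric point estimate is still attached.
#'
#' @param model a `combined_cox` fitted on the full cohort.
#' @param subset_idx integer/logical index of the subgroup's rows within
#'   the model's data (default: all rows).
#' @param t_star landmark time in years.
#' @param plan a `bootstrap_plan`.
#' @param label subgroup label recorded on the estimate.
#' @return object of class `benefit_estimate`: `subgroup`, `t_star`,
#'   `risk_control`, `risk_treated`, `arr`, `arr_ci`, `arr_se`, `nnt`,
#'   `nnt_unrounded`, `nnt_defined`, `n`, `events`, `boot` (the resample
#'   ARR vector).
#' @export
arr_nnt <- function(model, subset_idx = seq_len(nrow(model$data)),
                    t_star = 3.6, plan = bootstrap_plan(), label = "all") {
  d <- model$data
  if (is.logical(subset_idx)) subset_idx <- which(subset_idx)
  sub <- d[subset_idx, , drop = FALSE]
  rc <- predicted_risk(model, sub, t_star, "control")
  rt <- predicted_risk(model, sub, t_star, "treated")
  arr <- rc - rt
  in_sub <- seq_len(nrow(d)) %in% subset_idx
  strata <- interaction(in_sub, d$arm, drop = TRUE)
  set.seed(plan$seed)
  boot <- vapply(seq_len(plan$B), function(b) {
    idx <- unlist(lapply(split(seq_len(nrow(d)), strata), function(ii)
      ii[sample.int(length(ii), length(ii), replace = TRUE)]),
      use.names = FALSE)
    db <- d[idx, , drop = FALSE]
    fb <- tryCatch(survival::coxph(model$formula, data = db, ties = "efron",
                                   model = TRUE),
                   error = function(e) NULL)
    if (is.null(fb) || anyNA(stats::coef(fb))) return(NA_real_)
    mb <- list(fit = fb, data = db,
               basehaz = survival::basehaz(fb, centered = FALSE))
    class(mb) <- "combined_cox"
    sb <- db[in_sub[idx], , drop = FALSE]
    tryCatch(
      predicted_risk(mb, sb, t_star, "control") -
        predicted_risk(mb, sb, t_star, "treated"),
      error = function(e) NA_real_)
  }, 0)
  boot_ok <- boot[!is.na(boot)]
  ci <- stats::quantile(boot_ok, c(0.025, 0.975), names = FALSE, type = 7)
  structure(list(subgroup = label, t_star = t_star,
                 risk_control = rc, risk_treated = rt, arr = arr,
                 arr_ci = ci, arr_se = stats::sd(boot_ok),
                 nnt = nnt_from_arr(arr),
                 nnt_unrounded = if (arr == 0) NA_real_ else 1 / arr,
                 nnt_defined = !(ci[1] <= 0 && ci[2] >= 0) && arr != 0,
                 n = nrow(sub), events = sum(sub$event), boot = boot),
            class = "benefit_estimate")
}

#' @export
print.benefit_estimate <- function(x, ...) {
  cat(sprintf(
    "[%s] t*=%.1fy risk(control)=%.3f risk(treated)=%.3f ARR=%.3f (95%% CI %.3f-%.3f) NNT=%s\n",
    x$subgroup, x$t_star, x$risk_control, x$risk_treated, x$arr,
    x$arr_ci[1], x$arr_ci[2],
    if (is.na(x$nnt)) "undefined"
    else if (x$nnt_defined) as.character(x$nnt)
    else paste0(x$nnt, " (not defined: CI crosses 0)")))
  invisible(x)
}

#' Gail-Simon interaction tests across subgroups
#'
#' Given per-subgroup effect estimates D_k with standard errors s_k (on
#' the ARR or log-HR scale), computes Q+ = sum over positive D_k of
#' (D_k/s_k)^2 and Q- likewise over negative D_k. The qualitative
#' (crossover) test uses min(Q+, Q-) against its least-favorable null
#' distribution, the binomial mixture of chi-squares:
#' p = sum_{j=1}^{K-1} C(K-1, j) (1/2)^(K-1) P(chi2_j > min(Q+, Q-)).
#' The quantitative (same-direction heterogeneity) test is the
#' inverse-variance-weighted chi-square sum((D_k - Dbar_w)^2 / s_k^2) with
#' K - 1 degrees of freedom.
#'
#' @param d numeric vector of subgroup effects D_k (K >= 2).
#' @param s positive standard errors s_k.
#' @param scale tag recorded on the result (e.g. `"ARR"`, `"logHR"`).
#' @return object of class `gail_simon_result` with `q_plus`, `q_minus`,
#'   `q_min`, `p_qualitative`, `q_het`, `df`, `p_quantitative`, `scale`.
#' @export
gail_simon_test <- function(d, s, scale = "ARR") {
  K <- length(d)
  stopifnot(K >= 2, length(s) == K)
  if (any(s <= 0)) stop("all standard errors must be > 0")
  z2 <- (d / s)^2
  q_plus <- sum(z2[d > 0])
  q_minus <- sum(z2[d < 0])
  q_min <- min(q_plus, q_minus)
  j <- seq_len(K - 1)
  p_qual <- sum(stats::dbinom(j, K - 1, 0.5) *
                  stats::pchisq(q_min, df = j, lower.tail = FALSE))
  if (q_min == 0) p_qual <- 1
  w <- 1 / s^2
  dbar <- sum(d * w) / sum(w)
  q_het <- sum((d - dbar)^2 * w)
  structure(list(q_plus = q_plus, q_minus = q_minus, q_min = q_min,
                 p_qualitative = p_qual, q_het = q_het, df = K - 1L,
                 p_quantitative = stats::pchisq(q_het, K - 1,
                                                lower.tail = FALSE),
                 scale = scale, d = d, s = s),
            class = "gail_simon_result")
}

#' @export
print.gail_simon_result <- function(x, ...) {
  cat(sprintf(paste0("Gail-Simon (%s scale): Q+=%.3f Q-=%.3f\n",
                     "  qualitative (crossover) p = %.4f\n",
                     "  quantitative heterogeneity chi2=%.3f df=%d p = %.4f\n"),
              x$scale, x$q_plus, x$q_minus, x$p_qualitative, x$q_het,
              x$df, x$p_quantitative))
  invisible(x)
}

#' Relative-scale (hazard ratio) interaction test
#'
#' Cox model with treatment, subgroup, treatment-by-subgroup interaction
#' terms (plus a source indicator and optional adjustments); returns the
#' Wald test of joint nullity of the interaction coefficients.
#'
#' @param cohort longitudinal `cohort_table` with a `subgroup` column.
#' @param adjustments adjustment covariate names.
#' @return list with `p_value`, `statistic`, `df`.
#' @export
relative_scale_interaction <- function(cohort, adjustments = character()) {
  d <- as.data.frame(cohort)
  if (is.null(d$subgroup)) stop("cohort has no subgroup column")
  groups <- sort(unique(d$subgroup))
  if (length(groups) < 2) stop("need at least 2 subgroups")
  empty <- vapply(groups, function(g) sum(d$subgroup == g) == 0, TRUE)
  if (any(empty)) stop("empty subgroup(s)")
  d$.treated <- as.numeric(d$arm == "treated")
  d$.grp <- factor(d$subgroup)
  multi <- length(unique(d$source)) > 1
  rhs <- c(".treated * .grp", adjustments, if (multi) "factor(source)")
  f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                               paste(rhs, collapse = " + ")))
  fit <- survival::coxph(f, data = d, ties = "efron")
  ix <- grep("^\\.treated:", names(stats::coef(fit)))
  b <- stats::coef(fit)[ix]
  V <- fit$var[ix, ix, drop = FALSE]
  stat <- as.numeric(t(b) %*% solve(V, b))
  list(p_value = stats::pchisq(stat, length(ix), lower.tail = FALSE),
       statistic = stat, df = length(ix))
}

subgroup_arm_imbalance <- function(d, covariates, schema) {
  # covariates imbalanced across arms within a subgroup: SMD > 0.1 and
  # p < 0.05 (t-test / chi-square by kind)
  tr <- d[d$arm == "treated", , drop = FALSE]
  ct <- d[d$arm == "control", , drop = FALSE]
  flagged <- character()
  for (nm in covariates) {
    kind <- schema_kind(schema, nm)
    smd <- standardized_mean_difference(tr[[nm]], ct[[nm]], kind)
    if (!is.finite(smd) || smd <= 0.1) next
    p <- if (kind == "continuous") {
      stats::t.test(tr[[nm]], ct[[nm]])$p.value
    } else {
      tab <- rbind(c(sum(tr[[nm]] == 1), sum(tr[[nm]] == 0)),
                   c(sum(ct[[nm]] == 1), sum(ct[[nm]] == 0)))
      if (any(colSums(tab) == 0)) 1
      else stats::chisq.test(tab, correct = FALSE)$p.value
    }
    if (p < 0.05) flagged <- c(flagged, nm)
  }
  flagged
}

#' Per-subgroup clinical-benefit report
#'
#' For each subgroup of a tree: Cox treatment HR (with trial indicator),
#' G-computation risks at the landmark time, ARR with percentile bootstrap
#' CI, and NNT; followed by the interaction footer: relative-scale Wald
#' p-value and Gail-Simon qualitative/quantitative p-values on the ARR
#' scale (using the bootstrap standard errors). With `sensitivity = TRUE`,
#' covariates imbalanced across arms within a subgroup (SMD > 0.1 and
#' p < 0.05) are added to that subgroup's model and reported.
#'
#' @param cohort longitudinal `cohort_table`.
#' @param tree a `subgroup_tree` (or NULL for a single overall group).
#' @param plan a `bootstrap_plan`.
#' @param adjustments baseline adjustment covariates for every subgroup
#'   model.
#' @param t_star landmark time in years (3.6 for trial-style cohorts; 2.1
#'   is the conventional choice for shorter-follow-up external-validation
#'   cohorts).
#' @param sensitivity apply the within-subgroup imbalance adjustment rule.
#' @return object of class `benefit_report`: `table` (one row per
#'   subgroup), `gail_simon` (ARR scale), `relative_interaction`,
#'   `benefits` (list of `benefit_estimate`s), `extra_adjustments`.
#' @export
subgroup_benefit_report <- function(cohort, tree = NULL,
                                    plan = bootstrap_plan(),
                                    adjustments = character(),
                                    t_star = 3.6, sensitivity = FALSE) {
  schema <- cohort_schema(cohort)
  d <- if (is.null(tree)) {
    out <- as.data.frame(cohort); out$subgroup <- "all"; out
  } else as.data.frame(assign_subgroups(cohort, tree))
  groups <- sort(unique(d$subgroup))
  benefits <- list(); rows <- list(); extra <- list()
  for (g in groups) {
    dg <- d[d$subgroup == g, , drop = FALSE]
    adj_g <- adjustments
    if (sensitivity) {
      flg <- subgroup_arm_imbalance(dg, schema_names(schema), schema)
      extra[[g]] <- flg
      adj_g <- union(adj_g, flg)
    }
    adj_g <- adj_g[vapply(dg[adj_g], function(v) length(unique(v)) > 1, TRUE)]
    cg <- cohort_table(dg[, setdiff(names(dg), "subgroup")],
                       schema = schema, validate = FALSE)
    model <- fit_combined_cox(cg, covariates = adj_g)
    hr <- weighted_cox_hr(cg, NULL, covariate_adjustments = adj_g,
                          strata = if (length(unique(dg$source)) > 1) "source",
                          method = paste0("subgroup ", g))
    ben <- arr_nnt(model, t_star = t_star, plan = plan, label = g)
    benefits[[g]] <- ben
    rows[[g]] <- data.frame(
      subgroup = g, n = nrow(dg), events = sum(dg$event),
      hr = hr$hr, ci_lower = hr$ci_lower, ci_upper = hr$ci_upper,
      log_hr = hr$log_hr, log_hr_se = hr$se,
      risk_control = ben$risk_control, risk_treated = ben$risk_treated,
      arr = ben$arr, arr_lower = ben$arr_ci[1], arr_upper = ben$arr_ci[2],
      arr_se = ben$arr_se, nnt = ben$nnt, nnt_defined = ben$nnt_defined,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  gs <- NULL; rel <- NULL
  if (length(groups) >= 2) {
    gs <- gail_simon_test(tab$arr, tab$arr_se, scale = "ARR")
    rel <- relative_scale_interaction(
      {dd <- cohort_table(d[, setdiff(names(d), "subgroup")],
                          schema = schema, validate = FALSE)
       dd$subgroup <- d$subgroup; dd},
      adjustments = adjustments)
  }
  structure(list(table = tab, gail_simon = gs, relative_interaction = rel,
                 benefits = benefits, extra_adjustments = extra,
                 t_star = t_star),
            class = "benefit_report")
}

#' @export
print.benefit_report <- function(x, ...) {
  cat("Per-subgroup clinical benefit at t* =", x$t_star, "years\n")
  print(x$table[, c("subgroup", "n", "events", "hr", "ci_lower", "ci_upper",
                    "risk_control", "risk_treated", "arr", "arr_lower",
                    "arr_upper", "nnt")], digits = 3)
  if (!is.null(x$relative_interaction))
    cat(sprintf("relative-scale interaction p = %.3f\n",
                x$relative_interaction$p_value))
  if (!is.null(x$gail_simon))
    cat(sprintf("Gail-Simon p: qualitative %.3f, quantitative %.3f\n",
                x$gail_simon$p_qualitative, x$gail_simon$p_quantitative))
  invisible(x)
}
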