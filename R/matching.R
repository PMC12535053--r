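#' Propensity-score model for exposure
#'
#' Maximum-likelihood logistic regression of the probability of being in
#' the exposed group given baseline covariates, fitted on the stacked
#' exposed + comparator cohort. Covariates without variation are rejected.
#'
#' @param cohort longitudinal `cohort_table`; `arm == "treated"` marks the
#'   exposed (new-user) group, `arm == "control"` the comparator group.
#' @param covariates covariate names entering the PS model.
#' @return object of class `propensity_model`: `fit`, `covariates`, `ps`
#'   (named by subject_id), `logit_ps`.
#' @export
estimate_propensity <- function(cohort,
                                covariates = schema_names(cohort_schema(cohort))) {
  d <- as.data.frame(cohort)
  d$.exposed <- as.numeric(d$arm == "treated")
  if (length(unique(d$.exposed)) < 2)
    stop("both exposure groups must be non-empty")
  novar <- covariates[!vapply(d[covariates],
                              function(v) length(unique(v)) > 1, TRUE)]
  if (length(novar))
    stop("covariate(s) without variation cannot enter the PS model: ",
         paste(novar, collapse = ", "))
  f <- stats::as.formula(paste(".exposed ~",
                               paste(covariates, collapse = " + ")))
  fit <- stats::glm(f, data = d, family = stats::binomial())
  p <- stats::fitted(fit)
  eps <- 1e-8
  if (any(p > 1 - eps | p < eps)) {
    z <- abs(stats::coef(fit)[-1]) * vapply(d[covariates], stats::sd, 0)
    stop("(near-)perfect separation in the PS model; largest standardized ",
         "coefficient(s): ",
         paste(names(sort(z, decreasing = TRUE))[1:min(3, length(z))],
               collapse = ", "))
  }
  names(p) <- d$subject_id
  structure(list(fit = fit, covariates = covariates, ps = p,
                 logit_ps = stats::qlogis(p)),
            class = "propensity_model")
}

#' Nearest-neighbor matching on the logit propensity distance
#'
#' Greedy 1:1 matching: exposed subjects are processed in deterministic
#' order (descending logit PS, ties by subject_id) and each is matched to
#' the comparator minimizing |logit PS difference| (ties by subject_id).
#' With replacement a comparator may serve several exposed subjects;
#' without replacement it is removed from the pool. Pairs whose distance
#' exceeds the caliper (in SD units of the logit PS) are dropped with a log
#' entry.
#'
#' @param model a `propensity_model` covering the cohort.
#' @param cohort the stacked exposed + comparator `cohort_table`.
#' @param with_replacement logical (default TRUE).
#' @param caliper optional caliper in logit-PS standard-deviation units;
#'   `NULL` (default) disables it.
#' @return object of class `match_result`: `pairs` (data.frame
#'   `exposed_id`, `comparator_id`, `distance`), `with_replacement`,
#'   `caliper`, `dropped` (exposed ids without an eligible match).
#' @export
nn_match <- function(model, cohort, with_replacement = TRUE,
                     caliper = NULL) {
  d <- as.data.frame(cohort)
  lp <- model$logit_ps[d$subject_id]
  if (anyNA(lp)) stop("propensity model does not cover every subject")
  exposed <- d$arm == "treated"
  n_e <- sum(exposed); n_c <- sum(!exposed)
  if (!with_replacement && n_c < n_e)
    stop("matching without replacement needs at least as many comparators (",
         n_c, ") as exposed subjects (", n_e, ")")
  cal_abs <- if (is.null(caliper)) Inf else caliper * stats::sd(lp)
  e_ids <- d$subject_id[exposed]
  e_lp <- lp[exposed]
  ord <- order(-e_lp, e_ids)
  c_ids <- d$subject_id[!exposed]
  c_lp <- lp[!exposed]
  # comparator pool sorted by (logit PS, subject_id) for binary search
  c_ord <- order(c_lp, c_ids)
  pool_lp <- c_lp[c_ord]; pool_id <- c_ids[c_ord]
  alive <- rep(TRUE, length(pool_lp))
  pairs <- vector("list", length(ord))
  dropped <- character()
  for (k in seq_along(ord)) {
    x <- e_lp[ord[k]]
    idx <- which(alive)
    if (!length(idx)) { dropped <- c(dropped, e_ids[ord[k]]); next }
    dist <- abs(pool_lp[idx] - x)
    m <- min(dist)
    if (m > cal_abs) { dropped <- c(dropped, e_ids[ord[k]]); next }
    cand <- idx[dist <= m + 1e-15]
    j <- cand[order(pool_id[cand])][1]   # tie-break by comparator id
    pairs[[k]] <- data.frame(exposed_id = e_ids[ord[k]],
                             comparator_id = pool_id[j],
                             distance = abs(pool_lp[j] - x),
                             stringsAsFactors = FALSE)
    if (!with_replacement) alive[j] <- FALSE
  }
  pairs <- pairs[!vapply(pairs, is.null, TRUE)]
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(exposed_id = character(), comparator_id = character(),
               distance = numeric(), stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, with_replacement = with_replacement,
                 caliper = caliper, dropped = dropped),
            class = "match_result")
}

#' Standardized mean difference
#'
#' Continuous: |mean_a - mean_b| / sqrt((var_a + var_b)/2) with sample
#' (n-1) variances. Binary: |p_a - p_b| / sqrt((p_a(1-p_a) +
#' p_b(1-p_b))/2). Weighted versions use weighted means and weighted
#' (frequency-weight) variances. Zero pooled variance with unequal means
#' yields +Inf.
#'
#' @param x_a,x_b samples from the two groups.
#' @param kind `"continuous"` or `"binary"`.
#' @param w_a,w_b optional non-negative weights (e.g. comparator reuse
#'   counts after matching with replacement).
#' @return a non-negative number (possibly `Inf`).
#' @export
standardized_mean_difference <- function(x_a, x_b,
                                         kind = c("continuous", "binary"),
                                         w_a = NULL, w_b = NULL) {
  kind <- match.arg(kind)
  if (!length(x_a) || !length(x_b)) stop("both samples must be non-empty")
  wmean <- function(x, w) if (is.null(w)) mean(x) else sum(w * x) / sum(w)
  wvar <- function(x, w) {
    if (is.null(w)) return(stats::var(x))
    m <- sum(w * x) / sum(w)
    sum(w * (x - m)^2) / (sum(w) - 1)
  }
  ma <- wmean(x_a, w_a); mb <- wmean(x_b, w_b)
  if (kind == "binary") {
    va <- ma * (1 - ma); vb <- mb * (1 - mb)
  } else {
    va <- wvar(x_a, w_a); vb <- wvar(x_b, w_b)
  }
  pooled <- sqrt((va + vb) / 2)
  if (pooled == 0) return(if (ma == mb) 0 else Inf)
  abs(ma - mb) / pooled
}

#' Covariate balance before and after matching
#'
#' Per covariate: the standardized mean difference between exposure groups
#' before matching (full groups) and after matching (exposed subjects in
#' the matched pairs versus comparators weighted by their reuse count).
#' Good balance is SMD < 0.10 for every covariate.
#'
#' @param cohort the stacked `cohort_table` that was matched.
#' @param match a `match_result`.
#' @param covariates covariate names to assess.
#' @return object of class `balance_report`: data.frame `table`
#'   (`covariate`, `smd_before`, `smd_after`, `balanced`) and `pass`.
#' @export
balance_report <- function(cohort, match,
                           covariates = schema_names(cohort_schema(cohort))) {
  d <- as.data.frame(cohort)
  schema <- cohort_schema(cohort)
  exp_rows <- d[match(match$pairs$exposed_id, d$subject_id), , drop = FALSE]
  reuse <- table(match$pairs$comparator_id)
  cmp_rows <- d[match(names(reuse), d$subject_id), , drop = FALSE]
  w_cmp <- as.numeric(reuse)
  before_a <- d[d$arm == "treated", , drop = FALSE]
  before_b <- d[d$arm == "control", , drop = FALSE]
  rows <- lapply(covariates, function(nm) {
    kind <- schema_kind(schema, nm)
    data.frame(
      covariate = nm,
      smd_before = standardized_mean_difference(before_a[[nm]],
                                                before_b[[nm]], kind),
      smd_after = standardized_mean_difference(exp_rows[[nm]],
                                               cmp_rows[[nm]], kind,
                                               w_b = w_cmp),
      stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(covariate = character(), smd_before = numeric(),
               smd_after = numeric(), stringsAsFactors = FALSE)
  tab$balanced <- is.finite(tab$smd_after) & tab$smd_after < 0.10
  structure(list(table = tab, pass = all(tab$balanced)),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  print(x$table, digits = 3)
  cat(if (x$pass) "balance PASS (all SMD < 0.10)\n" else
    "balance FAIL (some SMD >= 0.10)\n")
  invisible(x)
}

matched_analysis_set <- function(cohort, match) {
  d <- as.data.frame(cohort)
  exp_rows <- d[match(match$pairs$exposed_id, d$subject_id), , drop = FALSE]
  exp_rows$.fw <- 1
  reuse <- table(match$pairs$comparator_id)
  cmp_rows <- d[match(names(reuse), d$subject_id), , drop = FALSE]
  cmp_rows$.fw <- as.numeric(reuse)
  out <- rbind(exp_rows, cmp_rows)
  rownames(out) <- NULL
  out
}

#' Exposure hazard ratio on the matched cohort
#'
#' Cox regression of the outcome on exposure in the matched analysis set
#' (comparators enter with frequency weights equal to their reuse count;
#' the variance is the robust sandwich estimator, since matching with
#' replacement breaks independence). With a comparator-class column
#' present (two matched sub-studies concatenated), an indicator for the
#' comparison is included. Given a subgroup tree, per-subgroup estimates
#' are returned and, per the within-subgroup balance rule, covariates with
#' after-match SMD > 0.1 across exposure groups are added as adjustments
#' (reported alongside).
#'
#' @param cohort the stacked `cohort_table` that was matched.
#' @param match a `match_result`.
#' @param tree optional `subgroup_tree` for subgroup analyses.
#' @param adjustments always-included adjustment covariates.
#' @param comparator_class optional column name indicating the comparator
#'   sub-study.
#' @return data.frame with one row per analysis (overall, then subgroups):
#'   `subgroup`, `n`, `events`, `hr`, `ci_lower`, `ci_upper`, `log_hr`,
#'   `se`, `adjusted_for`.
#' @export
comparator_cox <- function(cohort, match, tree = NULL,
                           adjustments = character(),
                           comparator_class = NULL) {
  schema <- cohort_schema(cohort)
  d <- matched_analysis_set(cohort, match)
  if (!is.null(tree))
    d <- cbind(d, subgroup = assign_subgroups(
      cohort_table(d[, setdiff(names(d), ".fw")], schema = schema,
                   validate = FALSE), tree)$subgroup)
  fit_one <- function(dd, label) {
    dd$.treated <- as.numeric(dd$arm == "treated")
    adj <- adjustments
    # within-stratum residual imbalance rule: SMD > 0.1 across arms
    for (nm in schema_names(schema)) {
      if (nm %in% adj) next
      a <- dd[dd$.treated == 1, ]; b <- dd[dd$.treated == 0, ]
      smd <- standardized_mean_difference(a[[nm]], b[[nm]],
                                          schema_kind(schema, nm),
                                          w_a = a$.fw, w_b = b$.fw)
      if (is.finite(smd) && smd > 0.1) adj <- c(adj, nm)
    }
    adj <- adj[vapply(dd[adj], function(v) length(unique(v)) > 1, TRUE)]
    rhs <- c(".treated", adj,
             if (!is.null(comparator_class)) comparator_class)
    f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(rhs, collapse = " + ")))
    fit <- survival::coxph(f, data = dd, weights = dd$.fw, robust = TRUE,
                           ties = "efron")
    b <- stats::coef(fit)[".treated"]; se <- sqrt(diag(fit$var))[1]
    data.frame(subgroup = label, n = nrow(dd), events = sum(dd$event * dd$.fw),
               hr = exp(b), ci_lower = exp(b - 1.96 * se),
               ci_upper = exp(b + 1.96 * se), log_hr = unname(b),
               se = unname(se),
               adjusted_for = paste(adj, collapse = ";"),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- fit_one(d, "overall")
  if (!is.null(tree))
    for (g in sort(unique(d$subgroup)))
      out <- rbind(out, fit_one(d[d$subgroup == g, , drop = FALSE], g))
  out
}
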