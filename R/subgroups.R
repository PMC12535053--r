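#' Stratified train/test split protocol
#'
#' @param train_fraction fraction of each source assigned to the training
#'   set (default 0.70).
#' @param seed integer seed.
#' @return object of class `split_protocol`.
#' @export
split_protocol <- function(train_fraction = 0.70, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  structure(list(train_fraction = train_fraction, seed = seed),
            class = "split_protocol")
}

#' Split cohorts into train and test sets, stratified by source
#'
#' Each source contributes `train_fraction` of its subjects (rounded to the
#' nearest subject) to the training set; every subject lands in exactly one
#' partition; membership is deterministic given the protocol seed.
#'
#' @param cohorts a `cohort_table` or list of `cohort_table`s (stacked).
#' @param protocol a `split_protocol`.
#' @return list with `train` and `test` `cohort_table`s.
#' @export
split_train_test <- function(cohorts, protocol = split_protocol()) {
  if (inherits(cohorts, "cohort_table")) cohorts <- list(cohorts)
  schema <- cohort_schema(cohorts[[1]])
  df <- do.call(rbind, lapply(cohorts, as.data.frame))
  rownames(df) <- NULL
  counts <- table(df$source)
  if (any(counts < 10))
    stop("source(s) with fewer than 10 subjects: ",
         paste(names(counts)[counts < 10], collapse = ", "))
  set.seed(protocol$seed)
  in_train <- logical(nrow(df))
  for (src in sort(unique(df$source))) {
    idx <- which(df$source == src)
    n_tr <- round(protocol$train_fraction * length(idx))
    in_train[sample(idx, n_tr)] <- TRUE
  }
  mk <- function(rows) {
    out <- df[rows, , drop = FALSE]; rownames(out) <- NULL
    cohort_table(out, schema = schema)
  }
  list(train = mk(in_train), test = mk(!in_train))
}

#' Prognostic risk model under control conditions
#'
#' Fits a multivariable Cox model for the outcome on control-arm subjects
#' only and returns the linear-predictor risk score for every subject of
#' the cohort (both arms). This is the first step of the subgroup-discovery
#' pipeline: a control-condition risk model that anchors subsequent
#' effect-modification screening.
#'
#' @param train longitudinal `cohort_table`.
#' @param covariates covariate names entering the risk model.
#' @return list with `fit` (coxph on controls), `score` (named numeric,
#'   linear predictor per subject), `covariates`.
#' @export
fit_control_risk_model <- function(train,
                                   covariates = schema_names(cohort_schema(train))) {
  d <- as.data.frame(train)
  ctrl <- d[d$arm == "control", , drop = FALSE]
  if (nrow(ctrl) == 0 || sum(ctrl$event) == 0)
    stop("no control-arm events: cannot fit the control risk model")
  keep <- covariates[vapply(ctrl[covariates],
                            function(v) length(unique(v)) > 1, TRUE)]
  f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                               paste(keep, collapse = " + ")))
  fit <- survival::coxph(f, data = ctrl, ties = "efron")
  b <- stats::coef(fit)
  score <- as.vector(as.matrix(d[, keep, drop = FALSE]) %*% b)
  names(score) <- d$subject_id
  list(fit = fit, score = score, covariates = keep)
}

#' Elastic-net screening of treatment-effect modifiers
#'
#' Fits a penalized Cox model containing unpenalized main effects (all
#' covariates, the treatment arm, and a trial-source indicator when several
#' sources are present) and penalized treatment-by-covariate interaction
#' terms (covariates centered before interacting). The penalty is chosen by
#' seeded k-fold cross-validation; the importance of each covariate is the
#' magnitude of its standardized interaction coefficient at the selected
#' penalty. Ordering is total: ties are broken lexicographically by
#' covariate name.
#'
#' @param train longitudinal `cohort_table` (training set only).
#' @param covariates candidate modifier names.
#' @param alpha elastic-net mixing parameter (default 0.5).
#' @param nfolds cross-validation folds (default 5).
#' @param seed fold-assignment seed.
#' @param lambda `"lambda.min"` (default) or `"lambda.1se"`.
#' @return object of class `modifier_ranking`: data.frame `covariate`,
#'   `importance`, `coefficient` ordered by decreasing importance, plus the
#'   settings used.
#' @export
elastic_net_interaction_filter <- function(train,
                                           covariates = schema_names(cohort_schema(train)),
                                           alpha = 0.5, nfolds = 5,
                                           seed = 1L, lambda = "lambda.min") {
  d <- as.data.frame(train)
  if (length(unique(d$arm[d$arm != "none"])) < 2)
    stop("treatment arm has no variation")
  treated <- as.numeric(d$arm == "treated")
  keep <- covariates[vapply(d[covariates],
                            function(v) length(unique(v)) > 1, TRUE)]
  Xm <- as.matrix(d[, keep, drop = FALSE])
  Xc <- sweep(Xm, 2, colMeans(Xm))
  Xi <- Xc * treated
  colnames(Xi) <- paste0("trt_x_", keep)
  src <- if (length(unique(d$source)) > 1)
    stats::model.matrix(~ factor(source), d)[, -1, drop = FALSE] else NULL
  X <- cbind(Xm, treated = treated, src, Xi)
  pf <- c(rep(0, ncol(Xm) + 1 + if (is.null(src)) 0 else ncol(src)),
          rep(1, ncol(Xi)))
  y <- survival::Surv(d$time, d$event)
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(nfolds), nrow(d)))
  cv <- glmnet::cv.glmnet(X, y, family = "cox", alpha = alpha,
                          foldid = foldid, penalty.factor = pf,
                          standardize = TRUE)
  b <- as.vector(stats::coef(cv, s = lambda))
  names(b) <- rownames(stats::coef(cv, s = lambda))
  bi <- b[paste0("trt_x_", keep)]
  importance <- abs(bi) * apply(Xm, 2, stats::sd)
  ord <- order(-importance, keep)
  structure(list(
    ranking = data.frame(covariate = keep[ord],
                         importance = unname(importance[ord]),
                         coefficient = unname(bi[ord]),
                         stringsAsFactors = FALSE),
    settings = list(alpha = alpha, nfolds = nfolds, seed = seed,
                    lambda = lambda, lambda_value = cv[[lambda]])),
    class = "modifier_ranking")
}

#' @export
print.modifier_ranking <- function(x, ...) {
  cat("<modifier_ranking> (elastic net, alpha =", x$settings$alpha, ")\n")
  print(utils::head(x$ranking, 10))
  invisible(x)
}

leaf_arm_fit <- function(d) {
  d$.treated <- as.numeric(d$arm == "treated")
  multi <- length(unique(d$source)) > 1
  f <- if (multi)
    survival::Surv(time, event) ~ .treated + strata(source)
  else survival::Surv(time, event) ~ .treated
  fit <- survival::coxph(f, data = d, ties = "efron")
  c(b = unname(stats::coef(fit)[1]), se = sqrt(fit$var[1, 1]))
}

#' Derive a shallow subgroup tree by greedy benefit-contrast search
#'
#' Greedy recursive partitioning on the top-ranked treatment-effect
#' modifiers. At each node, every candidate covariate is scanned over a
#' quantile grid of thresholds (binary flags split at 0.5); the split score
#' is the z-statistic of the contrast between the two children's Cox
#' treatment coefficients. The best split is kept if its |z| reaches
#' `z_crit` and both children satisfy the minimum leaf size and per-arm
#' event counts; otherwise the node becomes a leaf. Ties are broken by
#' lexicographic covariate name, then smaller threshold. Leaves are labeled
#' deterministically: leaves on the prior-event branch first (when a
#' prior-event flag is a split variable), then by descending control-arm
#' event rate — A, B, C, ...
#'
#' @param train longitudinal training `cohort_table`.
#' @param ranking a `modifier_ranking`.
#' @param max_depth maximum tree depth (default 2).
#' @param min_leaf minimum subjects per leaf (default 50).
#' @param min_events minimum events per arm per leaf (default 5).
#' @param top_k number of top-ranked modifiers used as split candidates
#'   (default 2, i.e. the two most important variables).
#' @param z_crit contrast z-statistic required to accept a split
#'   (default 1.96).
#' @param grid quantile grid for continuous thresholds (default percentiles
#'   10 to 90 by 5).
#' @param prior_flag name of the prior-event flag used in leaf labeling.
#' @return object of class `subgroup_tree`.
#' @export
derive_subgroup_tree <- function(train, ranking, max_depth = 2,
                                 min_leaf = 50, min_events = 5, top_k = 2,
                                 z_crit = 1.96,
                                 grid = seq(0.10, 0.90, by = 0.05),
                                 prior_flag = "prior_mi_stroke") {
  stopifnot(inherits(ranking, "modifier_ranking"))
  schema <- cohort_schema(train)
  rk <- ranking$ranking
  candidates <- utils::head(rk$covariate[rk$importance > 0], top_k)
  d <- as.data.frame(train)
  build <- function(rows, depth) {
    if (depth >= max_depth || length(candidates) == 0)
      return(list(leaf = TRUE, n = length(rows)))
    best <- NULL
    for (cv in sort(candidates)) {
      kind <- schema_kind(schema, cv)
      thrs <- if (kind == "binary") 0.5 else
        sort(unique(stats::quantile(d[[cv]][rows], probs = grid,
                                    names = FALSE, type = 7)))
      for (thr in thrs) {
        left <- rows[d[[cv]][rows] <= thr]
        right <- setdiff(rows, left)
        if (length(left) < min_leaf || length(right) < min_leaf) next
        ok <- vapply(list(left, right), function(rr) {
          ev <- tapply(d$event[rr], d$arm[rr], sum)
          length(ev) == 2 && all(ev >= min_events)
        }, TRUE)
        if (!all(ok)) next
        fl <- leaf_arm_fit(d[left, ]); fr <- leaf_arm_fit(d[right, ])
        z <- (fl["b"] - fr["b"]) / sqrt(fl["se"]^2 + fr["se"]^2)
        if (is.null(best) || abs(z) > abs(best$z) + 1e-12)
          best <- list(var = cv, thr = thr, z = unname(z),
                       left = left, right = right)
      }
    }
    if (is.null(best) || abs(best$z) < z_crit)
      return(list(leaf = TRUE, n = length(rows)))
    list(leaf = FALSE, var = best$var, thr = best$thr, z = best$z,
         left = build(best$left, depth + 1),
         right = build(best$right, depth + 1))
  }
  root <- build(seq_len(nrow(d)), 0)
  tree <- structure(list(root = root, schema = schema,
                         prior_flag = prior_flag),
                    class = "subgroup_tree")
  if (root$leaf) {
    tree$leaves <- data.frame(label = "A", path = "(all)",
                              stringsAsFactors = FALSE)
    warning("no admissible split: single-leaf tree")
    return(tree)
  }
  # collect leaves with paths, then label deterministically
  paths <- list()
  walk <- function(node, conds, rules) {
    if (node$leaf) {
      paths[[length(paths) + 1]] <<- list(conds = conds, rules = rules)
      return(invisible())
    }
    walk(node$left, c(conds, sprintf("%s <= %g", node$var, node$thr)),
         rbind(rules, data.frame(var = node$var, op = "<=", thr = node$thr)))
    walk(node$right, c(conds, sprintf("%s > %g", node$var, node$thr)),
         rbind(rules, data.frame(var = node$var, op = ">", thr = node$thr)))
  }
  walk(root, character(), NULL)
  info <- lapply(paths, function(p) {
    sel <- rep(TRUE, nrow(d))
    for (i in seq_len(nrow(p$rules))) {
      v <- d[[p$rules$var[i]]]
      sel <- sel & if (p$rules$op[i] == "<=") v <= p$rules$thr[i]
      else v > p$rules$thr[i]
    }
    ctrl <- sel & d$arm == "control"
    prior_side <- any(p$rules$var == prior_flag & p$rules$op == ">")
    list(path = paste(p$conds, collapse = " & "),
         risk = if (any(ctrl)) mean(d$event[ctrl]) else 0,
         prior = prior_side)
  })
  ord <- order(!vapply(info, `[[`, TRUE, "prior"),
               -vapply(info, `[[`, 0, "risk"))
  tree$leaves <- data.frame(
    label = LETTERS[match(seq_along(info), ord)],
    path = vapply(info, `[[`, "", "path"),
    control_risk = vapply(info, `[[`, 0, "risk"),
    stringsAsFactors = FALSE)
  tree
}

#' @export
print.subgroup_tree <- function(x, ...) {
  cat("<subgroup_tree>\n")
  if (x$root$leaf) {
    cat("  (single leaf: all subjects -> A)\n")
  } else {
    for (i in seq_len(nrow(x$leaves)))
      cat(sprintf("  %s: %s\n", x$leaves$label[i], x$leaves$path[i]))
  }
  invisible(x)
}

#' Reference prior-event / age classification tree
#'
#' The fixed two-level classification used for benefit reporting and
#' external validation: group A = prior MI/stroke; group B = no prior
#' event and age above the threshold; group C = no prior event and age at
#' or below the threshold.
#'
#' @param age_threshold age cut in years (default 71).
#' @param schema `covariate_schema` the rules refer to.
#' @return a `subgroup_tree` with leaves A, B, C.
#' @export
reference_subgroup_tree <- function(age_threshold = 71,
                                    schema = default_schema()) {
  root <- list(leaf = FALSE, var = "prior_mi_stroke", thr = 0.5,
               left = list(leaf = FALSE, var = "age", thr = age_threshold,
                           left = list(leaf = TRUE),
                           right = list(leaf = TRUE)),
               right = list(leaf = TRUE))
  structure(list(
    root = root, schema = schema, prior_flag = "prior_mi_stroke",
    leaves = data.frame(
      label = c("C", "B", "A"),
      path = c(sprintf("prior_mi_stroke <= 0.5 & age <= %g", age_threshold),
               sprintf("prior_mi_stroke <= 0.5 & age > %g", age_threshold),
               "prior_mi_stroke > 0.5"),
      stringsAsFactors = FALSE)),
    class = "subgroup_tree")
}

#' Split variables of a subgroup tree
#' @param tree a `subgroup_tree`.
#' @return character vector of distinct split covariates (depth order).
#' @export
tree_split_vars <- function(tree) {
  out <- character()
  walk <- function(node) {
    if (node$leaf) return(invisible())
    out <<- c(out, node$var)
    walk(node$left); walk(node$right)
  }
  walk(tree$root)
  unique(out)
}

#' Assign subgroup labels to a cohort
#'
#' Routes each subject through the tree (rule `x <= thr` goes left) and
#' appends a `subgroup` column. Every subject maps to exactly one leaf.
#'
#' @param cohort a `cohort_table` carrying the tree's split covariates.
#' @param tree a `subgroup_tree`.
#' @return the cohort with a `subgroup` column.
#' @export
assign_subgroups <- function(cohort, tree) {
  miss <- setdiff(tree_split_vars(tree), names(cohort))
  if (length(miss))
    stop("cohort lacks covariate(s) used by the tree: ",
         paste(miss, collapse = ", "))
  n <- nrow(cohort)
  if (tree$root$leaf) {
    cohort$subgroup <- rep("A", n)
    return(cohort)
  }
  leaf_id <- integer(n)
  counter <- 0L
  walk <- function(node, rows) {
    if (node$leaf) {
      counter <<- counter + 1L
      leaf_id[rows] <<- counter
      return(invisible())
    }
    go_left <- cohort[[node$var]][rows] <= node$thr
    walk(node$left, rows[go_left])
    walk(node$right, rows[!go_left])
  }
  walk(tree$root, seq_len(n))
  cohort$subgroup <- tree$leaves$label[leaf_id]
  cohort
}

#' Subgroup shares per source
#' @param cohort a `cohort_table` with a `subgroup` column.
#' @return data.frame of proportions, one row per source x subgroup.
#' @export
subgroup_proportions <- function(cohort) {
  tab <- prop.table(table(cohort$source, cohort$subgroup), margin = 1)
  as.data.frame(tab, responseName = "proportion",
                stringsAsFactors = FALSE) |>
    stats::setNames(c("source", "subgroup", "proportion"))
}

#' Held-out per-subgroup treatment effects
#'
#' Per-leaf Cox treatment hazard ratios on an evaluation cohort (typically
#' the held-out test set), stratifying the baseline hazard by trial source
#' when several sources are present. Leaves with zero events in either arm
#' are flagged and their HR omitted.
#'
#' @param test longitudinal `cohort_table` (not used to build the tree).
#' @param tree a `subgroup_tree`.
#' @return data.frame: `subgroup`, `n`, `events`, `log_hr`, `se`, `hr`,
#'   `ci_lower`, `ci_upper`, `flagged`.
#' @export
evaluate_subgroups <- function(test, tree) {
  lab <- assign_subgroups(test, tree)
  d <- as.data.frame(lab)
  out <- lapply(sort(unique(d$subgroup)), function(g) {
    dg <- d[d$subgroup == g, , drop = FALSE]
    ev <- tapply(dg$event, dg$arm, sum)
    if (length(ev) < 2 || any(ev == 0) || anyNA(ev))
      return(data.frame(subgroup = g, n = nrow(dg), events = sum(dg$event),
                        log_hr = NA_real_, se = NA_real_, hr = NA_real_,
                        ci_lower = NA_real_, ci_upper = NA_real_,
                        flagged = TRUE))
    fit <- leaf_arm_fit(dg)
    data.frame(subgroup = g, n = nrow(dg), events = sum(dg$event),
               log_hr = fit["b"], se = fit["se"], hr = exp(fit["b"]),
               ci_lower = exp(fit["b"] - 1.96 * fit["se"]),
               ci_upper = exp(fit["b"] + 1.96 * fit["se"]),
               flagged = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}
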