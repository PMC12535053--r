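test_that("stratified 70/30 split partitions each source to within one subject", {
  set.seed(3)
  coh <- rbind_cohorts <- cohort_table(rbind(
    as.data.frame(toy_cohort(arm = rep(c("treated", "control"), 500),
                             time = rexp(1000) + 0.01,
                             event = rbinom(1000, 1, 0.3),
                             subject_id = paste0("L", 1:1000),
                             source = "trial_1")),
    as.data.frame(toy_cohort(arm = rep(c("treated", "control"), 150),
                             time = rexp(300) + 0.01,
                             event = rbinom(300, 1, 0.3),
                             subject_id = paste0("S", 1:300),
                             source = "trial_2"))))
  sp <- split_train_test(coh, split_protocol(seed = 42))
  tab_tr <- table(sp$train$source)
  tab_te <- table(sp$test$source)
  expect_true(abs(tab_tr[["trial_1"]] - 700) <= 1)
  expect_true(abs(tab_tr[["trial_2"]] - 210) <= 1)
  expect_true(abs(tab_te[["trial_1"]] - 300) <= 1)
  expect_true(abs(tab_te[["trial_2"]] - 90) <= 1)
  # partition: union is the input, intersection empty
  expect_setequal(c(sp$train$subject_id, sp$test$subject_id),
                  coh$subject_id)
  expect_length(intersect(sp$train$subject_id, sp$test$subject_id), 0)
  # determinism
  sp2 <- split_train_test(coh, split_protocol(seed = 42))
  expect_identical(sp$train$subject_id, sp2$train$subject_id)
  expect_error(split_train_test(coh[1:5, ], split_protocol()), "fewer than 10")
})

test_that("control risk model recovers the sign of a strong risk covariate", {
  rate_C <- 0.05
  spec <- exp_scenario(rate = rate_C, hr = 1, horizon = 5, n = 6000, seed = 2)
  spec$outcome$coefficients <- list(list(rule = "prior_mi_stroke", beta = 1.2))
  b <- generate_scenario(spec)
  rm <- fit_control_risk_model(b$trials$trial_1,
                               covariates = c("prior_mi_stroke", "bmi"))
  expect_gt(coef(rm$fit)["prior_mi_stroke"], 0.8)
  expect_lt(abs(coef(rm$fit)["bmi"]), 0.1)
  expect_length(rm$score, nrow(b$trials$trial_1))
  # no control events -> explicit error
  tiny <- b$trials$trial_1[1:50, ]
  tiny$event[tiny$arm == "control"] <- 0
  expect_error(fit_control_risk_model(cohort_table(as.data.frame(tiny))),
               "control-arm events")
})

test_that("elastic net ranks true modifiers first in a strong-signal scenario", {
  spec <- exp_scenario(rate = 0.06, hr = 1, horizon = 5, n = 8000, seed = 4)
  spec$outcome$beta_treat <- 0
  spec$outcome$modifiers <- list(
    list(rule = "prior_mi_stroke", log_hr = -0.9),
    list(rule = "age > 66", log_hr = -0.9))
  b <- generate_scenario(spec)
  rk <- elastic_net_interaction_filter(b$trials$trial_1, seed = 11)
  expect_setequal(rk$ranking$covariate[1:2], c("age", "prior_mi_stroke"))
  expect_true(all(diff(rk$ranking$importance) <= 1e-12))
  # determinism under the fold seed
  rk2 <- elastic_net_interaction_filter(b$trials$trial_1, seed = 11)
  expect_identical(rk$ranking, rk2$ranking)
})

test_that("duplicated covariate columns share importance and keep a total order", {
  spec <- exp_scenario(rate = 0.06, hr = 1, horizon = 5, n = 4000, seed = 6)
  spec$outcome$beta_treat <- 0
  spec$outcome$modifiers <- list(list(rule = "prior_mi_stroke",
                                      log_hr = -0.9))
  b <- generate_scenario(spec)
  coh <- b$trials$trial_1
  coh$prior_cvd <- coh$prior_mi_stroke  # exact duplicate column
  rk <- elastic_net_interaction_filter(coh,
                                       covariates = c("prior_cvd",
                                                      "prior_mi_stroke",
                                                      "bmi", "hba1c"),
                                       seed = 3)
  expect_equal(nrow(rk$ranking), 4)
  expect_false(is.unsorted(rev(rk$ranking$importance)))
  both <- rk$ranking$importance[match(c("prior_cvd", "prior_mi_stroke"),
                                      rk$ranking$covariate)]
  # the duplicated pair carries (jointly) the signal; ties broken by name
  expect_gt(sum(both), 0)
})

test_that("tree derivation: depth 0, null data, and structure recovery", {
  spec <- exp_scenario(rate = 0.06, hr = 1, horizon = 5, n = 8000, seed = 8)
  spec$outcome$beta_treat <- 0
  spec$outcome$modifiers <- list(
    list(rule = "prior_mi_stroke", log_hr = -1.0),
    list(rule = "(prior_mi_stroke == 0) & (age > 66)", log_hr = -1.0))
  b <- generate_scenario(spec)
  rk <- elastic_net_interaction_filter(b$trials$trial_1, seed = 5)
  expect_warning(
    t0 <- derive_subgroup_tree(b$trials$trial_1, rk, max_depth = 0),
    "single-leaf")
  expect_true(t0$root$leaf)
  tree <- derive_subgroup_tree(b$trials$trial_1, rk)
  expect_setequal(tree_split_vars(tree), c("prior_mi_stroke", "age"))
  # null scenario: no admissible split
  null_spec <- exp_scenario(rate = 0.06, hr = 0.9, horizon = 5, n = 4000,
                            seed = 9)
  bn <- generate_scenario(null_spec)
  rkn <- elastic_net_interaction_filter(bn$trials$trial_1, seed = 5)
  tn <- suppressWarnings(derive_subgroup_tree(bn$trials$trial_1, rkn))
  expect_true(tn$root$leaf)
})

test_that("subgroup assignment follows the discovered rule structure", {
  tree <- fig_tree()
  subj <- toy_cohort(arm = rep("none", 4),
                     prior_mi_stroke = c(0, 1, 0, 1),
                     age = c(75, 40, 71, 80))
  got <- assign_subgroups(subj, tree)
  # no prior event & age>71 -> B; prior event -> A; age exactly 71 -> C
  expect_equal(got$subgroup, c("B", "A", "C", "A"))
  # every subject maps to exactly one leaf
  expect_false(anyNA(got$subgroup))
  bad <- subj; bad$age <- NULL
  expect_error(assign_subgroups(bad, tree), "age")
  props <- subgroup_proportions(got)
  expect_equal(sum(props$proportion), 1)
})

test_that("held-out evaluation recovers leaf effects and flags empty arms", {
  spec <- exp_scenario(rate = 0.06, hr = 0.9, horizon = 5, n = 12000, seed = 14)
  spec$outcome$modifiers <- list(
    list(rule = "(prior_mi_stroke == 0) & (age > 71)",
         log_hr = log(0.55 / 0.9)))
  b <- generate_scenario(spec)
  eff <- evaluate_subgroups(b$trials$trial_1, fig_tree())
  expect_equal(eff$subgroup, c("A", "B", "C"))
  expect_false(any(eff$flagged))
  hrB <- eff$hr[eff$subgroup == "B"]
  expect_lt(abs(hrB - 0.55), 0.25)
  expect_lt(eff$hr[eff$subgroup == "B"], eff$hr[eff$subgroup == "C"])
  # a leaf with no treated events is flagged, not estimated
  few <- as.data.frame(b$trials$trial_1)
  few$event[few$prior_mi_stroke == 1 & few$arm == "treated"] <- 0
  eff2 <- evaluate_subgroups(cohort_table(few), fig_tree())
  expect_true(eff2$flagged[eff2$subgroup == "A"])
  expect_true(is.na(eff2$hr[eff2$subgroup == "A"]))
})
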