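zero_treatment_model <- function(model) {
  # force a literally null treatment coefficient (coefficient-zero identity)
  model$fit$coefficients[".treated"] <- 0
  model
}

test_that("predicted survival is a proper survival function", {
  coh <- make_exp_cohort(rate = 0.1, hr = 0.8, horizon = 6, n = 3000, seed = 2)
  model <- fit_combined_cox(coh)
  s0 <- predict_survival(model, coh[1:50, ], 1e-9)
  expect_true(all(abs(s0 - 1) < 1e-6))     # S(0 | X, arm) = 1
  grid <- seq(0.5, 4.5, by = 0.5)
  risks <- vapply(grid, function(t)
    predicted_risk(model, coh[1:200, ], t, "control"), 0)
  expect_false(is.unsorted(risks))          # risk non-decreasing in t
  surv <- 1 - risks
  expect_true(all(diff(surv) <= 1e-12))     # S non-increasing in t
  expect_error(predict_survival(model, coh[1:5, ], 50), "beyond the last")
})

test_that("Breslow cumulative hazard matches the exponential closed form", {
  coh <- make_exp_cohort(rate = 0.1, hr = 1, horizon = 6, n = 20000, seed = 5)
  model <- fit_combined_cox(coh)
  model <- zero_treatment_model(model)
  # with a null coefficient the baseline is the common hazard: H(t) = 0.1 t
  for (t in c(1, 2, 3.6))
    expect_lt(abs(cumhaz_at(model$basehaz, t) - 0.1 * t), 0.012)
  # control risk at 3.6 y for rate 0.028: 1 - exp(-0.1008) = 0.0959
  coh2 <- make_exp_cohort(rate = 0.028, hr = 1, horizon = 6, n = 30000,
                          seed = 6)
  m2 <- zero_treatment_model(fit_combined_cox(coh2))
  expect_lt(abs(predicted_risk(m2, coh2, 3.6, "control") -
                  (1 - exp(-0.1008))), 0.006)
})

test_that("null treatment coefficient gives identical counterfactual risks", {
  coh <- make_exp_cohort(rate = 0.1, hr = 0.7, horizon = 6, n = 2000, seed = 7)
  model <- zero_treatment_model(fit_combined_cox(coh))
  rc <- predicted_risk(model, coh, 3, "control")
  rt <- predicted_risk(model, coh, 3, "treated")
  expect_identical(rc, rt)
  ben <- arr_nnt(model, t_star = 3, plan = bootstrap_plan(B = 5, seed = 1))
  expect_identical(ben$arr, 0)
  expect_true(is.na(ben$nnt))
})

test_that("NNT reporting uses nearest-integer reciprocal ARR", {
  expect_equal(nnt_from_arr(0.040), 25)
  expect_equal(nnt_from_arr(0.038), 26)   # 1/0.038 = 26.3
  expect_equal(nnt_from_arr(-0.05), -20)  # sign follows the ARR
  expect_true(is.na(nnt_from_arr(0)))
})

test_that("ARR identity, bootstrap determinism and CI sanity", {
  coh <- make_exp_cohort(rate = 0.15, hr = 0.6, horizon = 5, n = 1500,
                         seed = 9)
  model <- fit_combined_cox(coh)
  plan <- bootstrap_plan(B = 199, seed = 21)
  ben <- arr_nnt(model, t_star = 3, plan = plan)
  expect_identical(ben$arr, ben$risk_control - ben$risk_treated)
  expect_equal(ben$nnt_unrounded * ben$arr, 1, tolerance = 1e-12)
  # percentile CI endpoints are order statistics of the stored resamples
  expect_equal(unname(ben$arr_ci),
               unname(quantile(ben$boot[!is.na(ben$boot)], c(0.025, 0.975),
                               type = 7)))
  expect_true(ben$arr_ci[1] <= ben$arr && ben$arr <= ben$arr_ci[2])
  ben2 <- arr_nnt(model, t_star = 3, plan = plan)
  expect_identical(ben$boot, ben2$boot)    # reproducible given the seed
  # true ARR for rate 0.15, HR 0.6 at t = 3:
  truth <- exp(-0.45 * 0.6) - exp(-0.45)
  expect_lt(abs(ben$arr - truth), 0.04)
})

test_that("Gail-Simon statistics: closed forms and invariances", {
  # all same sign: no crossover evidence at all
  same <- gail_simon_test(c(2, 2), c(1, 1))
  expect_equal(min(same$q_plus, same$q_minus), 0)
  expect_equal(same$p_qualitative, 1)
  # K=2 at +/- 1.96 SE: min statistic is 1.96^2 = 3.8416,
  # p = (1/2) P(chi2_1 > 3.8416) = 0.025
  cross <- gail_simon_test(c(1.96, -1.96), c(1, 1))
  expect_equal(cross$q_min, 1.96^2, tolerance = 1e-12)
  expect_equal(cross$p_qualitative, 0.5 * pchisq(1.96^2, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # equal estimates: zero heterogeneity
  eq <- gail_simon_test(c(0.04, 0.04, 0.04), c(0.01, 0.02, 0.01))
  expect_equal(eq$q_het, 0, tolerance = 1e-12)
  expect_equal(eq$p_quantitative, 1)
  # invariance to relabeling and to a global sign flip
  d <- c(0.05, -0.01, 0.03); s <- c(0.02, 0.015, 0.01)
  a <- gail_simon_test(d, s)
  b <- gail_simon_test(rev(d), rev(s))
  cc <- gail_simon_test(-d, s)
  expect_equal(a$p_qualitative, b$p_qualitative, tolerance = 1e-12)
  expect_equal(a$p_qualitative, cc$p_qualitative, tolerance = 1e-12)
  expect_equal(a$p_quantitative, cc$p_quantitative, tolerance = 1e-12)
  expect_error(gail_simon_test(c(1, 2), c(1, 0)), "> 0")
  expect_error(gail_simon_test(1, 1))
})

test_that("relative-scale interaction is null for a duplicated subgroup labeling", {
  coh <- make_exp_cohort(rate = 0.12, hr = 0.7, horizon = 5, n = 4000,
                         seed = 11)
  coh$subgroup <- rep(c("g1", "g2"), length.out = nrow(coh))  # arbitrary split
  res <- relative_scale_interaction(coh)
  expect_equal(res$df, 1)
  expect_lt(res$statistic, qchisq(0.999, 1))
  one <- coh; one$subgroup <- "g1"
  expect_error(relative_scale_interaction(one), "at least 2")
})

test_that("benefit report: per-subgroup rows, interaction footer, single group", {
  spec <- exp_scenario(rate = 0.05, hr = 1, horizon = 5, n = 9000, seed = 13)
  spec$outcome$beta_treat <- log(0.85)
  spec$outcome$modifiers <- list(
    list(rule = "(prior_mi_stroke == 0) & (age > 71)",
         log_hr = log(0.55 / 0.85)))
  spec$outcome$coefficients <- list(list(rule = "prior_mi_stroke",
                                         beta = 0.8))
  b <- generate_scenario(spec)
  tree <- fig_tree()
  rep <- subgroup_benefit_report(b$trials$trial_1, tree,
                                 plan = bootstrap_plan(B = 30, seed = 3),
                                 t_star = 3.6)
  expect_equal(rep$table$subgroup, c("A", "B", "C"))
  expect_equal(rep$table$arr,
               rep$table$risk_control - rep$table$risk_treated,
               tolerance = 1e-12)
  expect_s3_class(rep$gail_simon, "gail_simon_result")
  expect_true(rep$relative_interaction$p_value >= 0 &&
                rep$relative_interaction$p_value <= 1)
  # single-subgroup report suppresses the interaction tests
  solo <- subgroup_benefit_report(b$trials$trial_1, tree = NULL,
                                  plan = bootstrap_plan(B = 10, seed = 4),
                                  t_star = 3.6)
  expect_equal(nrow(solo$table), 1)
  expect_null(solo$gail_simon)
  expect_null(solo$relative_interaction)
})
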