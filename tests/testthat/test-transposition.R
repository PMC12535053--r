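test_that("logistic membership model matches a brute-force MLE on a toy stack", {
  trial <- toy_cohort(arm = rep("none", 3), age = c(55, 60, 67),
                      subject_id = c("t1", "t2", "t3"))
  target <- toy_cohort(arm = rep("none", 3), age = c(66, 72, 80),
                       subject_id = c("g1", "g2", "g3"))
  fit <- fit_membership_lr(trial, target, covariates = "age")
  oracle <- oracle_logistic_mle(
    X = c(55, 60, 67, 66, 72, 80), y = c(1, 1, 1, 0, 0, 0))
  expect_equal(unname(coef(fit$fit)), oracle, tolerance = 1e-6)
  expect_true(all(fit$p_trial > 0 & fit$p_trial < 1))
  # trial younger => membership decreases with age
  expect_lt(coef(fit$fit)["age"], 0)
})

test_that("no-signal stacking yields flat membership at the trial fraction", {
  set.seed(8)
  n <- 4000
  mk <- function(pref) toy_cohort(arm = rep("none", n),
                                  age = rnorm(n, 65, 7),
                                  prior_cvd = rbinom(n, 1, 0.4),
                                  subject_id = paste0(pref, seq_len(n)))
  fit <- fit_membership_lr(mk("a"), mk("b"),
                           covariates = c("age", "prior_cvd"))
  expect_true(all(abs(fit$p_trial - 0.5) < 0.05))
  b <- coef(fit$fit)[-1]
  se <- sqrt(diag(vcov(fit$fit)))[-1]
  expect_true(all(abs(b / se) < 4))
})

test_that("perfect separation is reported with the offending covariate", {
  trial <- toy_cohort(arm = rep("none", 20), age = 50 + seq_len(20))
  target <- toy_cohort(arm = rep("none", 20), age = 80 + seq_len(20),
                       subject_id = paste0("g", 1:20))
  expect_error(suppressWarnings(
    fit_membership_lr(trial, target, covariates = "age")), "age")
})

test_that("inverse odds weights follow (1-p)/p with clipping", {
  model <- structure(list(method = "LR",
                          p_trial = c(a = 0.5, b = 0.25, c = 0.8)),
                     class = "membership_model")
  trial <- toy_cohort(arm = rep("none", 3), subject_id = c("a", "b", "c"))
  ws <- inverse_odds_weights(model, trial)
  expect_equal(ws$w, c(1, 3, 0.25))
  expect_equal(unname(ws$summary["ess"]), effective_sample_size(c(1, 3, 0.25)))
  # boundary probability: error without clipping, clipped otherwise
  model$p_trial <- c(a = 1, b = 0.5, c = 0.5)
  expect_error(inverse_odds_weights(model, trial, clip = NULL), "0/1")
  clipped <- inverse_odds_weights(model, trial, clip = c(0.005, 0.995))
  expect_equal(clipped$n_clipped, 1L)
  expect_equal(clipped$w[1], (1 - 0.995) / 0.995)
})

test_that("Kish effective sample size closed forms", {
  expect_equal(effective_sample_size(rep(2.5, 7)), 7)
  expect_equal(effective_sample_size(c(1, 3)), 16 / 10)
  expect_equal(effective_sample_size(c(1, 1, 2)), 16 / 6)
  expect_error(effective_sample_size(numeric()), "empty")
  expect_error(effective_sample_size(c(1, -1)), "> 0")
})

test_that("weighted Cox equals the hand-written partial likelihood oracle", {
  # 8 subjects, distinct event times
  d <- toy_cohort(
    subject_id = sprintf("p%d", 1:8),
    arm = rep(c("treated", "control"), each = 4),
    time = c(1.1, 2.3, 3.7, 4.9, 0.8, 1.9, 2.6, 4.1),
    event = c(1, 0, 1, 1, 1, 1, 0, 1))
  x <- as.numeric(d$arm == "treated")
  est <- weighted_cox_hr(d)
  expect_equal(est$log_hr, oracle_cox_mle(d$time, d$event, x),
               tolerance = 1e-6)
  # weighted fit against the weighted oracle
  w <- c(1, 2, 1, 3, 1, 1, 2, 1)
  estw <- weighted_cox_hr(d, w)
  expect_equal(estw$log_hr, oracle_cox_mle(d$time, d$event, x, w),
               tolerance = 1e-6)
})

test_that("unit weights reproduce the unweighted fit; scale invariance holds", {
  coh <- make_exp_cohort(rate = 0.2, hr = 0.7, horizon = 5, n = 500, seed = 3)
  unw <- weighted_cox_hr(coh)
  w1 <- weighted_cox_hr(coh, rep(1, nrow(coh)))
  expect_equal(w1$log_hr, unw$log_hr, tolerance = 1e-8)
  w <- runif(nrow(coh), 0.5, 2)
  a <- weighted_cox_hr(coh, w)
  b <- weighted_cox_hr(coh, 17.3 * w)
  expect_equal(a$log_hr, b$log_hr, tolerance = 1e-8)
  expect_equal(effective_sample_size(w), effective_sample_size(17.3 * w),
               tolerance = 1e-12)
})

test_that("integer-weighted Cox equals row-replication Cox", {
  d <- toy_cohort(
    subject_id = sprintf("p%d", 1:6),
    arm = rep(c("treated", "control"), 3),
    time = c(1.2, 2.1, 3.3, 4.4, 5.1, 6.3),
    event = c(1, 1, 0, 1, 1, 0))
  k <- c(1, 3, 2, 1, 2, 1)
  # replication creates ties, so both fits use the Breslow approximation,
  # under which the weighted partial likelihood is exactly the replicated one
  west <- weighted_cox_hr(d, k, ties = "breslow")
  rep_df <- as.data.frame(d)[rep(seq_len(6), k), ]
  rep_df$subject_id <- paste0(rep_df$subject_id, "_", seq_len(nrow(rep_df)))
  rest <- weighted_cox_hr(cohort_table(rep_df, cohort_schema(d)),
                          ties = "breslow")
  expect_equal(west$log_hr, rest$log_hr, tolerance = 1e-8)
})

test_that("weight-by-treatment interaction flags degenerate weights", {
  coh <- make_exp_cohort(rate = 0.2, hr = 0.8, horizon = 5, n = 400, seed = 6)
  const <- weight_treatment_interaction(coh, rep(2, nrow(coh)))
  expect_true(const$degenerate)
  expect_equal(const$p_value, 1)
  varied <- weight_treatment_interaction(coh, runif(nrow(coh), 0.5, 2))
  expect_false(varied$degenerate)
  expect_true(varied$p_value >= 0 && varied$p_value <= 1)
})

test_that("transpose on no_shift collapses to the unweighted estimate", {
  b <- generate_scenario("no_shift", seed = 17,
                         n = c(trial_1 = 6000, trial_2 = 100, target = 6000,
                               rw = 100))
  res_lr <- transpose(b$trials$trial_1, b$target, method = "LR")
  expect_lt(abs(res_lr$transposed$log_hr - res_lr$unweighted$log_hr), 0.1)
  expect_gt(res_lr$transposed$ess, 0.5 * res_lr$unweighted$n)
  res_bn <- transpose(b$trials$trial_1, b$target, method = "BN",
                      settings = list(seed = 2, restarts = 2))
  expect_lt(abs(res_bn$transposed$log_hr - res_bn$unweighted$log_hr), 0.1)
})
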