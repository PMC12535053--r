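rw_cohort <- function(n = 2000, seed = 3, hr = 0.7) {
  sp <- scenario_preset("rw_validation", n = c(rw = n), seed = seed)
  sp$outcome$beta_treat <- log(hr)
  generate_scenario(sp, seed = seed)$rw
}

test_that("propensity model matches a brute-force logistic MLE", {
  coh <- toy_cohort(arm = c(rep("treated", 3), rep("control", 3)),
                    age = c(55, 72, 60, 66, 58, 80),
                    time = rep(1, 6), event = c(1, 0, 1, 0, 1, 0))
  ps <- estimate_propensity(coh, covariates = "age")
  oracle <- oracle_logistic_mle(X = coh$age,
                                y = as.numeric(coh$arm == "treated"))
  expect_equal(unname(coef(ps$fit)), oracle, tolerance = 1e-6)
  expect_true(all(ps$ps > 0 & ps$ps < 1))
  expect_error(estimate_propensity(coh, covariates = c("age", "pad")),
               "pad")   # constant column rejected by name
})

test_that("covariates independent of exposure give a flat propensity score", {
  set.seed(4)
  n <- 3000
  coh <- toy_cohort(arm = sample(c("treated", "control"), n, replace = TRUE),
                    age = rnorm(n, 70, 8), bmi = rnorm(n, 29, 4),
                    time = rexp(n) + 0.01, event = rbinom(n, 1, 0.2))
  ps <- estimate_propensity(coh, covariates = c("age", "bmi"))
  expect_true(all(abs(ps$ps - mean(coh$arm == "treated")) < 0.05))
})

test_that("nearest-neighbor matching: duplicates, brute force, contracts", {
  # pool containing an exact PS duplicate for every exposed subject (the
  # extra young controls make the PS informative, so scores are distinct)
  coh <- toy_cohort(
    subject_id = c(paste0("e", 1:4), paste0("c", 1:6)),
    arm = c(rep("treated", 4), rep("control", 6)),
    age = c(60, 65, 70, 75, 60, 65, 70, 75, 40, 45),
    time = rep(1, 10), event = rep(c(1, 0), 5))
  ps <- estimate_propensity(coh, covariates = "age")
  mt <- nn_match(ps, coh)
  expect_equal(nrow(mt$pairs), 4)
  expect_true(all(mt$pairs$distance < 1e-10))
  bal <- balance_report(coh, mt, covariates = "age")
  expect_true(bal$pass)
  expect_true(all(bal$table$smd_after < 1e-10))

  # 4 exposed vs 4 comparators with hand-listed scores: greedy order is
  # descending logit PS; verify each match is the pool nearest neighbour
  lp <- c(e1 = 0.9, e2 = 0.4, e3 = -0.2, e4 = -1.0,
          c1 = 1.0, c2 = 0.35, c3 = 0.3, c4 = -1.1)
  model <- structure(list(logit_ps = lp, ps = plogis(lp)),
                     class = "propensity_model")
  coh2 <- toy_cohort(subject_id = names(lp),
                     arm = rep(c("treated", "control"), each = 4),
                     time = rep(1, 8), event = rep(1, 8))
  got <- nn_match(model, coh2, with_replacement = TRUE)
  # brute force: for each exposed, the nearest comparator by |logit diff|
  nearest <- vapply(c("e1", "e2", "e3", "e4"), function(e) {
    cand <- lp[c("c1", "c2", "c3", "c4")]
    names(cand)[which.min(abs(cand - lp[e]))]
  }, "")
  expect_equal(got$pairs$comparator_id[match(names(nearest),
                                             got$pairs$exposed_id)],
               unname(nearest))
  # without replacement: e2 takes c2, so e3 must fall back to c3
  wor <- nn_match(model, coh2, with_replacement = FALSE)
  expect_equal(sort(wor$pairs$comparator_id),
               c("c1", "c2", "c3", "c4"))  # each comparator used once
  # more exposed than comparators without replacement is a hard error
  coh3 <- coh2; coh3$arm <- c(rep("treated", 5), rep("control", 3))
  model3 <- model
  expect_error(nn_match(model3, coh3, with_replacement = FALSE),
               "at least as many comparators")
  # caliper drops pairs beyond the distance bound
  tight <- nn_match(model, coh2, caliper = 0.01)
  expect_true(all(tight$pairs$distance <= 0.01 * sd(lp)))
  expect_true(length(tight$dropped) > 0)
})

test_that("standardized mean difference closed forms", {
  expect_equal(standardized_mean_difference(c(1, 2, 3), c(1, 2, 3)), 0)
  a <- rnorm(2000); b <- rnorm(2000) + 1
  smd <- standardized_mean_difference(a, b)
  expect_lt(abs(smd - 1), 0.1)
  expect_equal(
    standardized_mean_difference(rep(c(1, 0), c(50, 50)),
                                 rep(c(1, 0), c(30, 70)), "binary"),
    0.2 / sqrt((0.25 + 0.21) / 2), tolerance = 1e-12)
  expect_equal(round(0.2 / sqrt((0.25 + 0.21) / 2), 4), 0.4170)
  # zero pooled variance with unequal means
  expect_true(is.infinite(
    standardized_mean_difference(c(1, 1), c(0, 0), "binary")))
  expect_error(standardized_mean_difference(numeric(), 1), "non-empty")
})

test_that("empty covariate list yields a vacuous balance pass", {
  coh <- rw_cohort(n = 400, seed = 5)
  ps <- estimate_propensity(coh, covariates = c("age", "hba1c"))
  mt <- nn_match(ps, coh)
  bal <- balance_report(coh, mt, covariates = character())
  expect_equal(nrow(bal$table), 0)
  expect_true(bal$pass)
})

test_that("matching removes confounding and recovers the exposure effect", {
  coh <- rw_cohort(n = 6000, seed = 7, hr = 0.7)
  ps <- estimate_propensity(coh)
  raw <- weighted_cox_hr(coh)
  mt <- nn_match(ps, coh)
  bal <- balance_report(coh, mt)
  expect_true(mean(bal$table$smd_after < bal$table$smd_before) > 0.5)
  eff <- comparator_cox(coh, mt, tree = NULL)
  expect_equal(nrow(eff), 1)            # no tree: single overall row
  expect_lt(abs(eff$log_hr - log(0.7)), abs(raw$log_hr - log(0.7)) + 0.05)
})

test_that("matched analysis on exact clones equals the paired-cohort Cox", {
  set.seed(8)
  n <- 300
  base <- toy_cohort(arm = rep("treated", n),
                     age = rnorm(n, 70, 8),
                     time = rexp(n, 0.2) + 0.01,
                     event = rbinom(n, 1, 0.5),
                     subject_id = paste0("e", 1:n))
  clones <- as.data.frame(base)
  clones$subject_id <- paste0("c", 1:n)
  clones$arm <- "control"
  clones$time <- rexp(n, 0.3) + 0.01
  clones$event <- rbinom(n, 1, 0.5)
  # extra old controls keep the PS informative; every exposed subject still
  # has an exact-PS clone, which the matcher must pick at distance 0
  extras <- as.data.frame(toy_cohort(arm = rep("control", 100),
                                     age = rnorm(100, 90, 3),
                                     time = rexp(100, 0.3) + 0.01,
                                     event = rbinom(100, 1, 0.5),
                                     subject_id = paste0("x", 1:100)))
  coh <- cohort_table(rbind(as.data.frame(base), clones, extras))
  ps <- estimate_propensity(coh, covariates = "age")
  mt <- nn_match(ps, coh)
  expect_true(all(mt$pairs$distance < 1e-10))
  expect_setequal(mt$pairs$comparator_id, clones$subject_id)
  eff <- comparator_cox(coh, mt)
  direct <- weighted_cox_hr(cohort_table(rbind(as.data.frame(base), clones)))
  expect_equal(eff$log_hr, direct$log_hr, tolerance = 1e-6)
})
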