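test_that("ICC(A,1) matches an independent reference implementation", {
  # expected values frozen from an independent two-way random-effects
  # absolute-agreement single-measure ICC implementation on this fixture
  x <- c(10.914, 6.88, 12.251, 12.822, 4.147, 6.093, 10.384, 9.051)
  y <- c(10.897, 6.027, 13.13, 13.6, 4.213, 7.22, 10.852, 8.192)
  r <- icc_agreement(x, y)$table
  expect_equal(r$estimate, 0.9742261543, tolerance = 1e-8)
  expect_equal(r$p, 5.3685372e-06, tolerance = 1e-6)
  expect_equal(round(r$lo, 2), 0.89)
  expect_equal(round(r$hi, 2), 0.99)
})

test_that("ICC is 1 for identical vectors and tracks the variance components", {
  x <- c(3, 9, 4.5, 12, 7, 1)
  expect_equal(icc_agreement(x, x)$table$estimate, 1)
  # between-SD 1, noise-SD 1 on both raters -> ICC ~ 0.5
  set.seed(31)
  subj <- rnorm(3000)
  icc <- icc_agreement(subj + rnorm(3000), subj + rnorm(3000))$table$estimate
  expect_equal(icc, 0.5, tolerance = 0.05)
  # symmetry and shift invariance
  a <- subj + rnorm(3000, 0, 0.3)
  b <- subj + rnorm(3000, 0, 0.3)
  expect_equal(icc_agreement(a, b)$table$estimate,
               icc_agreement(b, a)$table$estimate)
  expect_equal(icc_agreement(a + 50, b + 50)$table$estimate,
               icc_agreement(a, b)$table$estimate)
  expect_error(icc_agreement(1:4, 1:5), "length")
  expect_error(icc_agreement(rep(1, 5), rep(1, 5)), "zero total variance")
})

test_that("agreement bands follow the printed boundaries", {
  expect_equal(classify_agreement(0.98), "excellent")
  expect_equal(classify_agreement(0.81), "excellent")
  expect_equal(classify_agreement(0.80), "substantial")
  expect_equal(classify_agreement(0.61), "substantial")
  expect_equal(classify_agreement(0.60), "moderate")
  expect_equal(classify_agreement(0.53), "moderate")
  expect_equal(classify_agreement(0.41), "moderate")
  expect_equal(classify_agreement(0.40), "fair")
  expect_equal(classify_agreement(0.21), "fair")
  expect_equal(classify_agreement(0.20), "poor")
  expect_equal(classify_agreement(-0.3), "poor")
  expect_error(classify_agreement(1.2), "exceed")
})

test_that("univariate logistic odds ratios behave under the null and rescale correctly", {
  set.seed(5)
  n <- 2000
  co <- data.frame(recurrence = rbinom(n, 1, 0.2), x = rnorm(n, 0, 10))
  r <- univariate_logistic(co, "x")$table
  expect_gt(1, r$lo)
  expect_lt(1, r$hi)
  # doubling the scale squares the OR
  r1 <- univariate_logistic(co, "x", scale = 1)$table
  r2 <- univariate_logistic(co, "x", scale = 2)$table
  expect_equal(r2$estimate, r1$estimate^2)
  expect_error(univariate_logistic(data.frame(recurrence = rep(1, 10), x = 1:10), "x"),
               "single class")
})

test_that("forward-conditional selection finds informative terms and skips noise", {
  # empty candidate set -> intercept-only with a note
  co <- data.frame(recurrence = rbinom(50, 1, 0.4))
  r0 <- forward_conditional_logistic(co, character(0))
  expect_equal(r0$table$term, "(Intercept)")
  expect_match(r0$notes, "intercept-only")
  # one informative predictor (true OR 2 per SD) among five noise columns:
  # the signal is (almost) always selected, and noise enters at about the
  # nominal per-candidate score-test rate, i.e. well under one term per run
  runs <- lapply(1:100, function(i) {
    set.seed(400 + i)
    n <- 1000
    x <- rnorm(n)
    noise <- matrix(rnorm(n * 5), n)
    y <- rbinom(n, 1, plogis(-1.5 + log(2) * x))
    dat <- data.frame(y = y, signal = x, noise)
    names(dat)[3:7] <- paste0("n", 1:5)
    forward_conditional_logistic(dat, c("signal", paste0("n", 1:5)),
                                 outcome = "y")$table$term
  })
  signal_rate <- mean(vapply(runs, function(s) "signal" %in% s, logical(1)))
  noise_count <- mean(vapply(runs, function(s) sum(grepl("^n[0-9]$", s)),
                             numeric(1)))
  expect_gte(signal_rate, 0.95)
  expect_lt(noise_count, 0.6) # nominal expectation ~ 5 * p_enter = 0.25/step
})

test_that("the stepwise trace is reproducible and ordered by entry strength", {
  co <- simulate_cohort(cohort_spec(n = 800, seed = 55))
  cands <- c("area_mm2_1mm", "mean_attenuation_hu_1mm", "circularity_1mm",
             "skewness_1mm")
  r1 <- forward_conditional_logistic(co, cands)
  r2 <- forward_conditional_logistic(co, cands)
  expect_identical(r1$trace, r2$trace)
  expect_true(all(c("area_mm2_1mm", "mean_attenuation_hu_1mm") %in% r1$table$term))
  expect_true(all(r1$trace$p[r1$trace$action == "enter"] < 0.05))
})

test_that("AUC equals the concordant-pair fraction and handles edge cases", {
  y <- c(rep(0, 6), rep(1, 4))
  s <- c(1:6, 7:10)
  expect_equal(roc_cindex(s, y)$table$estimate, 1) # perfect separation
  set.seed(13)
  for (i in 1:5) {
    n <- sample(10:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4)) # force both classes
    s <- round(rnorm(n), 1)             # ties occur
    expect_equal(roc_cindex(s, y)$table$estimate, auc_pair_fraction(s, y))
  }
  set.seed(3)
  y <- rbinom(2000, 1, 0.5)
  s <- rnorm(2000)
  expect_equal(roc_cindex(s, y)$table$estimate, 0.5, tolerance = 0.06)
  expect_error(roc_cindex(rnorm(5), rep(1, 5)), "single class")
})

test_that("a nested two-variable model never scores below its single variables in-sample", {
  co <- simulate_cohort(cohort_spec(n = 600, seed = 44))
  f2 <- glm(recurrence ~ area_mm2_1mm + mean_attenuation_hu_1mm,
            family = binomial(), data = co)
  auc2 <- roc_cindex(predict(f2), co$recurrence)$table$estimate
  for (v in c("area_mm2_1mm", "mean_attenuation_hu_1mm")) {
    f1 <- glm(reformulate(v, "recurrence"), family = binomial(), data = co)
    auc1 <- roc_cindex(predict(f1), co$recurrence)$table$estimate
    expect_gte(auc2, auc1 - 0.005)
  }
})

test_that("group comparisons reproduce the cohort-table tests", {
  # identical groups: t = 0, Fisher p = 1
  co <- data.frame(recurrence = rep(c(0, 1), each = 20),
                   v = rep(rnorm(20), 2),
                   cat = rep(rep(c("a", "b"), 10), 2))
  t_res <- group_compare(co, "v")
  expect_equal(t_res$statistic, 0, tolerance = 1e-10)
  f_res <- group_compare(co, "cat", method = "fisher")
  expect_equal(f_res$p, 1)
  # the 2x2 stage table: Pearson chi-square ~ 6.56, p prints as 0.01
  stage <- data.frame(
    recurrence = rep(c(0, 1), times = c(169, 25)),
    stage = c(rep(1, 156), rep(2, 13), rep(1, 19), rep(2, 6))
  )
  chi <- group_compare(stage, "stage", method = "chisq")
  expect_equal(chi$statistic, 6.5557, tolerance = 1e-4)
  expect_equal(round(chi$p, 2), 0.01)
  # auto rule switches to Fisher when an expected cell dips below 5
  auto <- group_compare(stage, "stage")
  expect_equal(auto$method, "fisher")
  # label swap leaves p unchanged
  swapped <- stage; swapped$recurrence <- 1 - swapped$recurrence
  expect_equal(group_compare(swapped, "stage", method = "chisq")$p, chi$p)
})

test_that("Cox regression recovers hazards and matches a hand-computed partial likelihood", {
  # null predictor -> HR ~ 1
  set.seed(61)
  n <- 2000
  co <- data.frame(time_years = rexp(n), event_observed = rbinom(n, 1, 0.7),
                   x = rnorm(n))
  r <- cox_univariate(co, "x")$table
  expect_gt(1, r$lo); expect_lt(1, r$hi)
  # exponential survival, true log-HR 0.7 per SD, ~30% censoring
  set.seed(62)
  x <- rnorm(1000)
  t_event <- rexp(1000, rate = 0.2 * exp(0.7 * x))
  cens <- rexp(1000, rate = 0.08)
  co2 <- data.frame(time_years = pmin(t_event, cens),
                    event_observed = as.integer(t_event <= cens), x = x)
  r2 <- cox_univariate(co2, "x")$table
  expect_gt(exp(0.7), r2$lo); expect_lt(exp(0.7), r2$hi)
  # two patients, distinct event times, binary covariate: the partial
  # likelihood enumerates to e^b/(e^b + 1) for the first event times 1 for the
  # second; check the evaluated log partial likelihood at a fixed coefficient
  co3 <- data.frame(time_years = c(1, 2), event_observed = c(1, 1), x = c(1, 0))
  fit0 <- survival::coxph(survival::Surv(time_years, event_observed) ~ x,
                          data = co3, init = 0.5,
                          control = survival::coxph.control(iter.max = 0))
  expect_equal(unname(fit0$loglik[2]), 0.5 - log(exp(0.5) + 1))
  expect_error(cox_univariate(data.frame(time_years = 1:3,
                                         event_observed = c(0, 0, 0),
                                         x = 1:3), "x"),
               "no observed events")
})

test_that("logistic OR is equivariant under predictor rescaling", {
  co <- simulate_cohort(cohort_spec(n = 500, seed = 90))
  co$area_scaled <- co$area_mm2_1mm / 100 # per cm^2
  r_mm <- univariate_logistic(co, "area_mm2_1mm")$table
  r_cm <- univariate_logistic(co, "area_scaled")$table
  expect_equal(r_cm$estimate, r_mm$estimate^100, tolerance = 1e-4)
  r_scaled <- univariate_logistic(co, "area_mm2_1mm", scale = 100)$table
  expect_equal(r_scaled$estimate, r_cm$estimate, tolerance = 1e-4)
})
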