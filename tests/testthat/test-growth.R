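test_that("AICc matches its closed form, its limits, and guards small n", {
  expect_equal(aicc(-100, 3, 30), 206 + 24 / 26)
  expect_equal(aicc(-100, 0, 30), 200)
  # large-n limit approaches plain AIC
  expect_equal(aicc(-100, 3, 1e9), 206, tolerance = 1e-6)
  expect_error(aicc(-100, 3, 4), "n must exceed")
})

test_that("the likelihood-ratio test reproduces the published chi-square tail values", {
  expect_equal(pchisq(19.1, 2, lower.tail = FALSE), 7.1e-5,
               tolerance = 0.01)
  expect_equal(pchisq(11.46, 2, lower.tail = FALSE), 3.2e-3,
               tolerance = 0.01)

  gd <- simulate_growth_data(seed = 151)
  m1 <- fit_growth(gd, character(0), "1")
  m2 <- fit_growth(gd, "age_c", "1")
  r <- lrt(m1, m2)
  expect_gte(r$delta_m2ll, 0)
  expect_equal(r$delta_df, 1)
  expect_equal(r$p, pchisq(r$delta_m2ll, 1, lower.tail = FALSE))

  # identical models: zero difference, p = 1
  r0 <- lrt(m1, m1)
  expect_equal(r0$delta_m2ll, 0)
  expect_equal(r0$p, 1)
  # reversed arguments raise
  expect_error(lrt(m2, m1), "lower likelihood")
})

test_that("random-slope addition is tested on 2 df", {
  gd <- simulate_growth_data(seed = 152, rs_sd = 0.08)
  m_ri <- fit_growth(gd, "age_c", "1")
  m_rs <- fit_growth(gd, "age_c", c("1", "age_c"))
  r <- lrt(m_ri, m_rs)
  expect_equal(r$delta_df, 2)
})

test_that("degenerate growth data produce exact fits", {
  # balanced data with no slope: the intercept is the sample mean
  set.seed(153)
  ids <- rep(sprintf("P%02d", 1:30), each = 4)
  age <- rep(c(-6, -2, 2, 6), 30)
  y <- rnorm(30)[match(ids, unique(ids))] + rnorm(120, 0, 0.5)
  gd <- data.frame(participant_id = ids, age_months = age + 18,
                   age_c = age, sex = 0, cohort = 0, outcome = y)
  m <- fit_growth(gd, character(0), "1")
  expect_equal(m$fixed$estimate[1], mean(y), tolerance = 1e-6)

  # noiseless lines: slope exact, residual variance at zero
  yd <- 1 - 0.11 * age + 0.3 * rnorm(30)[match(ids, unique(ids))]
  gd2 <- gd; gd2$outcome <- yd
  m2 <- fit_growth(gd2, "age_c", "1")
  expect_equal(m2$fixed$estimate[m2$fixed$term == "age_c"], -0.11,
               tolerance = 1e-6)
  expect_lt(m2$sigma2, 1e-6)
})

test_that("adding fixed effects never decreases the ML log-likelihood", {
  gd <- simulate_growth_data(seed = 154)
  lls <- c(fit_growth(gd, character(0), "1")$loglik,
           fit_growth(gd, "age_c", "1")$loglik,
           fit_growth(gd, c("age_c", "I(age_c^2)"), "1")$loglik,
           fit_growth(gd, c("age_c", "I(age_c^2)", "sex"), "1")$loglik)
  expect_true(all(diff(lls) > -1e-6))
})

test_that("the taxonomy selects the generating functional form", {
  # linear truth: the quadratic term should be rejected
  forms <- vapply(1:5, function(r) {
    taxonomy_search(simulate_growth_data(seed = 160 + r))$form
  }, "")
  expect_gte(sum(forms == "linear"), 4)

  # detectable curvature is recovered as a quadratic even when the
  # linear trend is flat (the higher-order pattern: near-zero slope,
  # real curvature)
  formsq <- vapply(1:5, function(r) {
    gd <- simulate_growth_data(seed = 170 + r, slope = -0.002,
                               quad = -0.004)
    taxonomy_search(gd)$form
  }, "")
  expect_gte(sum(formsq == "quadratic"), 4)

  # absent covariate effects are almost always dropped: across 5 null
  # replicates at most a small minority of the 20 candidate covariate
  # tests may survive by chance
  kept <- 0
  for (r in 1:5) {
    tx0 <- taxonomy_search(simulate_growth_data(seed = 180 + r))
    kept <- kept + sum(!tx0$best$fixed_terms %in% c("age_c", "I(age_c^2)"))
  }
  expect_lte(kept, 3)
})

test_that("sex effects on intercept and slope are picked up when generated", {
  gd <- simulate_growth_data(seed = 181, beta_sex = 0.4,
                             beta_sex_age = -0.034)
  tx <- taxonomy_search(gd)
  expect_true("sex" %in% tx$best$fixed_terms)
})

test_that("within-person SD scaling matches the published arithmetic", {
  gd <- simulate_growth_data(seed = 182)
  fit <- fit_growth(gd, "age_c", c("1", "age_c"))
  # manufactured check: slope -0.11 over 29 months against residual SD
  # 1.06 is about 3 SD
  fit2 <- fit
  fit2$fixed$estimate[fit2$fixed$term == "age_c"] <- -0.11
  fit2$sigma2 <- 1.06^2
  expect_equal(effect_in_within_person_sd(fit2, 29), 0.11 * 29 / 1.06,
               tolerance = 1e-10)
  expect_equal(effect_in_within_person_sd(fit2, 29), 3.0, tolerance = 0.02)

  # zero slope scales to zero; doubling the residual SD halves the value
  fit0 <- fit2
  fit0$fixed$estimate[fit0$fixed$term == "age_c"] <- 0
  expect_equal(effect_in_within_person_sd(fit0, 29), 0)
  fit3 <- fit2; fit3$sigma2 <- 4 * fit2$sigma2
  expect_equal(effect_in_within_person_sd(fit3, 29),
               effect_in_within_person_sd(fit2, 29) / 2)
  fitz <- fit2; fitz$sigma2 <- 0
  expect_error(effect_in_within_person_sd(fitz, 29), "zero residual")
})

test_that("variance explained is the squared correlation of conditional predictions", {
  gd <- simulate_growth_data(seed = 183)
  fit <- fit_growth(gd, "age_c", c("1", "age_c"))
  r2 <- variance_explained(fit)
  expect_gte(r2, 0); expect_lte(r2, 1)
  expect_equal(r2, cor(predict(fit$model), gd$outcome)^2)

  # a perfect fit gives 1
  gdp <- gd; gdp$outcome <- 1 + 0.2 * gdp$age_c
  # tiny jitter so lmer does not degenerate completely
  set.seed(1); gdp$outcome <- gdp$outcome + rnorm(nrow(gdp), 0, 1e-6)
  fitp <- fit_growth(gdp, "age_c", "1")
  expect_gte(variance_explained(fitp), 0.999)
})
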