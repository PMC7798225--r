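design4 <- moderator_design()

test_that("item probabilities and structural moments match closed forms", {
  p <- mnlfa_params(c("a", "b"), design4$covariates)
  expect_equal(item_prob(p, 1, eta = 0), 0.5)

  p$kappa["a", "age_c"] <- 1
  expect_equal(item_prob(p, "a", eta = 0, x = c(age_c = 1)), plogis(1),
               tolerance = 1e-10)

  # loading DIF shifts the slope on eta: logistic(1 - 0.294)
  q <- mnlfa_params("m", design4$covariates)
  q$delta["m", "age_c"] <- -0.147
  expect_equal(item_prob(q, "m", eta = 1, x = c(age_c = 2)),
               plogis(1 - 0.294), tolerance = 1e-10)
  expect_equal(unname(item_prob(q, "m", eta = 1, x = c(age_c = 2))), 0.6695,
               tolerance = 1e-3)

  # identification constraint at the reference
  r <- mnlfa_params("i", design4$covariates)
  r$gamma["age_c"] <- -0.107
  r$omega["age_c"] <- 0.068
  expect_equal(structural_moments(r), c(alpha = 0, psi = 1))
  m1 <- structural_moments(r, c(age_c = 1))
  expect_equal(unname(m1["alpha"]), -0.107)
  expect_equal(unname(m1["psi"]), exp(0.068))
  expect_equal(unname(m1["psi"]), 1.0704, tolerance = 1e-4)
})

test_that("probabilities and variances stay in range over random parameter draws", {
  set.seed(77)
  for (rep in 1:50) {
    p <- mnlfa_params(paste0("i", 1:3), design4$covariates,
                      nu0 = rnorm(3, 0, 3), lambda0 = rnorm(3, 0, 2),
                      kappa = matrix(rnorm(12, 0, 1), 3),
                      delta = matrix(rnorm(12, 0, 1), 3),
                      gamma = rnorm(4, 0, 0.5), omega = rnorm(4, 0, 0.3))
    x <- c(age_c = runif(1, -10, 19), sex = rbinom(1, 1, 0.5),
           cohort = rbinom(1, 1, 0.5))
    x["age_x_cohort"] <- x["age_c"] * x["cohort"]
    eta <- rnorm(1, 0, 3)
    sm <- structural_moments(p, x)
    expect_gt(sm["psi"], 0)
    for (j in 1:3) {
      pr <- item_prob(p, j, eta, x)
      expect_gt(pr, 0); expect_lt(pr, 1)
    }
  }
})

test_that("marginal log-likelihood matches the dense-grid oracle and is additive", {
  p <- mnlfa_params(paste0("i", 1:5), design4$covariates,
                    nu0 = seq(-1.2, 0.4, length.out = 5), lambda0 = 1,
                    gamma = c(-0.107, 0, 0, 0), omega = c(0.068, 0, 0, 0))
  p$delta["i1", "age_c"] <- -0.147
  sim <- simulate_calibration(p, design4, 50, seed = 61)
  ll <- marginal_loglik(p, sim$table, design4, quad_points = 101)
  llo <- oracle_ll_1d(p, sim$table, design4)
  expect_lt(abs(ll - llo), 1e-6)

  # node count marches monotonically toward the oracle
  errs <- sapply(c(21, 41, 81), function(q)
    abs(marginal_loglik(p, sim$table, design4, quad_points = q) - llo))
  expect_true(all(diff(errs) < 0))

  # duplicating every row doubles the log-likelihood exactly
  df2 <- rbind(as.data.frame(sim$table), as.data.frame(sim$table))
  tab2 <- response_table(df2, attr(sim$table, "item_map"), "binary")
  expect_equal(marginal_loglik(p, tab2, design4, quad_points = 101),
               2 * ll, tolerance = 1e-10)
})

test_that("with all loadings zero the likelihood collapses to independent Bernoullis", {
  p <- mnlfa_params(paste0("i", 1:4), design4$covariates,
                    nu0 = c(-1, -0.5, 0, 0.5), lambda0 = 0,
                    gamma = c(-0.1, 0, 0, 0))
  p$kappa["i2", "age_c"] <- 0.05
  sim <- simulate_calibration(p, design4, 40, seed = 62)
  x <- covariate_matrix(sim$table, design4)
  y <- as.matrix(as.data.frame(sim$table)[p$items])
  nux <- matrix(p$nu0, 40, 4, byrow = TRUE) + x %*% t(p$kappa)
  closed <- sum(ifelse(y == 1, plogis(nux, log.p = TRUE),
                       plogis(-nux, log.p = TRUE)), na.rm = TRUE)
  for (q in c(3, 21)) {
    expect_equal(marginal_loglik(p, sim$table, design4, quad_points = q),
                 closed, tolerance = 1e-9)
  }
})

test_that("fit_mnlfa recovers generating parameters and is a fixed point", {
  p <- mnlfa_params(paste0("i", 1:6), design4$covariates,
                    nu0 = seq(-1.5, 1, length.out = 6), lambda0 = 1)
  sim <- simulate_calibration(p, design4, 2000, seed = 63)
  fit <- fit_mnlfa(sim$table, design4)
  expect_true(fit$converged)
  # every estimate within 3 reported SEs of truth
  expect_true(all(abs(fit$params$nu0 - p$nu0) < 3 * fit$se$nu0))
  expect_true(all(abs(fit$params$lambda0 - p$lambda0) < 3 * fit$se$lambda0))

  # refit from the fitted point reproduces the optimum
  fit2 <- fit_mnlfa(sim$table, design4, mask = fit$mask, init = fit$params,
                    se = FALSE)
  expect_lt(abs(fit2$loglik - fit$loglik), 1e-6 * abs(fit$loglik))
})

test_that("a single-item model with frozen loading yields the logit endorsement rate", {
  map <- item_map("solo", "restricted")
  set.seed(64)
  df <- data.frame(participant_id = sprintf("P%03d", 1:200),
                   age_months = runif(200, 8, 36), sex = 0, cohort = 0,
                   solo = rbinom(200, 1, 0.35))
  tab <- response_table(df, map, "binary")
  init <- mnlfa_params("solo", design4$covariates, nu0 = 0, lambda0 = 0)
  mask <- param_mask(init, lambda0 = FALSE)
  fit <- fit_mnlfa(tab, design4, mask, init = init)
  expect_equal(unname(fit$params$nu0), qlogis(mean(df$solo)),
               tolerance = 5e-3)
})

test_that("quasi-separated items are frozen with a warning, not an error", {
  map <- item_map(c("ok", "always"), c("restricted", "restricted"))
  set.seed(65)
  df <- data.frame(participant_id = sprintf("P%03d", 1:100),
                   age_months = runif(100, 8, 36), sex = 0, cohort = 0,
                   ok = rbinom(100, 1, 0.4), always = 1)
  tab <- response_table(df, map, "binary")
  expect_warning(fit <- fit_mnlfa(tab, design4), "quasi-separated")
  expect_identical(fit$frozen_items, "always")
})

test_that("Wald z arithmetic matches the reported-scale magnitudes", {
  # estimate 0.107 with SE 0.017 gives z about 6.29 and p < 1e-9
  z <- 0.107 / 0.017
  expect_equal(z, 6.294, tolerance = 1e-3)
  expect_lt(2 * pnorm(-abs(z)), 1e-9)

  # a parameter estimated at exactly 0 is reported with p = 1
  p <- mnlfa_params(paste0("i", 1:4), design4$covariates, nu0 = -0.5)
  sim <- simulate_calibration(p, design4, 300, seed = 66)
  fit <- fit_mnlfa(sim$table, design4)
  wt <- wald_tests(fit)
  expect_true(all(wt$p >= 0 & wt$p <= 1))
  expect_named(wt, c("parameter", "block", "item", "covariate", "estimate",
                     "se", "z", "p"))
})

test_that("Wald p-values for a null DIF effect are uniform", {
  # 200 refits under a fully invariant generating model; the scanned
  # loading-DIF p-value should be U(0,1)
  p <- mnlfa_params(paste0("i", 1:5), design4$covariates,
                    nu0 = seq(-1, 0, length.out = 5))
  mask <- param_mask(p)
  mask$delta["i1", "age_c"] <- TRUE
  pvals <- vapply(1:200, function(r) {
    sim <- simulate_calibration(p, design4, 300, seed = 7000 + r)
    fit <- fit_mnlfa(sim$table, design4, mask)
    wt <- wald_tests(fit)
    wt$p[wt$block == "loading"]
  }, 0)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("EAP scores match the dense-grid posterior and respect monotonicity", {
  p <- mnlfa_params(paste0("i", 1:6), design4$covariates,
                    nu0 = seq(-1.2, 0.3, length.out = 6), lambda0 = 1,
                    gamma = c(-0.107, 0, 0, 0), omega = c(0.068, 0, 0, 0))
  sim <- simulate_calibration(p, design4, 40, seed = 67)
  df <- as.data.frame(sim$table)
  df$i3[5] <- NA                       # partial missingness
  df[10, p$items] <- NA                # fully missing row
  tab <- response_table(df, attr(sim$table, "item_map"), "binary")

  sc <- eap_scores(p, tab, design4, quad_points = 101)
  orc <- oracle_eap_1d(p, tab, design4)
  expect_lt(max(abs(sc$eta - orc[, "eta"])), 1e-6)
  expect_lt(max(abs(sc$eta_sd - orc[, "sd"])), 1e-6)
  expect_true(all(sc$eta_sd > 0))
  expect_equal(nrow(sc), nrow(tab))

  # row with no observed items scores at the prior
  x10 <- covariate_matrix(tab, design4)[10, ]
  expect_equal(sc$eta[10], sum(p$gamma * x10), tolerance = 1e-8)
  expect_equal(sc$eta_sd[10], exp(0.5 * sum(p$omega * x10)),
               tolerance = 1e-8)

  # endorsing a superset of positively-loaded items cannot lower the score
  df2 <- df[1:2, ]
  df2$participant_id <- c("A", "B")
  df2$age_months <- 18; df2$sex <- 0; df2$cohort <- 0
  df2[1, p$items] <- c(1, 0, 0, 0, 0, 0)
  df2[2, p$items] <- c(1, 1, 1, 0, 0, 0)
  sc2 <- eap_scores(p, response_table(df2, attr(sim$table, "item_map"),
                                      "binary"), design4)
  expect_gte(sc2$eta[2], sc2$eta[1])
})
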