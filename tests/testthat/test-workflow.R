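design4 <- moderator_design()

# One synthetic cohort and one full pipeline run shared across the tests
# in this file.
gen_wf <- generate_cohort(generator_config(), seed = 101)
rm_tab <- subscale_view(gen_wf$table, "repetitive_motor")
calib_wf <- draw_calibration_sample(rm_tab, 7)
pipe_wf <- finalize_and_score(rm_tab, calib_wf, design4)

test_that("the calibration sampler picks one age-balanced visit per participant", {
  expect_equal(nrow(calib_wf), 180)
  expect_false(anyDuplicated(calib_wf$participant_id) > 0)
  # deterministic given the seed
  again <- draw_calibration_sample(rm_tab, 7)
  expect_identical(as.data.frame(again), as.data.frame(calib_wf))
  # age distribution similar to the full sample
  expect_lt(abs(mean(calib_wf$age_months) - mean(rm_tab$age_months)), 2)

  # single-visit participants are forced through unchanged
  one <- rm_tab[!duplicated(rm_tab$participant_id), , drop = FALSE]
  attr(one, "item_map") <- attr(rm_tab, "item_map")
  attr(one, "response_scale") <- "binary"
  class(one) <- c("response_table", "data.frame")
  forced <- draw_calibration_sample(one, 3)
  expect_equal(sort(paste(forced$participant_id, forced$age_months)),
               sort(paste(one$participant_id, one$age_months)))

  # two seeds share some but not all rows
  c2 <- draw_calibration_sample(rm_tab, 8)
  overlap <- mean(paste(calib_wf$participant_id, calib_wf$age_months) %in%
                    paste(c2$participant_id, c2$age_months))
  expect_gte(overlap, 0.2); expect_lte(overlap, 0.6)
})

test_that("the impact stage retains the generated age effect and honours empty designs", {
  tr <- pipe_wf$trace
  imp <- tr[tr$stage == "impact", ]
  expect_setequal(imp$block, c("mean", "variance"))
  expect_equal(sum(imp$block == "mean"), 4)   # age, sex, cohort, age x cohort
  expect_equal(sum(imp$block == "variance"), 1)
  expect_true(imp$retained[imp$block == "mean" & imp$covariate == "age_c"])

  # design with no candidate moderators: plain 2PL, empty trace
  d0 <- moderator_design(mean_covariates = character(0),
                         var_covariates = character(0),
                         dif_covariates = character(0))
  imp0 <- fit_impact_model(calib_wf, d0)
  expect_equal(nrow(imp0$trace), 0)
  expect_length(imp0$fit$free, 18)  # 9 intercepts + 9 loadings
})

test_that("impact retention rate under a null generating model is near the nominal 10%", {
  p <- mnlfa_params(paste0("i", 1:5), design4$covariates,
                    nu0 = seq(-1, 0, length.out = 5))
  hits <- 0; total <- 0
  for (r in 1:50) {
    sim <- simulate_calibration(p, design4, 300, seed = 8000 + r)
    imp <- fit_impact_model(sim$table, design4)
    hits <- hits + sum(imp$trace$retained)
    total <- total + nrow(imp$trace)
  }
  rate <- hits / total
  expect_gte(rate, 0.03); expect_lte(rate, 0.18)
})

test_that("the impact stage detects an age effect of the published magnitude", {
  p <- mnlfa_params(paste0("i", 1:9), design4$covariates,
                    nu0 = seq(-1.4, -0.1, length.out = 9),
                    gamma = c(-0.107, 0, 0, 0))
  kept <- vapply(1:5, function(r) {
    sim <- simulate_calibration(p, design4, 1000, seed = 8100 + r)
    imp <- fit_impact_model(sim$table, design4)
    imp$trace$retained[imp$trace$block == "mean" &
                         imp$trace$covariate == "age_c"]
  }, TRUE)
  expect_gte(sum(kept), 4)
})

test_that("the DIF scan flags a strong loading-DIF effect and guards small item sets", {
  p <- mnlfa_params(paste0("i", 1:9), design4$covariates,
                    nu0 = seq(-1.4, -0.1, length.out = 9))
  p$delta["i4", "age_c"] <- -0.303
  hits <- vapply(1:5, function(r) {
    sim <- simulate_calibration(p, design4, 1000, seed = 8200 + r)
    imp <- fit_impact_model(sim$table, design4)
    sc <- scan_item_dif(sim$table, design4, imp$trace)
    sc$p[sc$item == "i4" & sc$block == "loading" &
           sc$covariate == "age_c"] < 0.05
  }, TRUE)
  expect_gte(sum(hits), 4)

  small <- subscale_view(gen_wf$table, "self_directed")
  two <- item_map(paste0("sd_0", 1:2), rep("self_directed", 2))
  df <- as.data.frame(small)[c("participant_id", "age_months", "sex",
                               "cohort", names(two))]
  expect_error(scan_item_dif(response_table(df, two, "binary"), design4,
                             pipe_wf$trace[0, ]), "< 3 items")
})

test_that("trimming refits survivors simultaneously and rejects duplicates", {
  tr <- pipe_wf$trace
  trim <- tr[tr$stage == "trim", ]
  cand <- tr[tr$stage %in% c("impact", "dif_scan"), ]
  surv <- cand[!is.na(cand$p) & cand$p < 0.05, ]
  expect_setequal(paste(trim$block, trim$item, trim$covariate),
                  paste(surv$block, surv$item, surv$covariate))

  dup <- rbind(surv[1, ], surv[1, ])
  expect_error(trim_and_refit(calib_wf, design4, dup), "duplicate")

  # no survivors: a plain unmoderated model comes back
  none <- surv[0, ]
  plain <- trim_and_refit(calib_wf, design4, none)
  expect_equal(nrow(plain$trace), 0)
  expect_length(plain$fit$free, 18)
})

test_that("Benjamini-Hochberg step-up matches its enumerated cases and p.adjust", {
  expect_equal(bh_correct(c(0.01, 0.02, 0.04), 0.05), 1:3)
  expect_equal(bh_correct(c(0.04, 0.8, 0.9), 0.05), integer(0))
  expect_equal(bh_correct(0.001, 0.05), 1L)
  expect_equal(bh_correct(numeric(0)), integer(0))

  # agreement with stats::p.adjust over random draws, and the retained
  # set never exceeds the unadjusted p < alpha set
  set.seed(9)
  for (r in 1:25) {
    pv <- runif(sample(1:12, 1))^sample(1:3, 1)
    got <- bh_correct(pv, 0.05)
    ref <- which(p.adjust(pv, "BH") <= 0.05)
    expect_equal(got, ref)
    expect_true(all(got %in% which(pv < 0.05)))
  }
})

test_that("the final model scores every longitudinal row and recovers the latent trend", {
  expect_equal(nrow(pipe_wf$scores), nrow(rm_tab))
  truth_eta <- gen_wf$truth$eta$eta_repetitive_motor
  expect_gte(cor(pipe_wf$scores$eta, truth_eta), 0.8)
  expect_gte(score_vs_raw_mean(pipe_wf$scores, rm_tab), 0.85)

  # scoring the calibration set as the "full" table is consistent
  res_c <- finalize_and_score(calib_wf, calib_wf, design4)
  keys <- paste(calib_wf$participant_id, calib_wf$age_months)
  full_keys <- paste(rm_tab$participant_id, rm_tab$age_months)
  expect_equal(res_c$scores$eta,
               pipe_wf$scores$eta[match(keys, full_keys)],
               tolerance = 1e-6)

  # affine scores correlate perfectly with raw means; zero-variance
  # raw means are rejected
  raw <- rowMeans(as.data.frame(rm_tab)[names(attr(rm_tab, "item_map"))])
  fake <- pipe_wf$scores
  fake$eta <- 2 * raw - 1
  expect_equal(score_vs_raw_mean(fake, rm_tab), 1)
  flat <- rm_tab
  flat[names(attr(rm_tab, "item_map"))] <- 0
  expect_error(score_vs_raw_mean(pipe_wf$scores, flat), "zero-variance")
})

test_that("the pipeline is deterministic and returns a well-formed trace", {
  rerun <- finalize_and_score(rm_tab, calib_wf, design4)
  expect_identical(rerun$trace, pipe_wf$trace)
  expect_equal(rerun$scores$eta, pipe_wf$scores$eta)
  expect_true(all(pipe_wf$trace$stage %in%
                    c("impact", "dif_scan", "trim", "final")))
  # retained sets are subsets of their stage's candidates
  tt <- pipe_wf$trace[pipe_wf$trace$stage == "trim", ]
  expect_true(all(tt$retained %in% c(TRUE, FALSE)))
})

test_that("identical calibration seeds give identical scores", {
  r <- stability_check(rm_tab, 7, 7, design4)
  expect_equal(as.numeric(r), 1, tolerance = 1e-12)
})
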