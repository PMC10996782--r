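test_that("extreme agents behave deterministically on the default set", {
  tr <- default_trials()
  # alpha -> 0 is the deterministic value-maximizer limit
  impatient <- simulate_agent_choices(
    list(log_k = 5, alpha = 1e-8, epsilon = 0), tr, seed = 1)
  expect_true(all(impatient == "SS"))
  patient <- simulate_agent_choices(
    list(log_k = -Inf, alpha = 1e-8, epsilon = 0), tr, seed = 1)
  expect_true(all(patient == "LL"))   # k = 0: value reduces to amount
})

test_that("a pure-noise agent chooses larger-later half the time", {
  tr <- default_trials()
  draws <- replicate(70, mean(simulate_agent_choices(
    list(log_k = -4, alpha = 2, epsilon = 0.5), tr,
    seed = sample.int(1e6, 1)) == "LL"))
  # 70 x 144 = 10,080 Bernoulli(0.5) draws; MC error ~ 0.005
  expect_lt(abs(mean(draws) - 0.5), 0.02)
})

test_that("simulated choices match the analytic choice-probability mean", {
  tr <- default_trials()
  pars <- list(log_k = -4.5, alpha = 4, epsilon = 0.05)
  k <- exp(pars$log_k)
  p <- choice_probability(
    hyperbolic_sv(tr$ss_amount, k, tr$ss_delay_days),
    hyperbolic_sv(tr$ll_amount, k, tr$ll_delay_days),
    pars$alpha, pars$epsilon)
  ll_rate <- replicate(70, mean(simulate_agent_choices(
    pars, tr, seed = sample.int(1e6, 1)) == "LL"))
  expect_lt(abs(mean(ll_rate) - mean(p)), 0.02)
})

test_that("cohorts reproduce their configured group structure", {
  cfg <- cohort_config(n_high = 200, n_low = 200, seed = 17)
  sim <- simulate_cohort(cfg, task_design(n_trials = 4, n_catch = 0))
  ag <- sim$agents
  diff_true <- mean(ag$logk_true[ag$group == "high"]) -
    mean(ag$logk_true[ag$group == "low"])
  expect_lt(abs(diff_true - (cfg$logk_mean_high - cfg$logk_mean_low)), 0.2)
  # high-risk agents sit above the clinical cutoff, low-risk at or below
  expect_true(all(ag$eat26_total[ag$group == "high"] > 20))
  expect_true(all(ag$eat26_total[ag$group == "low"] <= 20))
  expect_true(all(ag$eps_true >= 0 & ag$eps_true <= 0.5))
  expect_true(all(ag$alpha_true > 0))
})

test_that("the configured trait/log(k) correlation is honored", {
  # zero correlation, group means equalized so no group-induced component
  cfg <- cohort_config(n_high = 200, n_low = 200, r_future_logk = 0,
                       logk_mean_high = -4.1, logk_mean_low = -4.1,
                       seed = 23)
  sim <- simulate_cohort(cfg, task_design(n_trials = 4, n_catch = 0))
  expect_lt(abs(cor(sim$agents$future_true, sim$agents$logk_true)), 0.15)
  # default negative correlation appears within each risk group
  cfg2 <- cohort_config(n_high = 300, n_low = 300, seed = 29)
  ag <- simulate_cohort(cfg2, task_design(n_trials = 4, n_catch = 0))$agents
  low <- ag[ag$group == "low", ]
  expect_lt(abs(cor(low$future_true, low$logk_true) -
                  cfg2$r_future_logk), 0.15)
})

test_that("the same seed reproduces the cohort exactly", {
  cfg <- cohort_config(n_high = 8, n_low = 8, seed = 5)
  des <- task_design(n_trials = 20, seed = 2)
  expect_identical(simulate_cohort(cfg, des), simulate_cohort(cfg, des))
})

test_that("generated item tables score back to their targets exactly", {
  targets <- list(eat26_total = 21, cfc_total = 47, ztpi_future_mean = 4,
                  pfe_ratio = 0.6, bdi_total = 19, stai_total = 61,
                  atq_na_mean = 5)
  items <- simulate_questionnaire_responses(targets, seed = 12)
  items$participant_id <- 1
  sc <- score_cohort_items(items)
  expect_equal(sc$eat26_total, 21)
  expect_equal(sc$risk_group, "high")
  expect_equal(sc$cfc_total, 47)
  expect_equal(sc$ztpi_future_mean, 4)
  expect_equal(sc$pfe_ratio, 0.6)
  expect_equal(sc$bdi_total, 19)
  expect_equal(sc$stai_total, 61)
  expect_equal(sc$atq_na_mean, 5)
})

test_that("noisy mode lands within one scale unit of the target", {
  for (seed in 1:5) {
    items <- simulate_questionnaire_responses(list(cfc_total = 40),
                                              mode = "noisy", seed = seed)
    got <- score_cfc(as.numeric(items$response))$total
    expect_lte(abs(got - 40), 1)
  }
})

test_that("boundary and unattainable targets are handled", {
  lo <- simulate_questionnaire_responses(list(cfc_total = 12))
  expect_true(all(score_cfc(as.numeric(lo$response))$total == 12))
  expect_error(simulate_questionnaire_responses(list(cfc_total = 11)),
               "unattainable|Unattainable|12")
  expect_error(simulate_questionnaire_responses(list(eat26_total = 79)),
               "0-78")
})

test_that("injected missingness trips the completion exclusion rule", {
  items <- simulate_questionnaire_responses(list(cfc_total = 40),
                                            missing = c(cfc = 0.3),
                                            seed = 2)
  items$participant_id <- 1
  sc <- score_cohort_items(items)
  expect_lt(sc$cfc_completion, 0.75)
  out <- apply_quality_exclusions(sc)
  expect_equal(out$exclusions$reason, "insufficient responses")
  expect_equal(nrow(out$retained), 0)
})
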