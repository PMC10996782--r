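test_that("split R-hat separates mixed from unmixed chains", {
  set.seed(109)
  same <- matrix(rnorm(4000), 1000, 4)
  expect_lt(split_rhat(same), 1.01)
  shifted <- same + rep(c(0, 0, 1, 1), each = 1000)
  expect_gt(split_rhat(shifted), 1.1)
  # folded statistic catches pure scale disagreement
  scaled <- same %*% diag(c(1, 1, 3, 3))
  expect_gt(split_rhat(scaled), 1.05)
  expect_equal(split_rhat(matrix(2, 100, 4)), 1)
  # trend within chains (first half vs second half) is caught by splitting
  trended <- matrix(rnorm(4000) + rep(seq(0, 3, length.out = 1000), 4),
                    1000, 4)
  expect_gt(split_rhat(trended), 1.1)
})

test_that("the hierarchical fit recovers known parameters on a small cohort", {
  tr <- default_trials()
  logk_true <- c(-6.5, -6, -5.3, -5, -4.5, -4, -3.5, -3)
  # near-deterministic agents (tiny acuity noise, rare lapses): the
  # posterior is pinned between adjacent trial indifference points
  choices <- make_choices(logk_true, tr, alpha = 0.5, eps = 0.001, seed = 5)
  fit <- fit_discounting(choices, tr, settings = quick_mcmc(seed = 2))
  s <- tidy(fit)
  expect_equal(nrow(s), 8)
  expect_gt(cor(s$logk_mean, logk_true), 0.9)
  # 95% intervals bracket the generating values
  expect_true(all(s$logk_lo < logk_true & logk_true < s$logk_hi))
  expect_false(any(s$random_responder))
  g <- glance(fit)
  expect_gt(g$accuracy, 0.9)
  expect_true(is.finite(g$rhat_max))
})

test_that("the independent JAGS implementation agrees on a tiny fixture", {
  tr <- build_choice_set(task_design(n_trials = 60, seed = 13))
  logk_true <- c(-6.2, -5.5, -5, -4.6, -4, -3.2)
  choices <- make_choices(logk_true, tr, alpha = 3, eps = 0.02, seed = 7)
  fit <- fit_discounting(choices, tr, settings = quick_mcmc(seed = 3))

  dd <- dplyr::inner_join(choices, tr, by = "trial_id")
  model <- "model{
    mu ~ dnorm(-5.3, 0.16)
    sigma ~ dnorm(0, 0.16) T(0,)
    for (i in 1:P) {
      logk[i] ~ dnorm(mu, 1 / pow(sigma, 2))
      eps[i] ~ dbeta(1.1, 10.9) T(0, 0.5)
      alpha[i] ~ dnorm(0, 1 / pow(20, 2)) T(0.001,)
    }
    for (j in 1:N) {
      dv[j] <- a_ll[j] / (1 + exp(logk[pid[j]]) * t_ll[j]) -
               a_ss[j] / (1 + exp(logk[pid[j]]) * t_ss[j])
      p[j] <- eps[pid[j]] + (1 - 2 * eps[pid[j]]) * phi(dv[j] / alpha[pid[j]])
      y[j] ~ dbern(p[j])
    }
  }"
  jd <- list(y = as.integer(dd$choice == "LL"), pid = dd$participant_id,
             a_ss = dd$ss_amount, t_ss = dd$ss_delay_days,
             a_ll = dd$ll_amount, t_ll = dd$ll_delay_days,
             P = 6L, N = nrow(dd))
  jm <- rjags::jags.model(
    textConnection(model), data = jd, n.chains = 2, n.adapt = 1000,
    quiet = TRUE,
    inits = lapply(1:2, function(c) {
      list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = c)
    }))
  stats::update(jm, 500)
  samp <- rjags::coda.samples(jm, c("logk", "mu"), n.iter = 3000)
  m <- summary(samp)$statistics
  jags_logk <- m[paste0("logk[", 1:6, "]"), "Mean"]
  ours <- tidy(fit)$logk_mean
  expect_lt(mean(abs(ours - jags_logk)), 0.3)
  expect_gt(cor(ours, jags_logk), 0.95)
  expect_lt(abs(fit$group$mu_mean - m["mu", "Mean"]), 0.4)
})

test_that("partial pooling shrinks a sparse participant toward the group", {
  tr <- default_trials()
  full <- make_choices(rep(c(-4.6, -4.2, -3.8), each = 4), tr,
                       alpha = 2, eps = 0.01, seed = 9)
  sparse <- make_choices(-7.5, tr[1:8, ], alpha = 2, eps = 0.01, seed = 10)
  sparse$participant_id <- 13L
  choices <- dplyr::bind_rows(full, sparse)
  partial <- fit_discounting(choices, tr, settings = quick_mcmc(seed = 4))
  none <- fit_discounting(choices, tr, settings = quick_mcmc(seed = 4),
                          pooling = "none")
  mu <- partial$group$mu_mean
  est_partial <- tidy(partial)$logk_mean[13]
  est_none <- tidy(none)$logk_mean[13]
  expect_lt(abs(est_partial - mu), abs(est_none - mu))
})

test_that("fits reject malformed inputs and label convergence honestly", {
  tr <- default_trials()
  choices <- make_choices(-4, tr, seed = 2)
  expect_error(fit_discounting(choices[0, ], tr), "empty|No non-catch")
  bad <- choices; bad$choice[1] <- "left"
  expect_error(fit_discounting(bad, tr), "SS")
  tiny <- fit_discounting(choices, tr,
                          settings = mcmc_settings(n_chains = 2,
                                                   n_samples = 120,
                                                   n_burnin = 20,
                                                   n_thin = 1, seed = 1))
  expect_identical(tiny$converged, tiny$rhat_max <= 1.01)
  expect_error(mcmc_settings(n_samples = 100, n_burnin = 100), "burnin")
})

test_that("fit accessors and plots expose the expected shapes", {
  tr <- build_choice_set(task_design(n_trials = 30, seed = 21))
  choices <- make_choices(c(-5, -4), tr, seed = 31)
  fit <- fit_discounting(choices, tr,
                         settings = mcmc_settings(n_chains = 2,
                                                  n_samples = 400,
                                                  n_burnin = 100,
                                                  n_thin = 1, seed = 6))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_named(glance(fit),
               c("n_participants", "n_choices", "mu_mean", "sigma_mean",
                 "rhat_max", "converged", "accuracy",
                 "n_random_responders"))
  flags <- detect_random_responders(fit)
  expect_equal(nrow(flags), 2)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
  acc <- classify_choices(fit)
  expect_true(acc >= 0 && acc <= 1)
})
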