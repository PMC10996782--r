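#' Group-level prior for the hierarchical discounting model
#'
#' Participant log discount rates are partially pooled through
#' `log_k[i] ~ Normal(mu, sigma)` with `mu ~ Normal(logk_mean, logk_sd)` and
#' `sigma ~ half-Normal(sigma_scale)`. The default `Normal(-5.3, 2.5)` prior
#' on the group mean encodes the expectation that the choice set samples
#' discount rates evenly (see [balanced_log_k()]). Lapse rates get a
#' Beta(1.1, 10.9) prior truncated to `[0, 0.5]` (mode near 0.01) and the
#' comparison-acuity noise a half-Normal whose scale is set from the money
#' range of the task.
#'
#' @param logk_mean,logk_sd Mean and SD of the prior on the group-level
#'   mean of log(k).
#' @param sigma_scale Scale of the half-normal prior on the group SD.
#' @param eps_shape1,eps_shape2 Beta shape parameters for the lapse rate.
#' @param alpha_scale Scale (money units) of the half-normal prior on the
#'   acuity noise.
#' @return A `group_prior` list.
#' @export
group_prior <- function(logk_mean = -5.3, logk_sd = 2.5, sigma_scale = 2.5,
                        eps_shape1 = 1.1, eps_shape2 = 10.9,
                        alpha_scale = 20) {
  if (logk_sd <= 0 || sigma_scale <= 0 || alpha_scale <= 0) {
    abort("Prior scales must be positive.")
  }
  structure(list(logk_mean = logk_mean, logk_sd = logk_sd,
                 sigma_scale = sigma_scale, eps_shape1 = eps_shape1,
                 eps_shape2 = eps_shape2, alpha_scale = alpha_scale),
            class = "group_prior")
}

#' MCMC sampler settings
#'
#' `n_samples` counts all iterations per chain; the first `n_burnin` are
#' discarded (and used to adapt proposal scales), so `n_chains *
#' (n_samples - n_burnin)` draws are retained. A full-scale analysis uses
#' `mcmc_settings(n_samples = 25000, n_burnin = 1000)` (96,000 retained
#' draws over 4 chains); the default here is a light setting suitable for
#' simulation studies and tests.
#'
#' @param n_chains Number of independent chains.
#' @param n_samples Iterations per chain, including burn-in.
#' @param n_burnin Burn-in iterations per chain.
#' @param n_thin Metropolis updates of the participant blocks per stored
#'   iteration (improves mixing per retained draw at proportional cost).
#' @param seed Integer seed; chain seeds are derived from it.
#' @return An `mcmc_settings` list.
#' @export
mcmc_settings <- function(n_chains = 4, n_samples = 5000, n_burnin = 1500,
                          n_thin = 4, seed = 1L) {
  if (n_burnin >= n_samples) abort("`n_burnin` must be < `n_samples`.")
  if (n_chains < 2) abort("At least 2 chains are needed for R-hat.")
  if (n_thin < 1) abort("`n_thin` must be >= 1.")
  structure(list(n_chains = as.integer(n_chains),
                 n_samples = as.integer(n_samples),
                 n_burnin = as.integer(n_burnin),
                 n_thin = as.integer(n_thin),
                 seed = as.integer(seed)),
            class = "mcmc_settings")
}

# per-trial Bernoulli log-likelihood, summed by participant.
# logk/alpha/eps are length-P; the remaining vectors are per trial row.
participant_loglik <- function(logk, alpha, eps, pid, y,
                               a_ss, t_ss, a_ll, t_ll) {
  k <- exp(logk[pid])
  dv <- a_ll / (1 + k * t_ll) - a_ss / (1 + k * t_ss)
  p <- eps[pid] + (1 - 2 * eps[pid]) * pnorm(dv / alpha[pid])
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  ll <- ifelse(y == 1L, log(p), log1p(-p))
  as.numeric(rowsum(ll, pid, reorder = TRUE))
}

# log prior + Jacobian for the transformed participant block.
# theta is (logk, log alpha, u) with eps = 0.5 * plogis(u).
participant_logprior <- function(logk, alpha, eps, mu, sigma, prior,
                                 pooled = TRUE) {
  lp_k <- if (pooled) {
    dnorm(logk, mu, sigma, log = TRUE)
  } else {
    dnorm(logk, prior$logk_mean, prior$logk_sd, log = TRUE)
  }
  lp_a <- -alpha^2 / (2 * prior$alpha_scale^2) + log(alpha)
  lp_e <- (prior$eps_shape1 - 1) * log(eps) +
    (prior$eps_shape2 - 1) * log1p(-eps) +
    log(eps) + log1p(-2 * eps)           # Jacobian of eps = plogis(u)/2
  lp_k + lp_a + lp_e
}

run_dd_chain <- function(dat, prior, n_samples, n_burnin, n_thin, seed,
                         chain_id, pooled) {
  set.seed(seed)
  P <- dat$P
  offset <- c(-1.5, -0.5, 0.5, 1.5, rep(0, 8))[((chain_id - 1) %% 12) + 1]
  th <- cbind(rnorm(P, prior$logk_mean + offset, 1),
              log(5) + rnorm(P, 0, 0.3),
              qlogis(2 * 0.05) + rnorm(P, 0, 0.3))
  mu <- prior$logk_mean + offset
  sigma <- 2
  log_sigma_step <- log(0.3)

  # per-participant proposal: delta = exp(log_step) * L %*% z, with L a
  # lower-triangular Cholesky factor of the adapted empirical covariance
  # (Haario-style adaptive Metropolis), seeded with a diagonal guess
  L <- cbind(l11 = rep(0.4, P), l21 = 0, l22 = 0.4, l31 = 0, l32 = 0,
             l33 = 0.8)
  log_step <- rep(log(1), P)
  cnt <- 0; cov_cnt <- 0
  run_mean <- matrix(0, P, 3)
  run_m2 <- matrix(0, P, 6)              # cols: 11, 21, 22, 31, 32, 33
  cov_cols <- cbind(c(1, 2, 2, 3, 3, 3), c(1, 1, 2, 1, 2, 3))

  kept <- n_samples - n_burnin
  out <- list(logk = matrix(NA_real_, kept, P),
              alpha = matrix(NA_real_, kept, P),
              eps = matrix(NA_real_, kept, P),
              mu = numeric(kept), sigma = numeric(kept))

  unpack <- function(th) list(logk = th[, 1], alpha = exp(th[, 2]),
                              eps = 0.5 * plogis(th[, 3]))
  cur <- unpack(th)
  ll_cur <- participant_loglik(cur$logk, cur$alpha, cur$eps, dat$pid, dat$y,
                               dat$a_ss, dat$t_ss, dat$a_ll, dat$t_ll)
  lp_cur <- ll_cur + participant_logprior(cur$logk, cur$alpha, cur$eps,
                                          mu, sigma, prior, pooled)
  prior_prec <- 1 / prior$logk_sd^2

  for (it in seq_len(n_samples)) {
    for (sweep in seq_len(n_thin)) {
      z1 <- rnorm(P); z2 <- rnorm(P); z3 <- rnorm(P)
      s <- exp(log_step)
      th_p <- th + s * cbind(L[, "l11"] * z1,
                             L[, "l21"] * z1 + L[, "l22"] * z2,
                             L[, "l31"] * z1 + L[, "l32"] * z2 +
                               L[, "l33"] * z3)
      prop <- unpack(th_p)
      ll_p <- participant_loglik(prop$logk, prop$alpha, prop$eps, dat$pid,
                                 dat$y, dat$a_ss, dat$t_ss, dat$a_ll,
                                 dat$t_ll)
      lp_p <- ll_p + participant_logprior(prop$logk, prop$alpha, prop$eps,
                                          mu, sigma, prior, pooled)
      acc <- log(runif(P)) < (lp_p - lp_cur)
      th[acc, ] <- th_p[acc, ]
      ll_cur[acc] <- ll_p[acc]; lp_cur[acc] <- lp_p[acc]
      # diminishing adaptation (continues past burn-in, Haario-style)
      cnt <- cnt + 1
      cov_cnt <- cov_cnt + 1
      log_step <- log_step + cnt^-0.55 * (acc - 0.3)
      d <- th - run_mean
      run_mean <- run_mean + d / cov_cnt
      run_m2 <- run_m2 + d[, cov_cols[, 1]] * (th - run_mean)[, cov_cols[, 2]]
      if (cov_cnt >= 200 && cov_cnt %% 100 == 0) {
        cv <- run_m2 / (cov_cnt - 1)
        for (i in seq_len(P)) {
          C <- matrix(cv[i, c(1, 2, 4, 2, 3, 5, 4, 5, 6)], 3, 3)
          ch <- tryCatch(
            t(chol(2.38^2 / 3 * C + diag(1e-4, 3))),
            error = function(e) NULL)
          if (!is.null(ch)) {
            L[i, ] <- ch[lower.tri(ch, diag = TRUE)][c(1, 2, 4, 3, 5, 6)]
          }
        }
      }
    }
    if (it == n_burnin) {
      # restart covariance accumulation so the adapted geometry reflects
      # the converged region, not the burn-in transient
      cov_cnt <- 0
      run_mean[] <- 0
      run_m2[] <- 0
    }
    cur <- unpack(th)

    if (pooled) {
      # conjugate update of the group mean
      prec <- prior_prec + P / sigma^2
      mu <- rnorm(1, (prior$logk_mean * prior_prec +
                        sum(cur$logk) / sigma^2) / prec, sqrt(1 / prec))
      # random-walk update of the group SD on the log scale
      sigma_p <- sigma * exp(rnorm(1, 0, exp(log_sigma_step)))
      lr <- sum(dnorm(cur$logk, mu, sigma_p, log = TRUE)) -
        sum(dnorm(cur$logk, mu, sigma, log = TRUE)) +
        (-sigma_p^2 + sigma^2) / (2 * prior$sigma_scale^2) +
        log(sigma_p) - log(sigma)
      acc_s <- log(runif(1)) < lr
      if (acc_s) sigma <- sigma_p
      log_sigma_step <- log_sigma_step + it^-0.55 * ((acc_s) - 0.44)
      # participant log-priors depend on (mu, sigma): refresh cached values
      lp_cur <- ll_cur + participant_logprior(cur$logk, cur$alpha, cur$eps,
                                              mu, sigma, prior, pooled)
    }
    if (it > n_burnin) {
      j <- it - n_burnin
      out$logk[j, ] <- cur$logk; out$alpha[j, ] <- cur$alpha
      out$eps[j, ] <- cur$eps
      out$mu[j] <- mu; out$sigma[j] <- sigma
    }
  }
  out
}

#' Fit the hierarchical Bayesian discounting model
#'
#' Estimates per-participant hyperbolic discounting parameters (log(k),
#' acuity noise alpha, lapse rate epsilon) from binary choices, partially
#' pooling log(k) through a group-level normal distribution. Posterior
#' sampling uses an adaptive Metropolis-within-Gibbs scheme: a joint
#' random-walk proposal on each participant's transformed parameter block
#' whose covariance is adapted to the empirical posterior covariance with
#' diminishing weight (Haario-style), a conjugate Gibbs update for the
#' group mean, and a random-walk update for the group SD.
#' Convergence is assessed with rank-normalized split R-hat (bulk and
#' folded, threshold 1.01) for every parameter; a fit that misses the
#' threshold is flagged, never silently accepted.
#'
#' Catch trials (`is_catch = TRUE`) are excluded from the likelihood.
#' Risk groups should be fitted separately to keep their hierarchically
#' estimated parameters statistically independent.
#'
#' @param choices Tibble with columns `participant_id`, `trial_id` and
#'   `choice` (`"SS"`/`"LL"`).
#' @param trials Trial table from [build_choice_set()] (joined on
#'   `trial_id`).
#' @param prior A [group_prior()].
#' @param settings An [mcmc_settings()].
#' @param pooling `"partial"` for the hierarchical model, `"none"` to fit
#'   each participant independently under the `Normal(logk_mean, logk_sd)`
#'   prior (used to quantify shrinkage).
#' @return A `dd_fit` object; see [tidy.dd_fit()] and [glance.dd_fit()].
#' @export
fit_discounting <- function(choices, trials, prior = group_prior(),
                            settings = mcmc_settings(),
                            pooling = c("partial", "none")) {
  pooling <- match.arg(pooling)
  stopifnot(inherits(prior, "group_prior"), inherits(settings, "mcmc_settings"))
  if (!all(c("participant_id", "trial_id", "choice") %in% names(choices))) {
    abort("`choices` needs participant_id, trial_id and choice columns.")
  }
  dd <- dplyr::inner_join(tibble::as_tibble(choices), trials, by = "trial_id")
  dd <- dd[!dd$is_catch, ]
  if (!nrow(dd)) abort("No non-catch trials to fit (empty group?).")
  if (!all(dd$choice %in% c("SS", "LL"))) {
    abort("Choice codes must be 'SS' or 'LL'.")
  }
  ids <- sort(unique(dd$participant_id))
  dat <- list(
    P = length(ids),
    pid = match(dd$participant_id, ids),
    y = as.integer(dd$choice == "LL"),
    a_ss = dd$ss_amount, t_ss = dd$ss_delay_days,
    a_ll = dd$ll_amount, t_ll = dd$ll_delay_days
  )
  ord <- order(dat$pid)
  dat[c("pid", "y", "a_ss", "t_ss", "a_ll", "t_ll")] <-
    lapply(dat[c("pid", "y", "a_ss", "t_ss", "a_ll", "t_ll")], `[`, ord)

  chains <- lapply(seq_len(settings$n_chains), function(c) {
    chain_seed <- as.integer((as.numeric(settings$seed) * 1000 + c) %%
                               2147483647)
    run_dd_chain(dat, prior, settings$n_samples, settings$n_burnin,
                 settings$n_thin, seed = chain_seed,
                 chain_id = c, pooled = pooling == "partial")
  })

  stack <- function(field) {
    # iterations x chains x P (P dropped for scalars)
    if (is.matrix(chains[[1]][[field]])) {
      aperm(simplify2array(lapply(chains, `[[`, field)), c(1, 3, 2))
    } else {
      simplify2array(lapply(chains, `[[`, field))
    }
  }
  logk_d <- stack("logk"); alpha_d <- stack("alpha"); eps_d <- stack("eps")
  per_rhat <- function(arr) {
    vapply(seq_len(dim(arr)[3]), function(i) split_rhat(arr[, , i]),
           numeric(1))
  }
  rhat <- tibble::tibble(
    participant_id = ids,
    rhat_logk = per_rhat(logk_d),
    rhat_alpha = per_rhat(alpha_d),
    rhat_eps = per_rhat(eps_d)
  )
  flat <- function(arr, f) apply(arr, 3, function(m) f(as.vector(m)))
  summary <- tibble::tibble(
    participant_id = ids,
    logk_mean = flat(logk_d, mean),
    logk_median = flat(logk_d, median),
    logk_sd = flat(logk_d, sd),
    logk_lo = flat(logk_d, function(v) quantile(v, 0.025)),
    logk_hi = flat(logk_d, function(v) quantile(v, 0.975)),
    alpha_mean = flat(alpha_d, mean),
    eps_mean = flat(eps_d, mean),
    eps_median = flat(eps_d, median)
  )
  summary <- dplyr::left_join(summary, rhat, by = "participant_id")

  group_rhat <- if (pooling == "partial") {
    c(mu = split_rhat(stack("mu")), sigma = split_rhat(stack("sigma")))
  } else c(mu = NA_real_, sigma = NA_real_)
  rhat_max <- max(c(summary$rhat_logk, summary$rhat_alpha, summary$rhat_eps,
                    group_rhat), na.rm = TRUE)

  fit <- structure(
    list(summary = summary,
         group = list(
           mu_mean = if (pooling == "partial") mean(stack("mu")) else NA_real_,
           mu_lo = if (pooling == "partial") quantile(stack("mu"), 0.025) else NA_real_,
           mu_hi = if (pooling == "partial") quantile(stack("mu"), 0.975) else NA_real_,
           sigma_mean = if (pooling == "partial") mean(stack("sigma")) else NA_real_,
           rhat = group_rhat),
         draws = list(logk = logk_d, alpha = alpha_d, eps = eps_d),
         data = dd, ids = ids, prior = prior, settings = settings,
         pooling = pooling,
         rhat_max = rhat_max, converged = rhat_max <= 1.01),
    class = "dd_fit")
  acc <- classification_by_participant(fit)
  m <- match(ids, acc$participant_id)
  fit$summary$accuracy <- acc$accuracy[m]
  fit$summary$expected_accuracy <- acc$expected_accuracy[m]
  fit$summary$random_responder <- fit$summary$eps_median >= 0.25 |
    fit$summary$expected_accuracy <= 0.55
  fit
}

#' @export
print.dd_fit <- function(x, ...) {
  cat("<dd_fit> ", length(x$ids), " participants, ",
      nrow(x$data), " choices, ", x$pooling, " pooling\n",
      "  max R-hat = ", round(x$rhat_max, 4),
      if (x$converged) " (converged)" else " (NOT converged)", "\n",
      "  group log(k): mean ", round(x$group$mu_mean, 3),
      ", sd ", round(x$group$sigma_mean, 3), "\n",
      "  classification accuracy: ", round(classify_choices(x), 3), "\n",
      sep = "")
  invisible(x)
}

# per-participant in-sample accuracy from posterior point estimates
# (a predicted p(LL) of exactly 0.5 counts as a smaller-sooner prediction)
# and the model's expected accuracy, i.e. the posterior-predictive hit
# probability of its argmax predictions, mean(pmax(p, 1 - p)) -- 0.5 for a
# model that cannot distinguish the options at all
classification_by_participant <- function(fit) {
  s <- fit$summary
  idx <- match(fit$data$participant_id, s$participant_id)
  p <- choice_probability(
    hyperbolic_sv(fit$data$ss_amount, exp(s$logk_mean[idx]),
                  fit$data$ss_delay_days),
    hyperbolic_sv(fit$data$ll_amount, exp(s$logk_mean[idx]),
                  fit$data$ll_delay_days),
    s$alpha_mean[idx], pmin(s$eps_mean[idx], 0.5))
  pred <- ifelse(p > 0.5, "LL", "SS")
  tibble::tibble(participant_id = fit$data$participant_id,
                 hit = pred == fit$data$choice,
                 conf = pmax(p, 1 - p)) |>
    dplyr::summarise(accuracy = mean(.data$hit),
                     expected_accuracy = mean(.data$conf),
                     .by = "participant_id")
}

#' Classification accuracy of a fitted discounting model
#'
#' Fraction of observed choices matching the model prediction (larger-later
#' iff fitted p(LL) > 0.5 at the posterior point estimates), pooled over
#' participants. Ties at exactly 0.5 are scored as smaller-sooner
#' predictions.
#'
#' @param fit A `dd_fit`.
#' @return A single fraction in `[0, 1]`.
#' @export
classify_choices <- function(fit) {
  stopifnot(inherits(fit, "dd_fit"))
  acc <- classification_by_participant(fit)
  n <- table(fit$data$participant_id)[as.character(acc$participant_id)]
  sum(acc$accuracy * as.numeric(n)) / sum(n)
}

#' Flag random responders in a fitted discounting model
#'
#' A participant is flagged when the posterior indicates chance-level
#' responding: posterior median lapse rate at or above `eps_threshold`, or
#' posterior-predictive expected accuracy at or below
#' `accuracy_threshold`. Expected accuracy is the model's own hit
#' probability for its argmax predictions, `mean(pmax(p, 1 - p))`; it
#' equals 0.5 exactly when the fitted model cannot distinguish the options
#' (e.g. a coin-flip responder absorbed by a huge acuity noise), which
#' makes the flag insensitive to binomial noise in the realized hit rate.
#' Flagged participants should be excluded from downstream group
#' statistics.
#'
#' @param fit A `dd_fit`.
#' @param eps_threshold Posterior-median lapse cutoff (default 0.25).
#' @param accuracy_threshold Expected-accuracy cutoff (default 0.55).
#' @return Tibble with `participant_id`, `eps_median`, `accuracy`,
#'   `expected_accuracy`, `random_responder`.
#' @export
detect_random_responders <- function(fit, eps_threshold = 0.25,
                                     accuracy_threshold = 0.55) {
  stopifnot(inherits(fit, "dd_fit"))
  s <- fit$summary
  tibble::tibble(
    participant_id = s$participant_id,
    eps_median = s$eps_median,
    accuracy = s$accuracy,
    expected_accuracy = s$expected_accuracy,
    random_responder = s$eps_median >= eps_threshold |
      s$expected_accuracy <= accuracy_threshold
  )
}

#' @describeIn fit_discounting Per-participant posterior summaries as a
#'   tibble.
#' @param x A `dd_fit`.
#' @param ... Unused.
#' @method tidy dd_fit
#' @export
tidy.dd_fit <- function(x, ...) x$summary

#' @describeIn fit_discounting One-row fit summary (group posterior, max
#'   R-hat, convergence flag, pooled classification accuracy).
#' @method glance dd_fit
#' @export
glance.dd_fit <- function(x, ...) {
  tibble::tibble(
    n_participants = length(x$ids),
    n_choices = nrow(x$data),
    mu_mean = x$group$mu_mean,
    sigma_mean = x$group$sigma_mean,
    rhat_max = x$rhat_max,
    converged = x$converged,
    accuracy = classify_choices(x),
    n_random_responders = sum(x$summary$random_responder)
  )
}

#' Rank-normalized split R-hat
#'
#' Computes the split-chain, rank-normalized potential scale reduction
#' factor, taking the maximum of the bulk statistic and the folded
#' statistic (ranks of absolute deviations from the median), so both
#' location and scale disagreements between chains are detected. Values at
#' or below 1.01 indicate convergence.
#'
#' @param x Matrix of posterior draws, iterations x chains.
#' @return The R-hat value (scalar).
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x) %/% 2L
  halves <- cbind(x[seq_len(n), , drop = FALSE],
                  x[n + seq_len(n), , drop = FALSE])
  base_rhat <- function(m) {
    if (all(m == m[1])) return(1)
    nn <- nrow(m)
    bm <- colMeans(m)
    b <- nn * var(bm)
    w <- mean(apply(m, 2, var))
    sqrt(((nn - 1) / nn * w + b / nn) / w)
  }
  znorm <- function(m) {
    r <- rank(m, ties.method = "average")
    matrix(qnorm((r - 3 / 8) / (length(m) + 1 / 4)), nrow(m), ncol(m))
  }
  bulk <- base_rhat(znorm(halves))
  folded <- base_rhat(znorm(abs(halves - median(halves))))
  max(bulk, folded)
}
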