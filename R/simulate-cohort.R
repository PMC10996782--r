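#' Configuration of a simulated risk cohort
#'
#' Describes the generative conditions of a synthetic two-group cohort:
#' group sizes, group means and spread of the true log discount rate,
#' lapse/acuity distributions, the standardized group effect on the
#' future-orientation trait, the within-group correlation between future
#' orientation and log(k), and the correlation between dispositional
#' negativity and eating-disorder-risk severity. The defaults reproduce
#' the observed study conditions: 55 high-risk and 94 low-risk
#' participants, group log(k) means of -4.394 and -3.928 with SD 1.5, a
#' future-orientation group effect of d = 0.451, a future-orientation /
#' log(k) correlation of -0.26 and a negativity / risk-severity
#' correlation of 0.314.
#'
#' @param n_high,n_low Group sizes.
#' @param logk_mean_high,logk_mean_low Group means of true log(k)
#'   (high-risk mean below low-risk).
#' @param logk_sd Within-group SD of true log(k).
#' @param eps_dist Beta parameters (`shape1`, `shape2`) of the lapse rate
#'   (default mode 0.02, mean 0.038), truncated to `[0, 0.5]`.
#' @param alpha_dist Scale of the half-normal acuity-noise distribution
#'   (money units) plus a floor avoiding degenerate acuity.
#' @param trait_effect_d_future Standardized high-minus-low group effect
#'   on the future-orientation trait.
#' @param r_future_logk Within-group correlation between the
#'   future-orientation trait and log(k).
#' @param r_negativity_eat Correlation between dispositional negativity
#'   and the (standardized) eating-attitudes severity score.
#' @param seed Integer seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_high = 55, n_low = 94,
                          logk_mean_high = -4.394, logk_mean_low = -3.928,
                          logk_sd = 1.5,
                          eps_dist = c(shape1 = 2, shape2 = 50),
                          alpha_dist = c(scale = 4, floor = 0.25),
                          trait_effect_d_future = 0.451,
                          r_future_logk = -0.26,
                          r_negativity_eat = 0.314,
                          seed = 1L) {
  if (abs(r_future_logk) > 1 || abs(r_negativity_eat) > 1) {
    abort("Correlations must lie in [-1, 1].")
  }
  if (logk_sd <= 0) abort("`logk_sd` must be positive.")
  structure(list(n_high = as.integer(n_high), n_low = as.integer(n_low),
                 logk_mean_high = logk_mean_high,
                 logk_mean_low = logk_mean_low, logk_sd = logk_sd,
                 eps_dist = eps_dist, alpha_dist = alpha_dist,
                 trait_effect_d_future = trait_effect_d_future,
                 r_future_logk = r_future_logk,
                 r_negativity_eat = r_negativity_eat,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate an agent's intertemporal choices
#'
#' Draws one Bernoulli choice per trial with p(LL) from
#' [choice_probability()] at the agent's true parameters.
#'
#' @param params List or one-row data frame with `log_k`, `alpha`,
#'   `epsilon`.
#' @param trials Trial tibble (catch trials included; the lapse-free
#'   subjective-value comparison governs them too).
#' @param seed Integer seed.
#' @return Character vector of `"SS"`/`"LL"`, one per trial row.
#' @export
simulate_agent_choices <- function(params, trials, seed = 1L) {
  k <- exp(params$log_k)
  sv_ss <- hyperbolic_sv(trials$ss_amount, k, trials$ss_delay_days)
  sv_ll <- hyperbolic_sv(trials$ll_amount, k, trials$ll_delay_days)
  p <- choice_probability(sv_ss, sv_ll, params$alpha, params$epsilon)
  withr_seed(seed, y <- rbinom(nrow(trials), 1, p))
  ifelse(y == 1L, "LL", "SS")
}

# allocate `total - n * lo` surplus over n items bounded at hi - lo each;
# returns integer codes in [lo, hi] summing to total
distribute_codes <- function(total, n, lo, hi) {
  total <- as.integer(round(total))
  if (total < n * lo || total > n * hi) {
    abort(paste0("Target ", total, " unattainable with ", n,
                 " items in [", lo, ", ", hi, "]."))
  }
  extra <- total - n * lo
  span <- hi - lo
  full <- extra %/% span
  rem <- extra %% span
  codes <- rep(lo, n)
  if (full > 0) codes[seq_len(full)] <- hi
  if (rem > 0) codes[full + 1] <- lo + rem
  codes
}

#' Simulate item-level questionnaire responses for target scores
#'
#' Builds item tables whose computed scale scores (via the scoring
#' functions) reproduce the requested targets: exactly in deterministic
#' mode (continuous targets such as the ZTPI-future mean or PFE ratio are
#' first snapped to the nearest attainable value), or after adding at most
#' one scale unit of jitter in noisy mode. Optionally blanks a fraction of
#' a scale's items to exercise the 75%-completion exclusion rule.
#'
#' @param targets Named list or one-row data frame with any of
#'   `eat26_total` (0-78), `cfc_total` (12-60), `ztpi_future_mean` (1-5),
#'   `pfe_ratio` (0-1), `bdi_total` (0-63), `stai_total` (20-80),
#'   `atq_na_mean` (1-7).
#' @param mode `"deterministic"` or `"noisy"`.
#' @param missing Optional named numeric vector of per-scale missingness
#'   fractions, e.g. `c(cfc = 0.3)`.
#' @param seed Integer seed (noisy jitter, item shuffling, missingness).
#' @return Tibble with columns `scale`, `item`, `response` (character;
#'   numeric scales stored as numbers in character form, `NA` for blanked
#'   items).
#' @export
#' @examples
#' items <- simulate_questionnaire_responses(list(eat26_total = 21))
#' score_eat26(items$response[items$scale == "eat26"])
simulate_questionnaire_responses <- function(targets,
                                             mode = c("deterministic",
                                                      "noisy"),
                                             missing = NULL, seed = 1L) {
  mode <- match.arg(mode)
  targets <- as.list(targets)
  out <- list()
  withr_seed(seed, {
    jit <- function(x, unit = 1) {
      if (mode == "noisy") x + runif(1, -unit, unit) else x
    }
    if (!is.null(targets$eat26_total)) {
      tt <- round(jit(targets$eat26_total))
      if (tt < 0 || tt > 78) abort("EAT-26 target must lie in 0-78.")
      # item 26 scores 3 under "Never"; spend it first, rest over items 1-25
      i26 <- min(tt, 3L)
      codes <- sample(distribute_codes(tt - i26, 25, 0, 3))
      resp <- ifelse(codes == 0, "Never", eat26_menu[codes + 3])
      out$eat26 <- tibble::tibble(scale = "eat26", item = 1:26,
                                  response = c(resp, eat26_menu[4 - i26]))
    }
    if (!is.null(targets$cfc_total)) {
      tt <- round(jit(targets$cfc_total))
      codes <- sample(distribute_codes(tt, 12, 1, 5))
      raw <- codes
      raw[cfc_reversed] <- 6L - raw[cfc_reversed]
      out$cfc <- tibble::tibble(scale = "cfc", item = 1:12,
                                response = as.character(raw))
    }
    if (!is.null(targets$ztpi_future_mean)) {
      m <- max(1, min(5, jit(targets$ztpi_future_mean, 1 / 13)))
      codes <- sample(distribute_codes(round(m * 13), 13, 1, 5))
      raw <- rep(3L, 56)
      raw[ztpi_future_items] <- codes
      raw[ztpi_future_reversed] <- 6L - raw[ztpi_future_reversed]
      out$ztpi <- tibble::tibble(scale = "ztpi", item = 1:56,
                                 response = as.character(raw))
    }
    if (!is.null(targets$pfe_ratio)) {
      r <- max(0, min(1, jit(targets$pfe_ratio, 0.1)))
      n_fut <- round(r * 10)
      out$pfe <- tibble::tibble(
        scale = "pfe", item = 1:10,
        response = sample(c(rep("future", n_fut),
                            rep(c("past", "present"),
                                length.out = 10 - n_fut))))
    }
    if (!is.null(targets$bdi_total)) {
      codes <- sample(distribute_codes(round(jit(targets$bdi_total)),
                                       21, 0, 3))
      out$bdi <- tibble::tibble(scale = "bdi", item = 1:21,
                                response = as.character(codes))
    }
    if (!is.null(targets$stai_total)) {
      codes <- sample(distribute_codes(round(jit(targets$stai_total)),
                                       20, 1, 4))
      raw <- codes
      raw[stai_trait_reversed] <- 5L - raw[stai_trait_reversed]
      out$stai <- tibble::tibble(scale = "stai", item = 1:20,
                                 response = as.character(raw))
    }
    if (!is.null(targets$atq_na_mean)) {
      m <- max(1, min(7, jit(targets$atq_na_mean, 1 / 26)))
      codes <- sample(distribute_codes(round(m * 26), 26, 1, 7))
      out$atq_na <- tibble::tibble(scale = "atq_na", item = 1:26,
                                   response = as.character(codes))
    }
    res <- dplyr::bind_rows(out)
    if (!is.null(missing)) {
      for (sc in names(missing)) {
        rows <- which(res$scale == sc)
        blank <- sample(rows, ceiling(missing[[sc]] * length(rows)))
        res$response[blank] <- NA_character_
      }
    }
  })
  res
}

#' Simulate a full risk cohort with known ground truth
#'
#' Generates agents in two risk groups. True log discount rates come from
#' group-specific normals; latent future-orientation and
#' dispositional-negativity traits come from standard normals given the
#' configured group effect and correlations (a Gaussian-copula-style
#' construction: correlations are imposed on latent normals and the
#' observable questionnaire targets are monotone transforms of them).
#' Eating-attitudes severity places high-risk agents above the clinical
#' cutoff (total > 20) and low-risk agents at or below it. Each agent's
#' trial-level choices are simulated from the lapse-and-acuity choice rule
#' at their true parameters, and item-level questionnaire responses are
#' generated to match the target scale scores.
#'
#' @param config A [cohort_config()].
#' @param design A [task_design()].
#' @return List with `agents` (one row per agent: group, true parameters,
#'   latent traits, target scale scores), `trials` (the shared trial
#'   table), `choices` (agent x trial choice codes) and `items`
#'   (item-level questionnaire responses).
#' @export
simulate_cohort <- function(config = cohort_config(),
                            design = task_design()) {
  stopifnot(inherits(config, "cohort_config"))
  trials <- interleave_catch_trials(
    build_choice_set(design),
    build_catch_trials(design$n_catch, seed = design$seed + 1L),
    seed = design$seed + 2L)
  n <- config$n_high + config$n_low
  grp <- rep(c("high", "low"), c(config$n_high, config$n_low))
  withr_seed(config$seed, {
    z_k <- rnorm(n)
    logk <- ifelse(grp == "high", config$logk_mean_high,
                   config$logk_mean_low) + config$logk_sd * z_k
    eps <- rbeta(n, config$eps_dist[["shape1"]], config$eps_dist[["shape2"]])
    eps <- pmin(eps, 0.5)
    alpha <- config$alpha_dist[["floor"]] +
      abs(rnorm(n, 0, config$alpha_dist[["scale"]]))
    r <- config$r_future_logk
    future <- config$trait_effect_d_future * (grp == "high") +
      r * z_k + sqrt(1 - r^2) * rnorm(n)
    # risk severity: high-risk agents above the cutoff, low-risk at/below
    eat <- ifelse(grp == "high", 21 + stats::rbinom(n, 14, 0.4),
                  stats::rbinom(n, 20, 0.45))
    z_eat <- (eat - mean(eat)) / sd(eat)
    rn <- config$r_negativity_eat
    negativity <- rn * z_eat + sqrt(1 - rn^2) * rnorm(n)
    agents <- tibble::tibble(
      participant_id = seq_len(n),
      group = grp,
      logk_true = logk, alpha_true = alpha, eps_true = eps,
      future_true = future, negativity_true = negativity,
      eat26_total = as.integer(eat),
      cfc_total = pmin(60, pmax(12, round(36 + 8 *
        (0.75 * future + sqrt(1 - 0.75^2) * rnorm(n))))),
      ztpi_future_mean = pmin(5, pmax(1, 3.4 + 0.55 *
        (0.75 * future + sqrt(1 - 0.75^2) * rnorm(n)))),
      pfe_ratio = pmin(1, pmax(0, round(10 * (0.4 + 0.15 *
        (0.4 * future + sqrt(1 - 0.4^2) * rnorm(n)))) / 10)),
      bdi_total = pmin(63, pmax(0, round(12 + 8 *
        (0.8 * negativity + 0.6 * rnorm(n))))),
      stai_total = pmin(80, pmax(20, round(45 + 10 *
        (0.8 * negativity + 0.6 * rnorm(n))))),
      atq_na_mean = pmin(7, pmax(1, 3.8 + 0.9 *
        (0.8 * negativity + 0.6 * rnorm(n))))
    )
    agent_seeds <- sample.int(.Machine$integer.max %/% 2, n)
  })
  choices <- purrr::map_dfr(seq_len(n), function(i) {
    tibble::tibble(
      participant_id = i,
      trial_id = trials$trial_id,
      choice = simulate_agent_choices(
        list(log_k = agents$logk_true[i], alpha = agents$alpha_true[i],
             epsilon = agents$eps_true[i]),
        trials, seed = agent_seeds[i])
    )
  })
  items <- purrr::map_dfr(seq_len(n), function(i) {
    dplyr::mutate(
      simulate_questionnaire_responses(
        agents[i, c("eat26_total", "cfc_total", "ztpi_future_mean",
                    "pfe_ratio", "bdi_total", "stai_total", "atq_na_mean")],
        seed = agent_seeds[i] + 1L),
      participant_id = i, .before = 1)
  })
  list(agents = agents, trials = trials, choices = choices, items = items)
}
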