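#' Hyperbolic subjective value
#'
#' Discounts a delayed reward hyperbolically: `SV = A / (1 + k * t)`, where
#' `A` is the reward amount, `t` the delay in days and `k` the discount rate
#' per day. At `t = 0` the subjective value equals the amount; for `A > 0`
#' it decreases strictly in both `t` and `k`.
#'
#' @param amount Reward amount (USD), >= 0. Vectorized.
#' @param k Discount rate per day, >= 0.
#' @param t Delay in days, >= 0.
#' @return Subjective value in the same units as `amount`.
#' @export
#' @examples
#' hyperbolic_sv(100, 0.01, 100)  # 50
hyperbolic_sv <- function(amount, k, t) {
  if (any(amount < 0)) abort("`amount` must be >= 0.")
  if (any(k < 0)) abort("`k` must be >= 0.")
  if (any(t < 0)) abort("`t` must be >= 0.")
  amount / (1 + k * t)
}

#' Constant-sensitivity (Ebert-Prelec) subjective value
#'
#' `SV = A * exp(-(a * t)^b)`, separating impatience (`a`) from sensitivity
#' to time (`b`). `b = 1` recovers exponential discounting; `t = 0` returns
#' the undiscounted amount.
#'
#' @param amount Reward amount, >= 0. Vectorized.
#' @param a Impatience parameter, >= 0 (per day).
#' @param b Time-sensitivity parameter, > 0 (dimensionless).
#' @param t Delay in days, >= 0.
#' @return Subjective value.
#' @export
#' @examples
#' ebert_prelec_sv(30, 0.01, 1, 100)  # 30 * exp(-1)
ebert_prelec_sv <- function(amount, a, b, t) {
  if (any(amount < 0)) abort("`amount` must be >= 0.")
  if (any(a < 0)) abort("`a` must be >= 0.")
  if (any(b <= 0)) abort("`b` must be > 0.")
  if (any(t < 0)) abort("`t` must be >= 0.")
  amount * exp(-(a * t)^b)
}

#' Probability of choosing the larger-later option
#'
#' Models a binary intertemporal decision as a noisy function of the
#' subjective-value difference:
#' `p(LL) = epsilon + (1 - 2 * epsilon) * Phi((SV_LL - SV_SS) / alpha)`,
#' where `Phi` is the standard normal CDF, `epsilon` is a lapse rate (the
#' probability mass of value-independent random responding) and `alpha` is
#' the acuity of the value comparison, in money units. The output is bounded
#' in `[epsilon, 1 - epsilon]`, equals 0.5 when the subjective values tie,
#' and is nondecreasing in `SV_LL`.
#'
#' @param sv_ss Subjective value of the smaller-sooner option. Vectorized.
#' @param sv_ll Subjective value of the larger-later option.
#' @param alpha Comparison-acuity noise, > 0 (money units).
#' @param epsilon Lapse rate in `[0, 0.5]`.
#' @return Probability of choosing the larger-later option.
#' @export
#' @examples
#' choice_probability(50, 60, alpha = 10, epsilon = 0)  # pnorm(1)
choice_probability <- function(sv_ss, sv_ll, alpha, epsilon) {
  if (any(alpha <= 0)) abort("`alpha` must be > 0.")
  if (any(epsilon < 0 | epsilon > 0.5)) abort("`epsilon` must lie in [0, 0.5].")
  epsilon + (1 - 2 * epsilon) * pnorm((sv_ll - sv_ss) / alpha)
}

#' Log discount rate giving an even split on a choice set
#'
#' Grid-searches log(k) for the value at which a noiseless hyperbolic
#' decision-maker picks the larger-later option on exactly half the trials
#' of a choice set. A prior centred on this value encodes the expectation
#' that the choice set samples discount rates evenly.
#'
#' @param trials A trial tibble from [build_choice_set()] (catch rows are
#'   ignored).
#' @param grid Numeric vector of log(k) values to search.
#' @return The grid value whose larger-later fraction is nearest 0.5
#'   (midpoint of the nearest values if tied).
#' @export
balanced_log_k <- function(trials, grid = seq(-10, -1, by = 0.01)) {
  task <- trials[!trials$is_catch, ]
  if (!nrow(task)) abort("No non-catch trials supplied.")
  frac_ll <- vapply(grid, function(lk) {
    k <- exp(lk)
    sv_ss <- hyperbolic_sv(task$ss_amount, k, task$ss_delay_days)
    sv_ll <- hyperbolic_sv(task$ll_amount, k, task$ll_delay_days)
    mean(sv_ll > sv_ss)
  }, numeric(1))
  best <- which(abs(frac_ll - 0.5) == min(abs(frac_ll - 0.5)))
  mean(range(grid[best]))
}
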