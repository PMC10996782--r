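#' Interval-production (counting task) accuracy
#'
#' Mean signed error of produced time intervals, per pacing block. In the
#' counting task, numerals flash at 1 Hz or 0.5 Hz and the participant
#' keeps counting silently until reaching a target interval; the produced
#' interval is the elapsed time at the stop response. The per-trial error
#' is `produced - target` (seconds; positive = overproduction) and the
#' block summary is the mean over that block's trials. Trials with a
#' missing response are dropped and counted.
#'
#' @param trials Tibble with columns `participant_id`, `block_hz` (1 or
#'   0.5), `target_s`, `produced_s`.
#' @return Tibble with one row per participant and block: `block_hz`,
#'   `mean_error_s`, `n_trials`, `n_dropped`.
#' @export
volle_accuracy <- function(trials) {
  need <- c("participant_id", "block_hz", "target_s", "produced_s")
  if (!all(need %in% names(trials))) {
    abort("`trials` needs participant_id, block_hz, target_s, produced_s.")
  }
  tibble::as_tibble(trials) |>
    dplyr::mutate(error = .data$produced_s - .data$target_s) |>
    dplyr::summarise(
      mean_error_s = mean(.data$error, na.rm = TRUE),
      n_trials = sum(!is.na(.data$error)),
      n_dropped = sum(is.na(.data$error)),
      .by = c("participant_id", "block_hz")
    )
}

#' Horizon-estimation growth ratio
#'
#' For the future-time-estimation task, participants mark perceived lengths
#' of horizons (1 week up to 10 years) on a bounded slider, with the 1-week
#' horizon always asked first as the anchor. For each non-anchor trial,
#' objective growth is `(T - T_anchor) / T_anchor` and subjective growth is
#' `(S - S_anchor) / S_anchor`; their quotient is the growth ratio, and the
#' participant summary is the arithmetic mean of the per-trial ratios. A
#' ratio of 1 indicates accurate prospective time estimation; values below
#' 1 indicate compressed subjective growth. The ratio is invariant to a
#' common rescaling of the slider, except when the anchor response is 0,
#' which leaves subjective growth undefined and flags the participant.
#'
#' @param trials Tibble with columns `participant_id`, `horizon_days`,
#'   `slider`.
#' @param anchor_days Anchor horizon (default 7 = 1 week).
#' @return Tibble with one row per participant: `growth_ratio` (mean over
#'   non-anchor trials, `NA` when flagged), `n_trials`, `flagged`.
#' @export
#' @examples
#' zauberman_growth_ratio(tibble::tibble(
#'   participant_id = 1, horizon_days = c(7, 21), slider = c(10, 20)))
zauberman_growth_ratio <- function(trials, anchor_days = 7) {
  need <- c("participant_id", "horizon_days", "slider")
  if (!all(need %in% names(trials))) {
    abort("`trials` needs participant_id, horizon_days, slider.")
  }
  one <- function(d) {
    a <- d$slider[d$horizon_days == anchor_days]
    if (!length(a)) abort("Anchor trial missing for a participant.")
    a <- a[1]
    rest <- d[d$horizon_days != anchor_days, , drop = FALSE]
    if (!nrow(rest)) abort("Need at least one non-anchor trial.")
    if (a == 0) {
      return(tibble::tibble(growth_ratio = NA_real_, n_trials = nrow(rest),
                            flagged = TRUE))
    }
    obj <- (rest$horizon_days - anchor_days) / anchor_days
    subj <- (rest$slider - a) / a
    tibble::tibble(growth_ratio = mean(subj / obj), n_trials = nrow(rest),
                   flagged = FALSE)
  }
  tibble::as_tibble(trials) |>
    dplyr::reframe(one(dplyr::pick(dplyr::everything())),
                   .by = "participant_id")
}
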