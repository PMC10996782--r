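#' Describe an intertemporal-choice task design
#'
#' Collects the design constants of the delay-discounting task: number of
#' task trials, the menu of smaller-sooner delays, the span of larger-later
#' delays, the smaller-sooner amount range, the range of relative reward
#' differences, and the number of catch trials. The defaults reproduce the
#' deployed task: 144 trials, sooner delays of today / 2 weeks / 1 month,
#' later delays from 1 week to 6 months, sooner amounts $15-$85, and
#' relative differences from 2% to 100% (so later amounts span $16-$170).
#'
#' Calendar conversions are fixed at 1 week = 7 d, 2 weeks = 14 d,
#' 1 month = 30 d and 6 months = 180 d.
#'
#' @param n_trials Number of non-catch task trials.
#' @param ss_delay_menu Integer vector of allowed smaller-sooner delays (days).
#' @param ll_delay_range Length-2 integer vector; larger-later delays are
#'   drawn from this span (days).
#' @param ss_amount_range Length-2 numeric; smaller-sooner amounts (USD).
#' @param ratio_range Length-2 numeric; range of `ll/ss - 1`.
#' @param n_catch Number of catch trials (2 in the lab arm, 10 online).
#' @param seed Integer seed controlling trial sampling.
#' @return An object of class `task_design` (a list).
#' @export
#' @examples
#' task_design()
task_design <- function(n_trials = 144,
                        ss_delay_menu = c(0L, 14L, 30L),
                        ll_delay_range = c(7L, 180L),
                        ss_amount_range = c(15, 85),
                        ratio_range = c(0.02, 1),
                        n_catch = 2L,
                        seed = 1L) {
  if (n_trials < 1) abort("`n_trials` must be at least 1.")
  if (ratio_range[1] <= 0) {
    abort("`ratio_range` minimum must be positive: a zero or negative relative difference makes the later option non-dominant.")
  }
  if (diff(ss_amount_range) < 0 || diff(ratio_range) < 0 ||
      diff(ll_delay_range) < 0) {
    abort("Design ranges must be non-decreasing (min, max).")
  }
  if (any(ss_delay_menu < 0)) abort("Sooner delays must be >= 0 days.")
  structure(
    list(n_trials = as.integer(n_trials),
         ss_delay_menu = as.integer(ss_delay_menu),
         ll_delay_range = as.integer(ll_delay_range),
         ss_amount_range = ss_amount_range,
         ratio_range = ratio_range,
         n_catch = as.integer(n_catch),
         seed = as.integer(seed)),
    class = "task_design"
  )
}

#' @export
print.task_design <- function(x, ...) {
  cat("<task_design> ", x$n_trials, " trials + ", x$n_catch, " catch\n",
      "  SS: $", x$ss_amount_range[1], "-", x$ss_amount_range[2],
      " at ", paste(x$ss_delay_menu, collapse = "/"), " d; ",
      "LL: +", 100 * x$ratio_range[1], "% to +", 100 * x$ratio_range[2],
      "% at ", x$ll_delay_range[1], "-", x$ll_delay_range[2], " d\n",
      sep = "")
  invisible(x)
}

#' Build the intertemporal-choice trial set
#'
#' Generates `design$n_trials` non-catch trials. Smaller-sooner amounts and
#' relative reward differences are each taken as an evenly spaced grid over
#' the design range and randomly paired, so both ranges are fully covered;
#' the two extreme pairings (minimum amount with minimum difference, maximum
#' with maximum) are always present, which pins the later-amount span at its
#' nominal endpoints ($16 and $170 under the defaults). Later amounts are
#' rounded up to whole dollars, which keeps the realized relative difference
#' inside the design range and guarantees the later amount strictly exceeds
#' the sooner one. Later delays are drawn uniformly from the design span,
#' at least one week after the sooner delay. Screen side of the later option
#' alternates so left/right counts are equal to within 1.
#'
#' When `table` is supplied (e.g. a verbatim copy of a deployed trial list),
#' it is validated against the trial invariants and returned as-is instead
#' of sampling.
#'
#' @param design A [task_design()].
#' @param table Optional data frame with columns `trial_id`, `ss_amount`,
#'   `ss_delay_days`, `ll_amount`, `ll_delay_days` (and optionally
#'   `is_catch`, `side_ll`) to use verbatim.
#' @return A tibble with columns `trial_id`, `ss_amount`, `ss_delay_days`,
#'   `ll_amount`, `ll_delay_days`, `is_catch`, `side_ll`.
#' @export
#' @examples
#' trials <- build_choice_set(task_design(seed = 7))
#' range(trials$ll_amount)
build_choice_set <- function(design = task_design(), table = NULL) {
  if (!inherits(design, "task_design")) abort("`design` must be a task_design.")
  if (!is.null(table)) {
    out <- tibble::as_tibble(table)
    if (!"is_catch" %in% names(out)) out$is_catch <- FALSE
    if (!"side_ll" %in% names(out)) {
      out$side_ll <- rep_len(c("left", "right"), nrow(out))
    }
    validate_choice_set(out)
    return(out)
  }
  n <- design$n_trials
  withr_seed(design$seed, {
    ss <- round(seq(design$ss_amount_range[1], design$ss_amount_range[2],
                    length.out = n))
    ratio <- seq(design$ratio_range[1], design$ratio_range[2], length.out = n)
    ratio <- sample(ratio)
    # pin the printed extremes: min amount with min difference, max with max
    swap_to <- function(x, pos, value) {
      j <- which(x == value)[1]
      x[j] <- x[pos]; x[pos] <- value
      x
    }
    ratio <- swap_to(ratio, which.min(ss)[1], design$ratio_range[1])
    ratio <- swap_to(ratio, which.max(ss)[1], design$ratio_range[2])
    ll <- ceiling(ss * (1 + ratio))
    ss_d <- sample(design$ss_delay_menu, n, replace = TRUE)
    # informativeness: an indifference k exists only if t_LL exceeds
    # (A_LL/A_SS) * t_SS; a full-day margin above that bound keeps the
    # indifference rate at or below (A_LL/A_SS - 1) per day, i.e. k <= 1
    lo <- pmax(design$ll_delay_range[1], ss_d + 7L,
               ceiling((ll / ss) * ss_d) + 1L)
    # spread trial indifference points evenly on the log scale across the
    # range the design can express, so discount rates are estimable over
    # the whole plausible span; the later delay realizes each target
    r_min <- design$ratio_range[1]; r_max <- design$ratio_range[2]
    t_max <- design$ll_delay_range[2]
    # rank-match targets to reward ratios (small differences with low
    # targets, i.e. long delays) so the whole grid is realizable within
    # the delay bounds; jitter keeps the pairing from being deterministic
    lk_grid <- seq(log(r_min / t_max),
                   log(r_max / design$ll_delay_range[1]),
                   length.out = n) + rnorm(n, 0, 0.25)
    k_target <- exp(sort(lk_grid)[rank(ratio, ties.method = "first")])
    ll_d <- as.integer(pmin(t_max, pmax(lo, round((ll / ss - 1) / k_target +
                                                    (ll / ss) * ss_d))))
    side <- sample(rep_len(c("left", "right"), n))
    out <- tibble::tibble(
      trial_id = seq_len(n),
      ss_amount = as.numeric(ss),
      ss_delay_days = as.integer(ss_d),
      ll_amount = as.numeric(ll),
      ll_delay_days = as.integer(ll_d),
      is_catch = FALSE,
      side_ll = side
    )
  })
  validate_choice_set(out)
  out
}

# internal invariant checks shared by generated and verbatim trial tables
validate_choice_set <- function(trials) {
  task <- trials[!trials$is_catch, ]
  if (nrow(task)) {
    if (any(task$ll_delay_days <= task$ss_delay_days)) {
      abort("Non-catch trials must have ll_delay > ss_delay.")
    }
    if (any(task$ll_amount <= task$ss_amount)) {
      abort("Non-catch trials must have ll_amount > ss_amount.")
    }
  }
  catch <- trials[trials$is_catch, ]
  if (nrow(catch) && any(catch$ll_amount >= catch$ss_amount)) {
    abort("Catch trials must have a dominated (smaller) later option.")
  }
  invisible(trials)
}

#' Build catch trials with a dominated later option
#'
#' Catch trials pair a larger-sooner reward with a smaller-later reward
#' (e.g. $10 today vs. $5 in two weeks), so the sooner option strictly
#' dominates and any later choice marks inattention.
#'
#' @param n Number of catch trials (0 allowed).
#' @param seed Integer seed.
#' @return A tibble in the same schema as [build_choice_set()], with
#'   `is_catch = TRUE`.
#' @export
#' @examples
#' build_catch_trials(2)
build_catch_trials <- function(n = 2L, seed = 1L) {
  if (n < 0) abort("`n` must be >= 0.")
  n <- as.integer(n)
  if (n == 0L) {
    return(tibble::tibble(trial_id = integer(), ss_amount = numeric(),
                          ss_delay_days = integer(), ll_amount = numeric(),
                          ll_delay_days = integer(), is_catch = logical(),
                          side_ll = character()))
  }
  withr_seed(seed, {
    ss <- sample(8:15, n, replace = TRUE)
    out <- tibble::tibble(
      trial_id = seq_len(n),
      ss_amount = as.numeric(ss),
      ss_delay_days = 0L,
      ll_amount = as.numeric(pmax(1, round(ss / 3))),
      ll_delay_days = sample(c(7L, 14L, 30L), n, replace = TRUE),
      is_catch = TRUE,
      side_ll = sample(rep_len(c("left", "right"), n))
    )
  })
  validate_choice_set(out)
  out
}

#' Interleave catch trials at random positions
#'
#' Places catch trials at seeded random positions among the task trials and
#' renumbers `trial_id` in presentation order.
#'
#' @param trials Non-catch trial tibble.
#' @param catch Catch trial tibble.
#' @param seed Integer seed for placement.
#' @return A single tibble in presentation order.
#' @export
interleave_catch_trials <- function(trials, catch, seed = 1L) {
  all <- dplyr::bind_rows(trials, catch)
  withr_seed(seed, ord <- sample(nrow(all)))
  out <- all[ord, ]
  out$trial_id <- seq_len(nrow(out))
  out
}

#' Check responses on catch trials
#'
#' A participant fails the catch check if the dominated later option was
#' chosen on any catch trial; the strictest reading of "failed a catch
#' trial" (one dominated choice excludes) is applied downstream.
#'
#' @param trials A trial tibble; only rows with `is_catch = TRUE` are used.
#' @param responses Character vector of choice codes (`"SS"` or `"LL"`)
#'   aligned with the catch rows of `trials`.
#' @return A one-row tibble with `pass` (no dominated choices) and
#'   `n_failures`.
#' @export
#' @examples
#' validate_catch_responses(build_catch_trials(2), c("SS", "SS"))
validate_catch_responses <- function(trials, responses) {
  catch <- trials[trials$is_catch, , drop = FALSE]
  if (length(responses) != nrow(catch)) {
    abort("`responses` must align with the catch trials (length mismatch).")
  }
  if (length(responses) && !all(responses %in% c("SS", "LL"))) {
    abort("Choice codes must be 'SS' or 'LL'.")
  }
  n_fail <- sum(responses == "LL")
  tibble::tibble(pass = n_fail == 0L, n_failures = as.integer(n_fail))
}

# run code under a local RNG seed without disturbing the caller's stream
withr_seed <- function(seed, code) {
  force(seed)   # resolve before snapshotting the caller's RNG state
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(code))
}
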