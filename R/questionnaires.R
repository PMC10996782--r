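eat26_menu <- c("Never", "Rarely", "Sometimes", "Often", "Usually", "Always")
cfc_menu <- c("extremely uncharacteristic", "somewhat uncharacteristic",
              "uncertain", "somewhat characteristic",
              "extremely characteristic")

# ZTPI future subscale per the published 56-item instrument;
# reverse-keyed items are scored 6 - x
ztpi_future_items <- c(6L, 9L, 10L, 13L, 18L, 21L, 24L, 30L, 40L, 43L, 45L,
                       51L, 56L)
ztpi_future_reversed <- c(9L, 24L, 56L)

# STAI trait items keyed for anxiety absence (scored 5 - x)
stai_trait_reversed <- c(1L, 3L, 6L, 7L, 10L, 13L, 14L, 16L, 19L)

cfc_reversed <- c(3L, 4L, 5L, 9L, 10L, 11L, 12L)

scale_lengths <- c(eat26 = 26L, cfc = 12L, ztpi = 56L, pfe = 10L,
                   bdi = 21L, stai = 20L, atq_na = 26L)

coerce_items <- function(items, scale, menu = NULL) {
  if (is.data.frame(items)) {
    stopifnot(all(c("item", "response") %in% names(items)))
    v <- rep(NA, scale_lengths[[scale]])
    v[items$item] <- items$response
    items <- v
  }
  n <- scale_lengths[[scale]]
  if (length(items) != n) {
    abort(paste0("`", scale, "` expects ", n, " items, got ", length(items),
                 "."))
  }
  if (!is.null(menu) && !all(is.na(items) | items %in% menu)) {
    abort(paste0("Unknown response label for ", scale, "."))
  }
  items
}

#' Score the Eating Attitudes Test (EAT-26)
#'
#' Items 1-25 are coded Never/Rarely/Sometimes = 0, Often = 1, Usually = 2,
#' Always = 3; item 26 is reverse-coded (Always/Usually/Often = 0,
#' Sometimes = 1, Rarely = 2, Never = 3). The total ranges 0-78; totals
#' above 20 (i.e. 21 or more) label the respondent "high" eating-disorder
#' risk. With `exclude_bulimia = TRUE`, the binge-eating/purging items 4, 9
#' and 25 are dropped before summing and the same cutoff reapplied, giving
#' a risk index more specific to restrictive (anorexia-like) symptoms.
#'
#' @param items Character vector of 26 responses on the
#'   Never/Rarely/Sometimes/Often/Usually/Always menu, or a data frame with
#'   `item` and `response` columns. Missing responses are allowed and
#'   ignored in the sum (completion is policed by
#'   [apply_quality_exclusions()]).
#' @param exclude_bulimia Drop items 4, 9, 25 before summing.
#' @param cutoff Risk cutoff; totals strictly above it are "high".
#' @return One-row tibble with `total`, `risk_group`, `completion`.
#' @export
#' @examples
#' score_eat26(rep("Never", 26))   # total 3, low risk
#' score_eat26(rep("Always", 26))  # total 75, high risk
score_eat26 <- function(items, exclude_bulimia = FALSE, cutoff = 20) {
  items <- coerce_items(items, "eat26", eat26_menu)
  fwd <- pmax(match(items, eat26_menu) - 3L, 0L)        # 0,0,0,1,2,3
  rev <- pmax(4L - match(items, eat26_menu), 0L)        # 3,2,1,0,0,0
  code <- c(fwd[1:25], rev[26])
  keep <- if (exclude_bulimia) setdiff(1:26, c(4L, 9L, 25L)) else 1:26
  total <- sum(code[keep], na.rm = TRUE)
  tibble::tibble(
    total = total,
    risk_group = if (total > cutoff) "high" else "low",
    completion = mean(!is.na(items[keep]))
  )
}

#' Score the Consideration of Future Consequences scale (CFC)
#'
#' Twelve items on a 5-point characteristicness menu; items 1, 2, 6, 7, 8
#' are coded 1-5 ascending and items 3-5 and 9-12 are reverse-coded
#' (6 - x). The total ranges 12-60, higher meaning more future-minded.
#'
#' @param items Character vector of 12 responses on the CFC menu, integer
#'   codes 1-5, or a data frame with `item`/`response` columns.
#' @return One-row tibble with `total` and `completion`.
#' @export
#' @examples
#' score_cfc(rep("uncertain", 12))  # 36
score_cfc <- function(items) {
  items <- coerce_items(items, "cfc")
  x <- if (is.numeric(items)) items else as.integer(match(items, cfc_menu))
  if (!all(is.na(x) | (x >= 1 & x <= 5))) {
    abort("CFC responses must be on the 1-5 menu.")
  }
  x[cfc_reversed] <- 6L - x[cfc_reversed]
  tibble::tibble(total = sum(x, na.rm = TRUE), completion = mean(!is.na(x)))
}

#' Score the ZTPI future-orientation subscale
#'
#' Mean of the 13 future-subscale items of the 56-item Zimbardo Time
#' Perspective Inventory (items 6, 9, 10, 13, 18, 21, 24, 30, 40, 43, 45,
#' 51, 56; items 9, 24 and 56 reverse-keyed), each rated 1-5. Missing items
#' are ignored in the mean; the completion fraction is returned so the
#' 75%-completion rule can be applied downstream.
#'
#' @param items Numeric vector of all 56 ZTPI responses (1-5; positions
#'   outside the future subscale may be `NA`), or a data frame with
#'   `item`/`response` columns.
#' @return One-row tibble with `mean_score` and `completion` (of the future
#'   subscale).
#' @export
score_ztpi_future <- function(items) {
  items <- coerce_items(items, "ztpi")
  x <- as.numeric(items)
  ok <- !is.na(x)
  if (!all(is.na(x) | (x >= 1 & x <= 5))) {
    abort("ZTPI responses must lie in 1-5.")
  }
  x[ztpi_future_reversed] <- 6 - x[ztpi_future_reversed]
  fut <- x[ztpi_future_items]
  if (all(is.na(fut))) {
    return(tibble::tibble(mean_score = NA_real_, completion = 0))
  }
  tibble::tibble(mean_score = mean(fut, na.rm = TRUE),
                 completion = mean(!is.na(fut)))
}

#' Score preoccupation with future events (PFE)
#'
#' Participants list up to ten recent thoughts and label each as past,
#' present or future; the score is the fraction of listed thoughts labeled
#' future.
#'
#' @param thought_labels Character vector of labels in
#'   `c("past", "present", "future")` (1-10 entries).
#' @return One-row tibble with `ratio` (`NA` and flagged if no thoughts
#'   listed) and `n_listed`.
#' @export
#' @examples
#' score_pfe(c("future", "past", "future", "present"))  # 0.5
score_pfe <- function(thought_labels) {
  thought_labels <- thought_labels[!is.na(thought_labels)]
  if (!all(thought_labels %in% c("past", "present", "future"))) {
    abort("Thought labels must be past/present/future.")
  }
  n <- length(thought_labels)
  tibble::tibble(
    ratio = if (n == 0) NA_real_ else sum(thought_labels == "future") / n,
    n_listed = n
  )
}

#' Score the dispositional-negativity instruments
#'
#' Standard scoring for the three mood/anxiety questionnaires whose latent
#' factor defines dispositional negativity: Beck Depression Inventory (21
#' items coded 0-3, summed), trait STAI (20 items rated 1-4, anxiety-absent
#' items 1, 3, 6, 7, 10, 13, 14, 16, 19 reverse-keyed, summed) and the
#' negative-affect subscale of the short-form Adult Temperament
#' Questionnaire (26 items rated 1-7, averaged).
#'
#' @param bdi Numeric vector of 21 BDI responses (0-3).
#' @param stai Numeric vector of 20 trait-STAI responses (1-4).
#' @param atq_na Numeric vector of 26 ATQ negative-affect responses (1-7).
#' @return One-row tibble with `bdi_total`, `stai_total`, `atq_na_mean` and
#'   per-scale completion fractions.
#' @export
score_negativity_scales <- function(bdi, stai, atq_na) {
  bdi <- coerce_items(bdi, "bdi")
  stai <- coerce_items(stai, "stai")
  atq_na <- coerce_items(atq_na, "atq_na")
  if (!all(is.na(bdi) | (bdi >= 0 & bdi <= 3))) {
    abort("BDI responses must lie in 0-3.")
  }
  if (!all(is.na(stai) | (stai >= 1 & stai <= 4))) {
    abort("STAI responses must lie in 1-4.")
  }
  if (!all(is.na(atq_na) | (atq_na >= 1 & atq_na <= 7))) {
    abort("ATQ-NA responses must lie in 1-7.")
  }
  stai_coded <- stai
  stai_coded[stai_trait_reversed] <- 5 - stai_coded[stai_trait_reversed]
  tibble::tibble(
    bdi_total = sum(bdi, na.rm = TRUE),
    stai_total = sum(stai_coded, na.rm = TRUE),
    atq_na_mean = mean(atq_na, na.rm = TRUE),
    bdi_completion = mean(!is.na(bdi)),
    stai_completion = mean(!is.na(stai)),
    atq_na_completion = mean(!is.na(atq_na))
  )
}

#' Apply the protocol data-quality exclusions
#'
#' Drops participants who completed less than `min_completion` of any used
#' scale, then (in a single, non-iterative pass) participants whose value
#' on each of `outlier_cols` lies more than `outlier_sd` SDs from the
#' pre-exclusion sample mean of that column. Every exclusion is logged with
#' its reason.
#'
#' @param scored Tibble of scored participants, one row each.
#' @param completion_cols Character vector of completion-fraction columns
#'   to police (default: every column ending in `"completion"`).
#' @param outlier_cols Character vector of score columns subject to the SD
#'   rule (e.g. a factor-score column); may be empty.
#' @param min_completion Minimum completion fraction (default 0.75).
#' @param outlier_sd SD cutoff (default 3).
#' @return List with `retained` (tibble) and `exclusions` (tibble of
#'   `participant_id`, `reason`, `detail`).
#' @export
apply_quality_exclusions <- function(scored,
                                     completion_cols = NULL,
                                     outlier_cols = character(),
                                     min_completion = 0.75,
                                     outlier_sd = 3) {
  scored <- tibble::as_tibble(scored)
  if (is.null(completion_cols)) {
    completion_cols <- grep("completion$", names(scored), value = TRUE)
  }
  excl <- tibble::tibble(participant_id = scored$participant_id[0],
                         reason = character(), detail = character())
  drop <- rep(FALSE, nrow(scored))
  for (col in completion_cols) {
    bad <- !is.na(scored[[col]]) & scored[[col]] < min_completion
    if (any(bad)) {
      excl <- dplyr::bind_rows(excl, tibble::tibble(
        participant_id = scored$participant_id[bad],
        reason = "insufficient responses", detail = col))
      drop <- drop | bad
    }
  }
  for (col in outlier_cols) {
    v <- scored[[col]]
    m <- mean(v, na.rm = TRUE); s <- sd(v, na.rm = TRUE)
    bad <- !is.na(v) & s > 0 & abs(v - m) > outlier_sd * s
    if (any(bad)) {
      excl <- dplyr::bind_rows(excl, tibble::tibble(
        participant_id = scored$participant_id[bad],
        reason = "outlier", detail = col))
      drop <- drop | bad
    }
  }
  list(retained = scored[!drop, ],
       exclusions = dplyr::distinct(excl))
}
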