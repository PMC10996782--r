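test_that("EAT-26 coding rules force the boundary totals", {
  never <- score_eat26(rep("Never", 26))
  expect_equal(never$total, 3)          # item 26 reverse-codes Never to 3
  expect_equal(never$risk_group, "low")
  always <- score_eat26(rep("Always", 26))
  expect_equal(always$total, 75)        # 25 x 3 + 0
  expect_equal(always$risk_group, "high")
  expect_error(score_eat26(rep("Perhaps", 26)), "Unknown")
  expect_error(score_eat26(rep("Never", 25)), "26 items")
})

test_that("the risk cutoff is strictly above 20", {
  for (target in c(20, 21)) {
    items <- simulate_questionnaire_responses(list(eat26_total = target))
    s <- score_eat26(items$response)
    expect_equal(s$total, target)
    expect_equal(s$risk_group, if (target > 20) "high" else "low")
  }
})

test_that("dropping the bulimia items never raises the total", {
  set.seed(31)
  for (i in 1:30) {
    resp <- sample(c("Never", "Rarely", "Sometimes", "Often", "Usually",
                     "Always"), 26, replace = TRUE)
    full <- score_eat26(resp)$total
    nobul <- score_eat26(resp, exclude_bulimia = TRUE)$total
    expect_lte(nobul, full)
  }
})

test_that("CFC reversal key gives the documented totals and bounds", {
  expect_equal(score_cfc(rep("extremely uncharacteristic", 12))$total, 40)
  expect_equal(score_cfc(rep("uncertain", 12))$total, 36)
  maxed <- rep(5, 12); maxed[c(3:5, 9:12)] <- 1
  expect_equal(score_cfc(maxed)$total, 60)
  minned <- rep(1, 12); minned[c(3:5, 9:12)] <- 5
  expect_equal(score_cfc(minned)$total, 12)
  expect_error(score_cfc(rep(6, 12)), "1-5")
})

test_that("ZTPI future subscale averages with its reverse key", {
  raw <- rep(NA_real_, 56)
  fut <- c(6, 9, 10, 13, 18, 21, 24, 30, 40, 43, 45, 51, 56)
  rev <- c(9, 24, 56)
  raw[fut] <- 5; raw[rev] <- 1
  expect_equal(score_ztpi_future(raw)$mean_score, 5)
  raw[fut] <- 3; raw[rev] <- 3
  expect_equal(score_ztpi_future(raw)$mean_score, 3)
  raw[fut] <- c(rep(2, 6), rep(4, 6), 3); raw[rev] <- 6 - raw[rev]
  expect_equal(score_ztpi_future(raw)$mean_score, 3)
  # missing future items are ignored in the mean, tracked in completion
  raw[fut] <- 4; raw[rev] <- 2; raw[fut[1:3]] <- NA
  s <- score_ztpi_future(raw)
  expect_equal(s$mean_score, 4)
  expect_equal(s$completion, 10 / 13)
  expect_true(is.na(score_ztpi_future(rep(NA_real_, 56))$mean_score))
})

test_that("PFE is the fraction of future-labeled thoughts", {
  expect_equal(score_pfe(c(rep("future", 4), rep("past", 3),
                           rep("present", 3)))$ratio, 0.4)
  expect_equal(score_pfe(rep("past", 10))$ratio, 0)
  expect_equal(score_pfe(rep("future", 7))$ratio, 1)
  expect_true(is.na(score_pfe(character())$ratio))
  expect_error(score_pfe(c("future", "later")), "past/present/future")
})

test_that("negativity scales hit their floors and ceilings", {
  stai_min <- rep(1, 20); stai_min[c(1, 3, 6, 7, 10, 13, 14, 16, 19)] <- 4
  lo <- score_negativity_scales(rep(0, 21), stai_min, rep(1, 26))
  expect_equal(lo$bdi_total, 0)
  expect_equal(lo$stai_total, 20)
  expect_equal(lo$atq_na_mean, 1)
  stai_max <- rep(4, 20); stai_max[c(1, 3, 6, 7, 10, 13, 14, 16, 19)] <- 1
  hi <- score_negativity_scales(rep(3, 21), stai_max, rep(7, 26))
  expect_equal(hi$bdi_total, 63)
  expect_equal(hi$stai_total, 80)
  expect_equal(hi$atq_na_mean, 7)
  expect_error(score_negativity_scales(rep(4, 21), stai_min, rep(1, 26)),
               "0-3")
})

test_that("scoring is pure, order-independent and idempotent", {
  items <- simulate_questionnaire_responses(list(eat26_total = 17), seed = 8)
  df <- data.frame(item = 1:26, response = items$response)
  shuffled <- df[sample(26), ]
  expect_equal(score_eat26(df), score_eat26(shuffled))
  expect_equal(score_eat26(df), score_eat26(df))
})

test_that("quality exclusions drop low completion and outliers with reasons", {
  scored <- tibble::tibble(
    participant_id = 1:20,
    score = c(rnorm(19), 0),
    cfc_completion = c(0.70, rep(1, 19))
  )
  # far enough out to exceed 3 SD of the full (outlier-inclusive) sample
  scored$score[20] <- mean(scored$score[1:19]) + 8 * sd(scored$score[1:19])
  out <- apply_quality_exclusions(scored, outlier_cols = "score")
  expect_equal(sort(out$exclusions$participant_id), c(1L, 20L))
  expect_setequal(out$exclusions$reason,
                  c("insufficient responses", "outlier"))
  expect_equal(nrow(out$retained), 18)
  expect_false(any(out$retained$participant_id %in% c(1, 20)))
})

test_that("the outlier rule is a single pass over the pre-exclusion sample", {
  # a moderate value that is < 3 SD with the extreme point included must
  # survive, even if it would exceed 3 SD after the extreme is removed
  v <- c(rep(0, 30), 2.1, 30)
  scored <- tibble::tibble(participant_id = seq_along(v), score = v)
  out <- apply_quality_exclusions(scored, completion_cols = character(),
                                  outlier_cols = "score")
  expect_equal(out$exclusions$participant_id, 32L)
  expect_true(31 %in% out$retained$participant_id)
})
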