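#' Score a cohort's item-level questionnaire responses
#'
#' Applies every scale's scoring function to an item-level response table
#' (the schema written by [simulate_cohort()] or read from per-scale
#' CSVs) and returns one row per participant with all scale scores and
#' completion fractions.
#'
#' @param items Tibble with columns `participant_id`, `scale`, `item`,
#'   `response` (character).
#' @return Tibble with one row per participant: `eat26_total`,
#'   `eat26_total_no_bulimia`, `risk_group`, `cfc_total`,
#'   `ztpi_future_mean`, `pfe_ratio`, `bdi_total`, `stai_total`,
#'   `atq_na_mean` and per-scale `*_completion` columns.
#' @export
score_cohort_items <- function(items) {
  items <- tibble::as_tibble(items)
  one <- function(d) {
    pick <- function(sc) {
      s <- d[d$scale == sc, ]
      if (!nrow(s)) return(NULL)
      v <- rep(NA_character_, scale_lengths[[sc]])
      v[s$item] <- s$response
      v
    }
    out <- tibble::tibble(.rows = 1)
    if (!is.null(v <- pick("eat26"))) {
      e <- score_eat26(v)
      eb <- score_eat26(v, exclude_bulimia = TRUE)
      out <- dplyr::bind_cols(out, tibble::tibble(
        eat26_total = e$total, risk_group = e$risk_group,
        eat26_total_no_bulimia = eb$total,
        risk_group_no_bulimia = eb$risk_group,
        eat26_completion = e$completion))
    }
    if (!is.null(v <- pick("cfc"))) {
      s <- score_cfc(as.numeric(v))
      out <- dplyr::bind_cols(out, tibble::tibble(
        cfc_total = s$total, cfc_completion = s$completion))
    }
    if (!is.null(v <- pick("ztpi"))) {
      s <- score_ztpi_future(as.numeric(v))
      out <- dplyr::bind_cols(out, tibble::tibble(
        ztpi_future_mean = s$mean_score, ztpi_completion = s$completion))
    }
    if (!is.null(v <- pick("pfe"))) {
      s <- score_pfe(v[!is.na(v)])
      out <- dplyr::bind_cols(out, tibble::tibble(
        pfe_ratio = s$ratio,
        pfe_completion = sum(!is.na(v)) / 10))
    }
    has_neg <- !is.null(pick("bdi")) && !is.null(pick("stai")) &&
      !is.null(pick("atq_na"))
    if (has_neg) {
      s <- score_negativity_scales(as.numeric(pick("bdi")),
                                   as.numeric(pick("stai")),
                                   as.numeric(pick("atq_na")))
      out <- dplyr::bind_cols(out, s)
    }
    out
  }
  items |>
    dplyr::reframe(one(dplyr::pick(dplyr::everything())),
                   .by = "participant_id")
}

#' Pipeline configuration
#'
#' Bundles every stage's settings; all stage seeds derive from the single
#' `seed`, so a run is fully reproducible from the configuration alone.
#'
#' @param cohort A [cohort_config()] (its seed is overridden by `seed`).
#' @param design A [task_design()] (ditto).
#' @param prior A [group_prior()].
#' @param mcmc An [mcmc_settings()] (ditto).
#' @param n_boot Bootstrap resamples for the mediation stage.
#' @param seed Global integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            design = task_design(),
                            prior = group_prior(),
                            mcmc = mcmc_settings(),
                            n_boot = 2000, seed = 1L) {
  seed <- as.integer(seed)
  cohort$seed <- seed
  design$seed <- seed + 1L
  mcmc$seed <- seed + 2L
  structure(list(cohort = cohort, design = design, prior = prior,
                 mcmc = mcmc, n_boot = as.integer(n_boot), seed = seed),
            class = "pipeline_config")
}

#' Run the end-to-end analysis pipeline on a simulated cohort
#'
#' Executes the full analysis in order: simulate the cohort; score the
#' questionnaires; apply the questionnaire-stream exclusions (75%
#' completion, then a single-pass 3-SD rule on the future-orientation
#' factor score); apply the discounting-stream exclusions (any failed
#' catch trial, then model-flagged random responders); fit the
#' hierarchical discounting model separately per risk group; derive the
#' future-orientation (3- and 2-indicator) and dispositional-negativity
#' factors; and run the group comparisons, correlations and the bootstrap
#' mediation (risk group -> future orientation -> log(k)). The two
#' analysis streams keep independent exclusion ledgers whose counts
#' reconcile with the eligible sample.
#'
#' @param config A [pipeline_config()].
#' @return A list report: `samples` (eligible/analyzed counts per stream),
#'   `exclusions` (ledger tibble), `scored` (analysis table of retained
#'   participants), `fits` (per-group [glance.dd_fit()] rows), `factors`
#'   (loadings/variance tibbles), `tests` (tibble of group tests and
#'   correlations), `mediation` (tidy mediation tibble), `config_seed`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- simulate_cohort(config$cohort, config$design)
  n_eligible <- nrow(sim$agents)

  scored <- score_cohort_items(sim$items)

  # --- questionnaire stream -------------------------------------------------
  q1 <- apply_quality_exclusions(scored)
  fo_cols <- c("cfc_total", "ztpi_future_mean", "pfe_ratio")
  complete_fo <- q1$retained[complete.cases(q1$retained[fo_cols]), ]
  fo_pre <- fit_pca_factor(complete_fo[fo_cols])
  complete_fo$future_factor <- as.numeric(fo_pre$scores[, 1])
  q2 <- apply_quality_exclusions(complete_fo, completion_cols = character(),
                                 outlier_cols = "future_factor")
  quest <- q2$retained
  quest_excl <- dplyr::bind_rows(q1$exclusions, q2$exclusions)
  if (!nrow(quest)) abort("Questionnaire stream empty after exclusions.")
  fo3 <- fit_pca_factor(quest[fo_cols])
  fo2 <- fit_pca_factor(quest[c("cfc_total", "ztpi_future_mean")])
  neg_cols <- c("bdi_total", "stai_total", "atq_na_mean")
  neg <- fit_pca_factor(quest[neg_cols], anchor = "bdi_total")
  quest$future_factor <- as.numeric(fo3$scores[, 1])
  quest$future_factor_2ind <- as.numeric(fo2$scores[, 1])
  quest$negativity_factor <- as.numeric(neg$scores[, 1])

  # --- discounting stream ---------------------------------------------------
  catch_ids <- sim$trials$trial_id[sim$trials$is_catch]
  catch_check <- sim$choices |>
    dplyr::filter(.data$trial_id %in% catch_ids) |>
    dplyr::summarise(n_failures = sum(.data$choice == "LL"),
                     .by = "participant_id")
  failed_catch <- catch_check$participant_id[catch_check$n_failures > 0]
  dd_excl <- tibble::tibble(participant_id = failed_catch,
                            reason = "failed catch trial",
                            detail = "delay discounting")
  dd_keep <- setdiff(sim$agents$participant_id, failed_catch)
  fits <- list(); flags <- tibble::tibble()
  for (g in c("high", "low")) {
    ids_g <- sim$agents$participant_id[sim$agents$group == g]
    ids_g <- intersect(ids_g, dd_keep)
    if (!length(ids_g)) {
      abort(paste0("Empty ", g, "-risk group in the discounting stream."))
    }
    fit_g <- fit_discounting(
      dplyr::filter(sim$choices, .data$participant_id %in% ids_g),
      sim$trials, prior = config$prior, settings = config$mcmc)
    fits[[g]] <- fit_g
    flags <- dplyr::bind_rows(flags, detect_random_responders(fit_g))
  }
  random_ids <- flags$participant_id[flags$random_responder]
  dd_excl <- dplyr::bind_rows(dd_excl, tibble::tibble(
    participant_id = random_ids, reason = "random responding",
    detail = "delay discounting"))
  logk_tab <- dplyr::bind_rows(lapply(fits, tidy)) |>
    dplyr::filter(!.data$participant_id %in% random_ids) |>
    dplyr::select("participant_id", log_k = "logk_mean")

  # --- merged analysis table ------------------------------------------------
  analysis <- sim$agents |>
    dplyr::select("participant_id", "group") |>
    dplyr::inner_join(quest, by = "participant_id") |>
    dplyr::left_join(logk_tab, by = "participant_id") |>
    dplyr::mutate(risk_high = as.numeric(.data$group == "high"))

  tests <- dplyr::bind_rows(
    dplyr::mutate(group_ttest(analysis, "log_k", "group",
                              alternative = "less"),
                  test = "log_k by risk group", .before = 1),
    dplyr::mutate(group_ttest(analysis, "future_factor", "group",
                              alternative = "greater"),
                  test = "future orientation by risk group", .before = 1),
    dplyr::mutate(group_ttest(analysis, "negativity_factor", "group"),
                  test = "dispositional negativity by risk group",
                  .before = 1))
  correlations <- dplyr::bind_rows(
    dplyr::mutate(pearson_correlation(analysis, "future_factor", "log_k",
                                      alternative = "less"),
                  test = "future orientation vs log_k", .before = 1),
    dplyr::mutate(pearson_correlation(analysis, "eat26_total",
                                      "negativity_factor"),
                  test = "risk severity vs negativity", .before = 1))

  med <- mediate(analysis, x = "risk_high", y = "log_k",
                 mediators = "future_factor", n_boot = config$n_boot,
                 seed = config$seed + 3L)

  dd_n <- length(setdiff(dd_keep, random_ids))
  list(
    samples = tibble::tibble(
      stream = c("discounting", "questionnaire"),
      eligible = n_eligible,
      analyzed = c(dd_n, nrow(quest)),
      excluded = c(n_eligible - dd_n, n_eligible - nrow(quest))),
    exclusions = dplyr::bind_rows(dd_excl, quest_excl),
    scored = analysis,
    fits = dplyr::bind_rows(lapply(fits, glance), .id = "group"),
    factors = list(future_3ind = tidy(fo3), future_2ind = tidy(fo2),
                   negativity = tidy(neg)),
    tests = tests,
    correlations = correlations,
    mediation = tidy(med),
    config_seed = config$seed
  )
}

#' Write a pipeline report to JSON
#'
#' @param report A [run_pipeline()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pipeline_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
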