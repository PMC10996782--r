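#' Independent-samples t-test with pooled variance
#'
#' Two-group comparison with the classical pooled-variance t statistic
#' (df = n1 + n2 - 2) and a pooled-SD Cohen's d effect size (the
#' between-group contrast occasionally reported under the label "dz").
#' One-tailed tests honour the direction given in `alternative`, stated
#' for the first group level minus the second.
#'
#' @param data A data frame.
#' @param outcome Name of the numeric outcome column.
#' @param group Name of the two-level grouping column.
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `tail`,
#'   `estimate` (mean difference, first level minus second), `d`,
#'   `group1`, `group2`, `n1`, `n2`.
#' @export
group_ttest <- function(data, outcome, group,
                        alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  g <- factor(data[[group]])
  v <- data[[outcome]]
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- droplevels(g[keep])
  if (nlevels(g) != 2) abort("`group` must have exactly two levels.")
  n <- table(g)
  if (any(n < 2)) abort("Each group needs at least 2 observations.")
  tt <- stats::t.test(v ~ g, var.equal = TRUE, alternative = alternative)
  sp <- sqrt(unname(((n[1] - 1) * var(v[g == levels(g)[1]]) +
                       (n[2] - 1) * var(v[g == levels(g)[2]])) /
                      (sum(n) - 2)))
  diff <- unname(mean(v[g == levels(g)[1]]) - mean(v[g == levels(g)[2]]))
  tibble::tibble(
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    tail = if (alternative == "two.sided") "two" else "one",
    estimate = diff,
    d = diff / sp,
    group1 = levels(g)[1], group2 = levels(g)[2],
    n1 = unname(n[1]), n2 = unname(n[2])
  )
}

#' Pearson correlation with t-transform p value
#'
#' @param data A data frame.
#' @param x,y Names of the numeric columns.
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @return One-row tibble: `r`, `statistic` (t), `df` (n - 2), `p_value`,
#'   `tail`, `n`.
#' @export
pearson_correlation <- function(data, x, y,
                                alternative = c("two.sided", "less",
                                                "greater")) {
  alternative <- match.arg(alternative)
  keep <- complete.cases(data[c(x, y)])
  xv <- data[[x]][keep]; yv <- data[[y]][keep]
  if (length(xv) < 3) abort("Need at least 3 complete pairs.")
  if (sd(xv) == 0 || sd(yv) == 0) {
    abort("Correlation undefined: a variable has zero variance.")
  }
  ct <- stats::cor.test(xv, yv, method = "pearson",
                        alternative = alternative)
  tibble::tibble(
    r = unname(ct$estimate),
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = ct$p.value,
    tail = if (alternative == "two.sided") "two" else "one",
    n = length(xv)
  )
}

#' Covariate-adjusted group effect (ANCOVA F test)
#'
#' F test for the group term in a linear model containing the covariates,
#' using type-II sums of squares (the group term is tested against the
#' model containing all other terms).
#'
#' @param data A data frame.
#' @param outcome Name of the numeric outcome column.
#' @param group Name of the grouping column.
#' @param covariates Character vector of covariate column names.
#' @return One-row tibble: `statistic` (F), `df1`, `df2`, `p_value`.
#' @export
ancova_group_effect <- function(data, outcome, group,
                                covariates = character()) {
  keep <- complete.cases(data[c(outcome, group, covariates)])
  d <- data[keep, , drop = FALSE]
  d[[group]] <- factor(d[[group]])
  rhs <- paste(c(covariates, group), collapse = " + ")
  fml <- stats::as.formula(paste(outcome, "~", rhs))
  fit <- lm(fml, data = d)
  if (anyNA(coef(fit))) {
    abort(paste0("Rank-deficient model; collinear terms: ",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
                 "."))
  }
  dr <- drop1(fit, scope = stats::as.formula(paste("~", group)), test = "F")
  tibble::tibble(
    statistic = dr[group, "F value"],
    df1 = dr[group, "Df"],
    df2 = fit$df.residual,
    p_value = dr[group, "Pr(>F)"]
  )
}

coerce_binary <- function(v, name) {
  if (is.numeric(v)) {
    u <- sort(unique(v))
    if (!all(u %in% c(0, 1))) {
      if (length(u) != 2) abort(paste0("`", name, "` must be binary."))
      v <- as.numeric(v == u[2])
    }
    v
  } else {
    f <- factor(v)
    if (nlevels(f) != 2) abort(paste0("`", name, "` must be binary."))
    as.numeric(f == levels(f)[2])
  }
}

#' Bootstrap mediation with OLS paths
#'
#' Estimates, by ordinary least squares, how much of the association
#' between a binary predictor `x` and an outcome `y` flows through one or
#' more mediators: path `a_j` from `m_j ~ x (+ covariates)`, paths `b_j`
#' and the direct effect `c'` from `y ~ x + m_1..m_J (+ covariates)`, and
#' the total effect `c` from `y ~ x (+ covariates)`. The OLS decomposition
#' `c = c' + sum(a_j * b_j)` holds exactly. Effects are reported partially
#' standardized: `y` is z-scored on the analysis sample while the binary
#' `x` stays on its 0/1 scale (mediator scaling cancels in the `a * b`
#' product). Indirect-effect uncertainty comes from a case-resampling
#' percentile bootstrap (each resample re-estimates every path, including
#' the outcome standardization); with several mediators (parallel
#' mediation) one indirect effect and interval per mediator is reported
#' from the single joint outcome model.
#'
#' @param data A data frame; incomplete cases on the used columns are
#'   dropped.
#' @param x Name of the binary predictor column (group).
#' @param y Name of the numeric outcome column.
#' @param mediators Character vector of mediator column names.
#' @param covariates Character vector of covariate column names entered in
#'   every path model.
#' @param n_boot Number of bootstrap resamples (default 10,000).
#' @param seed Integer seed for the bootstrap.
#' @param level Confidence level of the percentile interval.
#' @return A `mediation` object; see [tidy.mediation()] and
#'   [glance.mediation()].
#' @export
mediate <- function(data, x, y, mediators, covariates = character(),
                    n_boot = 10000, seed = 1L, level = 0.95) {
  if (n_boot < 2) abort("`n_boot` must be at least 2.")
  cols <- c(x, y, mediators, covariates)
  d <- data[complete.cases(data[cols]), cols, drop = FALSE]
  n <- nrow(d)
  if (n < 10) abort("Too few complete cases for mediation.")
  xv <- coerce_binary(d[[x]], x)
  y_raw <- as.numeric(d[[y]])
  M <- as.matrix(d[mediators]); storage.mode(M) <- "double"
  if (any(apply(M, 2, sd) == 0)) abort("A mediator is constant.")
  C <- if (length(covariates)) {
    cm <- as.matrix(d[covariates]); storage.mode(cm) <- "double"; cm
  } else NULL

  paths_fun <- function(idx) {
    xb <- xv[idx]; yb <- y_raw[idx]
    yb <- (yb - mean(yb)) / sd(yb)
    Mb <- M[idx, , drop = FALSE]
    Cb <- if (is.null(C)) NULL else C[idx, , drop = FALSE]
    A_des <- cbind(1, xb, Cb)
    a <- qr.coef(qr(A_des), Mb)[2, ]
    Y_des <- cbind(1, xb, Mb, Cb)
    cf <- qr.coef(qr(Y_des), yb)
    b <- cf[3:(2 + ncol(M))]
    c_tot <- qr.coef(qr(A_des), yb)[2]
    list(a = a, b = b, c_prime = cf[2], c_total = c_tot)
  }

  est <- paths_fun(seq_len(n))
  # path-level SE/t/p from the full-sample OLS fits
  ds <- data.frame(.x = xv, .y = (y_raw - mean(y_raw)) / sd(y_raw), M)
  if (!is.null(C)) ds <- cbind(ds, as.data.frame(C))
  med_names <- colnames(M)
  cov_terms <- if (is.null(C)) character() else colnames(C)
  path_rows <- purrr::map_dfr(seq_along(med_names), function(j) {
    fm <- lm(stats::reformulate(c(".x", cov_terms), med_names[j]), data = ds)
    s <- unname(summary(fm)$coefficients[".x", ])
    tibble::tibble(path = "a", mediator = med_names[j], estimate = s[1],
                   se = s[2], statistic = s[3], p_value = s[4])
  })
  fy <- lm(stats::reformulate(c(".x", med_names, cov_terms), ".y"), data = ds)
  sy <- summary(fy)$coefficients
  path_rows <- dplyr::bind_rows(
    path_rows,
    tibble::tibble(path = "b", mediator = med_names,
                   estimate = unname(sy[med_names, 1]),
                   se = unname(sy[med_names, 2]),
                   statistic = unname(sy[med_names, 3]),
                   p_value = unname(sy[med_names, 4])),
    tibble::tibble(path = "c_prime", mediator = NA_character_,
                   estimate = unname(sy[".x", 1]), se = unname(sy[".x", 2]),
                   statistic = unname(sy[".x", 3]),
                   p_value = unname(sy[".x", 4])))
  fc <- lm(stats::reformulate(c(".x", cov_terms), ".y"), data = ds)
  sc <- summary(fc)$coefficients
  path_rows <- dplyr::bind_rows(
    path_rows,
    tibble::tibble(path = "c_total", mediator = NA_character_,
                   estimate = unname(sc[".x", 1]), se = unname(sc[".x", 2]),
                   statistic = unname(sc[".x", 3]),
                   p_value = unname(sc[".x", 4])))

  set.seed(seed)
  ab <- matrix(NA_real_, n_boot, ncol(M))
  for (bb in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    pb <- tryCatch(paths_fun(idx), error = function(e) NULL)
    if (!is.null(pb)) ab[bb, ] <- pb$a * pb$b
  }
  ab <- ab[complete.cases(ab), , drop = FALSE]
  alpha <- (1 - level) / 2
  indirect <- tibble::tibble(
    mediator = med_names,
    estimate = unname(est$a * est$b),
    se = apply(ab, 2, sd),
    ci_lo = apply(ab, 2, quantile, alpha),
    ci_hi = apply(ab, 2, quantile, 1 - alpha)
  )
  structure(
    list(paths = path_rows, indirect = indirect,
         c_total = unname(est$c_total), c_prime = unname(est$c_prime),
         n = n, n_boot = n_boot, seed = seed, level = level,
         x = x, y = y, mediators = mediators, covariates = covariates),
    class = "mediation")
}

#' @export
print.mediation <- function(x, ...) {
  cat("<mediation> ", x$x, " -> (", paste(x$mediators, collapse = ", "),
      ") -> ", x$y, ", n = ", x$n, "\n", sep = "")
  cat("  total effect c = ", round(x$c_total, 3),
      ", direct c' = ", round(x$c_prime, 3), "\n", sep = "")
  for (j in seq_len(nrow(x$indirect))) {
    cat("  indirect via ", x$indirect$mediator[j], ": ",
        round(x$indirect$estimate[j], 3), " [",
        round(x$indirect$ci_lo[j], 3), ", ",
        round(x$indirect$ci_hi[j], 3), "] (",
        100 * x$level, "% percentile, ", x$n_boot, " resamples)\n",
        sep = "")
  }
  invisible(x)
}

#' @describeIn mediate Indirect effects with bootstrap intervals, plus the
#'   path coefficients, as a tibble.
#' @param x A `mediation` object.
#' @param ... Unused.
#' @method tidy mediation
#' @export
tidy.mediation <- function(x, ...) {
  dplyr::bind_rows(
    x$paths,
    tibble::tibble(path = "indirect", mediator = x$indirect$mediator,
                   estimate = x$indirect$estimate, se = x$indirect$se,
                   statistic = NA_real_, p_value = NA_real_,
                   ci_lo = x$indirect$ci_lo, ci_hi = x$indirect$ci_hi))
}

#' @describeIn mediate One-row summary (total, direct and summed indirect
#'   effects, bootstrap settings).
#' @method glance mediation
#' @export
glance.mediation <- function(x, ...) {
  tibble::tibble(
    c_total = x$c_total, c_prime = x$c_prime,
    indirect_total = sum(x$indirect$estimate),
    n = x$n, n_boot = x$n_boot, level = x$level
  )
}
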