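#' @describeIn fit_discounting Plot per-participant posterior log(k) with
#'   95% intervals, random responders highlighted.
#' @param object A `dd_fit`.
#' @method autoplot dd_fit
#' @export
autoplot.dd_fit <- function(object, ...) {
  s <- object$summary
  s$participant <- factor(s$participant_id,
                          levels = s$participant_id[order(s$logk_mean)])
  ggplot2::ggplot(s, ggplot2::aes(x = .data$logk_mean,
                                  y = .data$participant,
                                  colour = .data$random_responder)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$logk_lo,
                                         xmax = .data$logk_hi),
                            height = 0) +
    ggplot2::geom_vline(xintercept = object$group$mu_mean,
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c("FALSE" = "grey30",
                                            "TRUE" = "firebrick")) +
    ggplot2::labs(x = "posterior log(k)", y = NULL,
                  colour = "random responder")
}

#' @describeIn fit_pca_factor Plot indicator loadings per component.
#' @param object A `pca_factor`.
#' @method autoplot pca_factor
#' @export
autoplot.pca_factor <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$indicator, y = .data$loading)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~.data$component) +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(y = "loading (indicator-component correlation)", x = NULL)
}

#' Plot hyperbolic discount curves
#'
#' Subjective value of a unit reward over delay for one or more discount
#' rates, e.g. fitted group means.
#'
#' @param log_k Numeric vector of log discount rates (per day).
#' @param t_max Longest delay to draw (days).
#' @return A ggplot object.
#' @export
plot_discount_curves <- function(log_k, t_max = 180) {
  d <- tidyr::expand_grid(log_k = log_k, t = seq(0, t_max, length.out = 200))
  d$sv <- hyperbolic_sv(1, exp(d$log_k), d$t)
  d$curve <- factor(round(d$log_k, 2))
  ggplot2::ggplot(d, ggplot2::aes(.data$t, .data$sv, colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "delay (days)", y = "subjective value / amount",
                  colour = "log(k)")
}
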