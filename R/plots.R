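# ggplot2 displays for the main result types.

#' Per-site temporal beta diversity plots
#'
#' Dot-and-error-bar displays of the per-site results: observed mean
#' consecutive-year dissimilarity (+/- 1 SD over the pair values) and
#' the null departure beta_dep with a dashed reference line at the
#' stability threshold (sites below it are more stable than expected by
#' chance).
#'
#' @param beta per-site results tibble from [temporal_beta_analysis()]
#'   (element `beta`) or [null_beta()].
#' @param threshold stability reference line for the departure panel.
#' @return a ggplot object.
#' @export
plot_beta_observed <- function(beta) {
  stopifnot(all(c("site", "beta_obs") %in% names(beta)))
  p <- ggplot2::ggplot(beta, ggplot2::aes(x = stats::reorder(.data$site, .data$beta_obs),
                                          y = .data$beta_obs))
  if ("beta_obs_sd" %in% names(beta)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$beta_obs - .data$beta_obs_sd,
                   ymax = .data$beta_obs + .data$beta_obs_sd),
      width = 0.25, colour = "grey50")
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = NULL, y = "Observed dissimilarity (Bray-Curtis)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @rdname plot_beta_observed
#' @export
plot_beta_departure <- function(beta, threshold = -2) {
  stopifnot(all(c("site", "beta_dep") %in% names(beta)))
  ggplot2::ggplot(beta, ggplot2::aes(x = stats::reorder(.data$site, .data$beta_dep),
                                     y = .data$beta_dep)) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = NULL, y = "Departure from null expectation (SES)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Importance plot for an all-subsets model set
#'
#' Bar chart of per-variable summed Akaike weights with the importance
#' threshold as a dashed line.
#'
#' @param object a `beta_model_set` from [fit_all_subsets()].
#' @param threshold importance threshold drawn as reference (default
#'   0.80).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot beta_model_set
#' @export
autoplot.beta_model_set <- function(object, threshold = 0.80, ...) {
  imp <- variable_importance(object, threshold = threshold)
  ggplot2::ggplot(imp, ggplot2::aes(x = stats::reorder(.data$variable, .data$importance),
                                    y = .data$importance)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "Summed Akaike weight (importance)",
                  title = sprintf("Response: %s", attr(object, "response"))) +
    ggplot2::theme_minimal()
}

#' Lag-profile plot
#'
#' Mean Bray-Curtis dissimilarity against year separation with the
#' smoothed trend; a flat profile means little temporal autocorrelation
#' beyond the one-year step.
#'
#' @param object a `lag_profile` from [lag_profile()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot lag_profile
#' @export
autoplot.lag_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_dissimilarity,
                                     size = .data$n_pairs), alpha = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), colour = "steelblue") +
    ggplot2::scale_size_continuous(range = c(1, 3)) +
    ggplot2::labs(x = "Year separation (lag)",
                  y = "Mean Bray-Curtis dissimilarity",
                  size = "pairs",
                  subtitle = sprintf("lag-1 effect: %.3f", lag1_effect(object))) +
    ggplot2::theme_minimal()
}
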