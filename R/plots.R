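#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_abline geom_hline
#'   geom_vline geom_col labs scale_x_log10 coord_cartesian theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a graphical-method fit
#'
#' Per-level proportions correct (point size by per-level n) against
#' concentration on a log10 axis, with the fitted performance line, the
#' criterion line, and the threshold (plus confidence bounds) where
#' defined.
#'
#' @param object A `graphical_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.graphical_fit <- function(object, ...) {
  p <- ggplot(object$level_proportions,
              aes(x = .data$concentration, y = .data$p_correct)) +
    geom_point(aes(size = .data$n), alpha = 0.8) +
    geom_abline(intercept = object$intercept, slope = object$slope) +
    geom_hline(yintercept = object$criterion, linetype = "dashed") +
    scale_x_log10() +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "concentration (ng/L)", y = "proportion correct",
         size = "n", title = "Graphical group threshold") +
    theme_minimal()
  if (!is.na(object$threshold)) {
    p <- p + geom_vline(xintercept = object$threshold, colour = "firebrick")
    if (!is.na(object$ci_lower)) {
      p <- p + geom_vline(xintercept = c(object$ci_lower, object$ci_upper),
                          colour = "firebrick", linetype = "dotted")
    }
  }
  p
}

#' Plot a rejection-threshold fit
#'
#' Per-level proportion choosing the spiked sample against concentration
#' on a log10 axis, with the fitted line and the rejection / preference
#' criteria; defined thresholds are marked.
#'
#' @param object A `rejection_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rejection_fit <- function(object, ...) {
  p <- ggplot(object$level_proportions,
              aes(x = .data$concentration, y = .data$p_spike)) +
    geom_point(aes(size = .data$n), alpha = 0.8) +
    geom_abline(intercept = object$intercept, slope = object$slope) +
    geom_hline(yintercept = c(object$rejection_criterion,
                              object$preference_criterion),
               linetype = "dashed") +
    scale_x_log10() +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "concentration (ng/L)", y = "proportion choosing spike",
         size = "n",
         title = paste0("Rejection threshold (", object$segment, ")")) +
    theme_minimal()
  for (thr in c(object$rejection_threshold, object$preference_threshold)) {
    if (!is.na(thr)) p <- p + geom_vline(xintercept = thr, colour = "firebrick")
  }
  p
}

#' Histogram of individual BETs
#'
#' Bar chart of BET counts over the attainable ladder midpoints (see
#' [bet_histogram()]), with the imputed non-responder bin shown in a
#' different fill — displayed but never part of summary statistics.
#'
#' @param bets BET tibble from [estimate_bets()].
#' @param series The [concentration_series()].
#' @return A ggplot object.
#' @export
plot_bet_histogram <- function(bets, series) {
  bins <- bet_histogram(bets, series)
  ggplot(bins, aes(x = .data$bet_value, y = .data$count, fill = .data$kind)) +
    geom_col() +
    scale_x_log10() +
    labs(x = "best estimate threshold (ng/L)", y = "panelists",
         fill = NULL, title = "Individual BETs") +
    theme_minimal()
}
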