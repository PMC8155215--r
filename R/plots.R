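#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_hline geom_vline
#'   geom_col geom_errorbar labs scale_color_manual theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Delta-PSI versus direction probability
#'
#' Scatter of per-event |delta-PSI| significance coordinates: delta-PSI (in
#' percentage points) against the direction-symmetric probability of
#' differential splicing, with the calling thresholds as dashed lines and
#' called events highlighted.
#'
#' @param object A `diffsplice_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.diffsplice_fit <- function(object, ...) {
  df <- object$results
  th <- object$thresholds
  ggplot(df, aes(x = 100 * .data$delta_psi, y = .data$prob_differential,
                 color = .data$significant)) +
    geom_point(alpha = 0.6, size = 1) +
    geom_hline(yintercept = th$prob_threshold, linetype = "dashed") +
    geom_vline(xintercept = c(-100, 100) * th$dpsi_threshold,
               linetype = "dashed") +
    scale_color_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                       name = "called") +
    labs(x = expression(Delta * "PSI (%)"),
         y = "P(differential splicing)") +
    theme_minimal()
}

#' Direction-of-change proportions with confidence intervals
#'
#' Bar plot of the proportion of called events with positive delta-PSI per
#' event type, with the Wilson confidence interval as error bars and the
#' null proportion 0.5 as a dashed line.
#'
#' @param object A `direction_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.direction_summary <- function(object, ...) {
  df <- object[!is.na(object$proportion), , drop = FALSE]
  ggplot(df, aes(x = .data$event_type, y = .data$proportion)) +
    geom_col(fill = "grey70", width = 0.6) +
    geom_errorbar(aes(ymin = .data$ci_low, ymax = .data$ci_high),
                  width = 0.15) +
    geom_hline(yintercept = 0.5, linetype = "dashed") +
    labs(x = "event type",
         y = expression("proportion of positive " * Delta * "PSI")) +
    theme_minimal()
}

#' @rdname autoplot.diffsplice_fit
#' @param fit A `diffsplice_fit`.
#' @export
plot_dpsi_scatter <- function(fit, ...) autoplot(fit, ...)

#' @rdname autoplot.direction_summary
#' @param summaries A `direction_summary`.
#' @export
plot_direction_props <- function(summaries, ...) autoplot(summaries, ...)
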