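# ggplot2 displays for the main result types

#' Plot a decoded track
#'
#' Track map in planar kilometres with steps coloured by decoded behavioural
#' state, the standard display for inspecting travelling/foraging structure
#' (outbound transit, area-restricted search, inbound transit).
#'
#' @param object a [fit_hmm()] object.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.dcrw_hmm <- function(object, ...) {
  st <- object$states
  ggplot2::ggplot(st, ggplot2::aes(.data$x_km, .data$y_km)) +
    ggplot2::geom_path(ggplot2::aes(group = .data$segment),
                       colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$state), size = 1.4) +
    ggplot2::scale_colour_manual(values = c(travelling = "#3B7EA1",
                                            foraging = "#2E7D32")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)", colour = "state") +
    ggplot2::theme_minimal()
}

#' Odds-ratio forest plot for an association model
#'
#' @param object a [fit_pql_glmm()] object.
#' @param ... unused.
#' @return a ggplot of odds ratios with Wald 95% intervals (log scale),
#'   intercept omitted.
#' @exportS3Method ggplot2::autoplot
autoplot.pql_glmm <- function(object, ...) {
  or <- odds_ratio_table(object)
  or <- or[or$term != "(Intercept)", ]
  ggplot2::ggplot(or, ggplot2::aes(.data$or, stats::reorder(.data$term, .data$or))) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi),
                            height = 0.2, colour = "grey40") +
    ggplot2::geom_point(colour = "#3B7EA1", size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a dive profile with phases
#'
#' @param dive one row of a phase-annotated dive tibble ([split_phases()]).
#' @return a ggplot of the depth trace coloured by phase (depth increasing
#'   downwards).
#' @export
plot_dive_profile <- function(dive) {
  smp <- dive$samples[[1]]
  ggplot2::ggplot(smp, ggplot2::aes(.data$timestamp, .data$depth_m)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$phase), size = 1.2) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "depth (m)", colour = "phase") +
    ggplot2::theme_minimal()
}
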