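#' Plot per-mouse survival curves with optional decay fits
#'
#' Dashed lines are individual mice; when `fit = TRUE`, a solid line per
#' genotype shows the pooled single-phase decay fit.
#'
#' @param object A `spine_survival` tibble from [survival_curves()].
#' @param fit Overlay pooled per-genotype decay fits? Default `TRUE`.
#' @param constrain_s0 Constraint mode for the overlay fits.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spine_survival
#' @export
autoplot.spine_survival <- function(object, fit = TRUE, constrain_s0 = FALSE,
                                    ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(
    x = .data$time, y = .data$survival,
    colour = .data$genotype, group = .data$mouse_id
  )) +
    ggplot2::geom_line(linetype = "dashed", alpha = 0.6) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "Days from first imaging", y = "Survival fraction S(t)",
                  colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_classic()
  if (fit) {
    grid <- do.call(rbind, lapply(split(object, object$genotype), function(d) {
      f <- fit_decay(d, constrain_s0 = constrain_s0)
      tt <- seq(0, max(d$time), length.out = 200)
      data.frame(genotype = d$genotype[1], time = tt,
                 survival = f$sp + f$si * exp(-tt / f$tau))
    }))
    p <- p + ggplot2::geom_line(
      data = grid,
      ggplot2::aes(x = .data$time, y = .data$survival,
                   colour = .data$genotype, group = .data$genotype),
      linewidth = 1
    )
  }
  p
}

#' Plot a Sholl intersection profile
#'
#' @param object A `sholl_profile` tibble from [sholl_intersections()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sholl_profile
#' @export
autoplot.sholl_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$radius,
                                       y = .data$intersections)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Distance from soma (µm)", y = "Intersections") +
    ggplot2::theme_classic()
}

#' Per-mouse turnover ratio dot plot
#'
#' Animal-level turnover ratios by genotype, the standard presentation for
#' two-session turnover comparisons.
#'
#' @param turnover Output of [count_turnover()].
#' @return A ggplot object.
#' @export
plot_turnover <- function(turnover) {
  ggplot2::ggplot(turnover, ggplot2::aes(x = .data$genotype, y = .data$ratio,
                                         colour = .data$genotype)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, size = 2) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3,
                          colour = "black", linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "Turnover ratio") +
    ggplot2::theme_classic() +
    ggplot2::theme(legend.position = "none")
}
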