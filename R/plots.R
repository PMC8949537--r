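#' Forest plot of an MR result
#'
#' Per-variant Wald ratios with 95% intervals and a summary row per
#' estimable method, drawn as a standard forest plot.
#'
#' @param object An `mr_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mr_result <- function(object, ...) {
  d <- render_forest_data(object)
  d$label <- factor(d$label, levels = rev(d$label))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$label,
                                  colour = .data$type)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_lower,
                                          xmax = .data$ci_upper)) +
    ggplot2::scale_colour_manual(values = c(variant = "grey30",
                                            summary = "firebrick")) +
    ggplot2::labs(x = "Causal effect per unit exposure", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of variant effects with fitted MR slopes
#'
#' Exposure betas against outcome betas with one fitted line per
#' estimable method (IVW through the origin, Egger with intercept).
#'
#' @param result An `mr_result`.
#' @return A ggplot object.
#' @export
plot_mr_scatter <- function(result) {
  h <- result$harmonized
  z <- qnorm(0.975)
  d <- tibble::tibble(bx = abs(h$beta_exposure),
                      by = h$beta_outcome * sign(h$beta_exposure),
                      sx = h$se_exposure, sy = h$se_outcome)
  m <- dplyr::filter(result$methods, .data$estimable,
                     .data$method %in% c("ivw", "egger", "weighted_median", "raps"))
  egger_int <- result$methods$estimate[result$methods$method == "egger_intercept"]
  lines <- tibble::tibble(
    method = m$method, slope = m$estimate,
    intercept = ifelse(m$method == "egger",
                       ifelse(length(egger_int), egger_int[1], 0), 0)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bx, y = .data$by)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$by - z * .data$sy,
                                        ymax = .data$by + z * .data$sy),
                           width = 0, colour = "grey70") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$bx - z * .data$sx,
                                         xmax = .data$bx + z * .data$sx),
                            height = 0, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(data = lines,
                         ggplot2::aes(slope = .data$slope,
                                      intercept = .data$intercept,
                                      colour = .data$method)) +
    ggplot2::labs(x = "Variant effect on exposure",
                  y = "Variant effect on outcome", colour = "Method") +
    ggplot2::theme_minimal()
}

#' Plot mediation effect decomposition with bootstrap intervals
#'
#' @param object A `mediation_boot`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mediation_boot <- function(object, ...) {
  d <- object$effects
  d$effect <- factor(d$effect, levels = rev(d$effect))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$effect)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_lower,
                                          xmax = .data$ci_upper)) +
    ggplot2::labs(x = "Effect estimate (bootstrap 95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Scree plot of nutrient-pattern components
#'
#' @param object A `nutrient_pca`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nutrient_pca <- function(object, ...) {
  d <- tibble::tibble(component = seq_along(object$variance_explained),
                      variance_explained = object$variance_explained)
  ggplot2::ggplot(d, ggplot2::aes(.data$component, .data$variance_explained)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Component", y = "Fraction of variance explained") +
    ggplot2::theme_minimal()
}
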