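# ggplot2 views of the result objects. Layout and styling are deliberately
# simple; GraphML export is the route to full-featured network drawing.

#' Plot an institution network
#'
#' Nodes on a circle, coloured by institution level; edge opacity and
#' width follow the log-transformed weight, matching the usual rendering
#' of shared-patient networks. Out-of-county institutions are drawn
#' hollow.
#'
#' @param object an `institution_network`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot institution_network
#' @export
autoplot.institution_network <- function(object, ...) {
  nodes <- object$nodes
  n <- nrow(nodes)
  if (n == 0) {
    return(ggplot() + labs(title = "empty network") + theme_void())
  }
  theta <- 2 * pi * (seq_len(n) - 1) / n
  pos <- tibble(node = nodes$node, x = cos(theta), y = sin(theta),
                level = nodes$level, in_county = nodes$in_county)
  edges <- object$edges |>
    dplyr::left_join(pos[c("node", "x", "y")], by = c(from = "node")) |>
    dplyr::left_join(pos[c("node", "x", "y")], by = c(to = "node"),
                     suffix = c("", "end"))
  p <- ggplot()
  if (nrow(edges) > 0) {
    p <- p + geom_segment(
      data = edges,
      aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
          linewidth = .data$display_weight, alpha = .data$display_weight),
      colour = "grey40")
  }
  p +
    geom_point(data = pos,
               aes(x = .data$x, y = .data$y, colour = .data$level,
                   shape = .data$in_county), size = 3) +
    scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                       name = "in county") +
    scale_linewidth(range = c(0.2, 1.5), guide = "none") +
    scale_alpha(range = c(0.3, 0.9), guide = "none") +
    coord_equal() +
    theme_void() +
    labs(title = sprintf("%s-dose user network (%s mode)",
                         object$group, object$mode),
         colour = "level")
}

#' Forest plot of adjusted odds ratios
#'
#' @param object a `zol_logistic` fit.
#' @param ... unused.
#' @return a ggplot object (log-scaled aOR axis with Wald 95% CIs).
#' @method autoplot zol_logistic
#' @export
autoplot.zol_logistic <- function(object, ...) {
  td <- tidy(object)
  ggplot(td, aes(x = .data$aOR, y = stats::reorder(.data$term, .data$aOR))) +
    geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    geom_errorbarh(aes(xmin = .data$conf.low, xmax = .data$conf.high),
                   height = 0.2) +
    geom_point() +
    scale_x_log10() +
    labs(x = "adjusted odds ratio (95% CI)", y = NULL,
         title = "Risk factors for high-dose membership") +
    theme_minimal()
}

#' Attrition funnel plot
#'
#' @param object a `cohort_trace` from [select_cohort()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot cohort_trace
#' @export
autoplot.cohort_trace <- function(object, ...) {
  tr <- object$trace |>
    dplyr::mutate(filter = factor(.data$filter, levels = rev(.data$filter)))
  ggplot(tr, aes(x = .data$n_remaining, y = .data$filter)) +
    geom_col(fill = "steelblue") +
    geom_text(aes(label = sprintf("-%d", .data$n_removed)),
              hjust = -0.1, size = 3) +
    labs(x = "patients remaining", y = NULL,
         title = "Cohort selection attrition") +
    theme_minimal()
}

#' @export
plot.institution_network <- function(x, ...) print(autoplot.institution_network(x, ...))

#' @export
plot.zol_logistic <- function(x, ...) print(autoplot.zol_logistic(x, ...))

#' @export
plot.cohort_trace <- function(x, ...) print(autoplot.cohort_trace(x, ...))
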