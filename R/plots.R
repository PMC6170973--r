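#' Plot the posterior over the number of clusters
#'
#' @param object a `bmm_chain`.
#' @param ... unused.
#' @return a ggplot: posterior mass per K, modal K highlighted.
#' @method autoplot bmm_chain
#' @export
autoplot.bmm_chain <- function(object, ...) {
  pk <- posterior_over_K(object)
  pk$modal <- pk$K == modal_K(object)
  ggplot2::ggplot(pk, ggplot2::aes(
    x = factor(.data$K), y = .data$prob, fill = .data$modal
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "#2166ac")) +
    ggplot2::labs(
      x = "number of clusters K", y = "posterior probability",
      title = "Posterior over the number of clusters"
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of posterior assignment probabilities
#'
#' @param object an `assignment_matrix`.
#' @param ... unused.
#' @return a ggplot tile map, components ordered by modal cluster.
#' @method autoplot assignment_matrix
#' @export
autoplot.assignment_matrix <- function(object, ...) {
  long <- tidy(object)
  ord <- object$component_id[order(object$modal_cluster, -object$modal_prob)]
  long$component_id <- factor(long$component_id, levels = ord)
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$cluster), y = .data$component_id,
    fill = .data$probability
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac", limits = c(0, 1)) +
    ggplot2::labs(
      x = "cluster", y = NULL, fill = "P(assign)",
      title = "Posterior assignment probabilities"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 5))
}

#' Alluvial-style view of cluster flows across ages
#'
#' Nodes are clusters per age (the inactive pool at the bottom), segment
#' widths proportional to the number of shared components. A data-level
#' rendering of the flow architecture, not a publication figure.
#'
#' @param object a `flow_graph`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot flow_graph
#' @export
autoplot.flow_graph <- function(object, ...) {
  edges <- tibble::as_tibble(object)
  ages <- attr(object, "ages")
  edges$x_from <- match(edges$age_from, ages)
  edges$x_to <- match(edges$age_to, ages)
  node_pos <- function(node) {
    ifelse(node == "inactive", 0, suppressWarnings(as.numeric(node)))
  }
  edges$y_from <- node_pos(edges$from)
  edges$y_to <- node_pos(edges$to)
  ggplot2::ggplot(edges) +
    ggplot2::geom_segment(
      ggplot2::aes(
        x = .data$x_from, xend = .data$x_to,
        y = .data$y_from, yend = .data$y_to,
        linewidth = .data$weight,
        colour = .data$from
      ),
      alpha = 0.6, show.legend = FALSE
    ) +
    ggplot2::geom_point(
      data = dplyr::bind_rows(
        tibble::tibble(x = edges$x_from, y = edges$y_from),
        tibble::tibble(x = edges$x_to, y = edges$y_to)
      ),
      ggplot2::aes(x = .data$x, y = .data$y), size = 3
    ) +
    ggplot2::scale_x_continuous(breaks = seq_along(ages), labels = ages) +
    ggplot2::labs(
      x = "age (years)", y = "cluster (0 = inactive)",
      title = "Cluster flows across ages"
    ) +
    ggplot2::theme_minimal()
}

#' Forest plot of cluster-outcome odds ratios
#'
#' @param object an `association_result` tibble.
#' @param ... unused.
#' @return a ggplot on a log OR axis, faceted by outcome and model.
#' @method autoplot association_result
#' @export
autoplot.association_result <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  dat <- dat[is.finite(dat$or), ]
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$or, y = .data$exposure
  )) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.2
    ) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_grid(model ~ outcome) +
    ggplot2::labs(
      x = "odds ratio (95% CI)", y = NULL,
      title = "Cluster sensitization and allergic outcomes"
    ) +
    ggplot2::theme_minimal()
}
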