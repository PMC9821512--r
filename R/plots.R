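## ggplot2 views of the result objects.

#' Plot the running-sum profile of one gene set
#'
#' @param ranked Ranked list tibble.
#' @param members Member IDs of the set.
#' @param weight_exponent Passed to [enrichment_score()].
#' @return A ggplot: running sum along the ranked list with hit positions
#'   marked in the rug.
#' @export
plot_running_sum <- function(ranked, members, weight_exponent = 1) {
  es <- enrichment_score(ranked, members, weight_exponent)
  df <- tibble(position = seq_along(es$running_sum), running_sum = es$running_sum,
               hit = ranked$gene_id %in% members)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$running_sum)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_rug(data = df[df$hit, ], sides = "b", alpha = 0.5) +
    ggplot2::labs(x = "Rank in fold-change list", y = "Running enrichment sum",
                  subtitle = sprintf("ES = %.3f", es$es)) +
    ggplot2::theme_minimal()
}

#' Volcano-style overview of a gene-set enrichment result
#'
#' @param object A `gsea_result`.
#' @param q_cutoff Dashed significance line.
#' @param ... Unused.
#' @return A ggplot: ES vs -log10 q, colored by direction.
#' @export
autoplot.gsea_result <- function(object, q_cutoff = 0.1, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$es, y = -log10(.data$q_value),
                                   color = .data$direction)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(q_cutoff), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::scale_color_manual(values = c(up = "#d7301f", down = "#0570b0")) +
    ggplot2::labs(x = "Enrichment score", y = expression(-log[10]~q),
                  color = "Direction") +
    ggplot2::theme_minimal()
}

#' Plot an enrichment map
#'
#' Enriched sets are points (red up, blue down, sized by set size) on a
#' deterministic circular layout; overlap edges are drawn with width
#' proportional to the shared-member count.
#'
#' @param object An `enrichment_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.enrichment_map <- function(object, ...) {
  nodes <- object$nodes
  if (nrow(nodes) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "No enriched sets"))
  }
  theta <- 2 * pi * (seq_len(nrow(nodes)) - 1) / nrow(nodes)
  nodes <- mutate(nodes, x = cos(theta), y = sin(theta))
  p <- ggplot2::ggplot()
  if (nrow(object$edges) > 0) {
    e <- object$edges
    e <- left_join(e, nodes[, c("set_id", "x", "y")], by = c(set_a = "set_id"))
    e <- left_join(e, nodes[, c("set_id", "x", "y")], by = c(set_b = "set_id"),
                   suffix = c("", "_b"))
    p <- p + ggplot2::geom_segment(
      data = e,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_b, yend = .data$y_b,
                   linewidth = .data$shared_count),
      color = "#31a354", alpha = 0.6) +
      ggplot2::scale_linewidth(range = c(0.3, 2.5))
  }
  p +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     color = .data$direction, size = .data$size)) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = 1.15 * .data$x, y = 1.15 * .data$y,
                                    label = .data$set_id), size = 3) +
    ggplot2::scale_color_manual(values = c(up = "#d7301f", down = "#0570b0")) +
    ggplot2::coord_equal(xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4)) +
    ggplot2::theme_void() +
    ggplot2::labs(color = "Direction", size = "Set size",
                  linewidth = "Shared proteins")
}

#' Degree vs betweenness view of candidate hubs
#'
#' Candidates are labeled by ID and colored by how many disorder subnetworks
#' each appears in.
#'
#' @param object A `hub_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hub_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$combined_degree,
                                   y = .data$combined_betweenness,
                                   color = factor(.data$n_disorders_present))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$id), vjust = -0.8, size = 3,
                       show.legend = FALSE) +
    ggplot2::labs(x = "Degree in combined network",
                  y = "Betweenness (normalized)",
                  color = "Disorders present") +
    ggplot2::theme_minimal()
}

#' Null-distribution view of a random-seed specificity test
#'
#' @param object A `hub_null`.
#' @param ... Unused.
#' @return A ggplot: histogram of the null statistic with the observed value
#'   marked.
#' @export
autoplot.hub_null <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null_stat)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed, color = "#d7301f") +
    ggplot2::labs(x = sprintf("Null statistic (%s)", object$statistic),
                  y = "Iterations",
                  subtitle = sprintf("empirical p = %.4g", object$empirical_p)) +
    ggplot2::theme_minimal()
}
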