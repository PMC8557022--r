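# ggplot2 views of the main result types.

#' Volcano plot of per-CpG differential methylation
#'
#' @param dms Output of [fit_dms()].
#' @param p_cut Raw-p highlight threshold.
#' @param delta_cut |delta-beta| highlight threshold.
#' @return A ggplot.
#' @export
plot_dms_volcano <- function(dms, p_cut = 5e-4, delta_cut = 0.1) {
  d <- mutate(dms, candidate = .data$p < p_cut &
                abs(.data$delta_beta) >= delta_cut)
  ggplot2::ggplot(d, ggplot2::aes(.data$delta_beta, -log10(.data$p),
                                  colour = .data$candidate)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = expression(Delta * beta ~ "(case - control)"),
                  y = expression(-log[10] ~ p)) +
    ggplot2::theme_minimal()
}

#' Manhattan-style view of smoothed DMR evidence
#'
#' @param dms Output of [fit_dms()].
#' @param dmrs Output of [call_dmrs()]; called regions are shaded.
#' @return A ggplot.
#' @export
plot_dmr_tracks <- function(dms, dmrs = NULL) {
  p <- ggplot2::ggplot(dms, ggplot2::aes(.data$pos, .data$t^2)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = expression(t^2)) +
    ggplot2::theme_minimal()
  if (!is.null(dmrs) && nrow(dmrs)) {
    p <- p + ggplot2::geom_rect(
      data = dmrs,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf, fill = .data$direction),
      alpha = 0.25, inherit.aes = FALSE) +
      ggplot2::scale_fill_manual(values = c(hyper = "firebrick",
                                            hypo = "steelblue"))
  }
  p
}

#' Age-acceleration comparison plot
#'
#' DNAm age against chronological age with the identity line, coloured by
#' group.
#'
#' @param aa Output of [age_acceleration()].
#' @param sheet Sample sheet with `group`.
#' @return A ggplot.
#' @export
plot_age_acceleration <- function(aa, sheet) {
  d <- inner_join(aa, sheet[, c("sample_id", "group")], by = "sample_id")
  ggplot2::ggplot(d, ggplot2::aes(.data$chrono_age, .data$dnam_age,
                                  colour = .data$group)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "chronological age (years)",
                  y = "DNAm age (years)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.epi_modules <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(stats::reorder(.data$seed_gene,
                                                 .data$score),
                                  .data$score,
                                  fill = .data$emp_p < 0.05)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "firebrick"),
                               name = "emp_p < 0.05") +
    ggplot2::labs(x = "module seed gene", y = "module score") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.integrated_network <- function(object, ...) {
  g <- object$graph
  set.seed(1)
  xy <- igraph::layout_with_fr(g)
  nodes <- object$nodes |>
    mutate(x = xy[, 1], y = xy[, 2])
  edges <- object$edges |>
    left_join(nodes[, c("node", "x", "y")], by = c(gene_a = "node")) |>
    rename(x0 = "x", y0 = "y") |>
    left_join(nodes[, c("node", "x", "y")], by = c(gene_b = "node"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x, yend = .data$y),
                          colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(.data$x, .data$y,
                                     colour = .data$label), size = 2.5) +
    ggplot2::labs(colour = "sources") +
    ggplot2::theme_void()
}
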