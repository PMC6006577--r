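#' Gene map of predicted MAR/SAR sites
#'
#' Draws the exon/intron track with named annotations (BCRs, SAR1) and one
#' marker per candidate site, in the style of a gene-scale distribution map.
#'
#' @param sites Clustered site tibble from [scan_mar_sar()].
#' @param model A gene model.
#' @return A ggplot object.
#' @export
plot_mar_sar_map <- function(sites, model) {
  exons <- model[model$type == "exon", ]
  ann <- model[model$type == "annotation", ]
  spans <- dplyr::distinct(sites, .data$site_id, .data$span_start,
                           .data$span_end)
  spans$mid <- (spans$span_start + spans$span_end) / 2
  ggplot2::ggplot() +
    ggplot2::geom_segment(ggplot2::aes(x = 1, xend = attr(model, "gene_length"),
                                       y = 0, yend = 0), linewidth = 0.3) +
    ggplot2::geom_rect(data = exons,
                       ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = -0.12, ymax = 0.12),
                       fill = "grey30") +
    ggplot2::geom_rect(data = ann,
                       ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = -0.3, ymax = -0.18,
                                    fill = .data$label), alpha = 0.7) +
    ggplot2::geom_point(data = spans,
                        ggplot2::aes(x = .data$mid, y = 0.3),
                        shape = 25, fill = "goldenrod", size = 3) +
    ggplot2::geom_text(data = spans,
                       ggplot2::aes(x = .data$mid, y = 0.42,
                                    label = .data$site_id), size = 3) +
    ggplot2::scale_y_continuous(limits = c(-0.5, 0.6), breaks = NULL) +
    ggplot2::labs(x = "gene-local position (bp)", y = NULL, fill = NULL,
                  title = "Predicted MAR/SAR sites") +
    ggplot2::theme_minimal()
}

#' Map of breakpoint calls within the region of study
#'
#' Vertical ticks at each called break, over the region of study and any
#' annotations intersecting it.
#'
#' @param calls Tibble with `position` (e.g. from [map_reads()]).
#' @param model A gene model.
#' @param config Optional [assay_config()]; restricts the x range to the
#'   region of study.
#' @return A ggplot object.
#' @export
plot_breakpoint_map <- function(calls, model, config = NULL) {
  xlim <- if (is.null(config)) range(calls$position) + c(-500, 500) else
    c(config$region_start, config$region_end)
  ann <- model[model$type == "annotation" & model$start <= xlim[2] &
                 model$end >= xlim[1], ]
  ggplot2::ggplot() +
    ggplot2::geom_rect(data = ann,
                       ggplot2::aes(xmin = pmax(.data$start, xlim[1]),
                                    xmax = pmin(.data$end, xlim[2]),
                                    ymin = -0.25, ymax = -0.05,
                                    fill = .data$label), alpha = 0.7) +
    ggplot2::geom_segment(data = calls,
                          ggplot2::aes(x = .data$position,
                                       xend = .data$position,
                                       y = 0, yend = 1),
                          colour = "firebrick", linewidth = 0.4) +
    ggplot2::coord_cartesian(xlim = xlim) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "gene-local position (bp)", y = NULL, fill = NULL,
                  title = "IPCR breakpoint calls") +
    ggplot2::theme_minimal()
}

#' Bar chart of cleavage frequencies
#'
#' Mean number of cleaved-gene bands per replicate, with SD error bars
#' across experiments.
#'
#' @param summary Output of [cleavage_frequency()].
#' @return A ggplot object.
#' @export
plot_cleavage_frequency <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$sample, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.15) +
    ggplot2::labs(x = NULL, y = "cleaved fragments per replicate",
                  title = "Gene cleavage frequency") +
    ggplot2::theme_minimal()
}

#' @rdname plot_cleavage_frequency
#' @param object A `cleavage_test`.
#' @param ... Unused.
#' @export
autoplot.cleavage_test <- function(object, ...) {
  df <- tibble(group = c("a", "b"), mean = c(object$mean_a, object$mean_b))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.5) +
    ggplot2::labs(x = NULL, y = "group mean",
                  subtitle = sprintf("two-sided p = %.4g",
                                     object$htest$p.value)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
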