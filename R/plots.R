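# ggplot2 views of the main result types

#' Plot loop category proportions per mark
#'
#' Stacked proportions of promoter-promoter (PP), promoter-intergenic (PI),
#' intergenic-intergenic (II) and other loops, per mark.
#'
#' @param loop_categories Output of [categorize_loops()].
#' @return A ggplot object.
#' @export
plot_loop_categories <- function(loop_categories) {
  ggplot2::ggplot(loop_categories,
                  ggplot2::aes(x = .data$mark, fill = .data$category)) +
    ggplot2::geom_bar(position = "fill") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "loops", fill = "category") +
    ggplot2::theme_minimal()
}

#' Plot loop span distributions
#'
#' @param loop_categories Output of [categorize_loops()] (intrachromosomal
#'   loops only are shown).
#' @return A ggplot object with log10 span densities per mark.
#' @export
plot_span_distribution <- function(loop_categories) {
  df <- loop_categories[!is.na(loop_categories$span_bp) &
                          loop_categories$span_bp > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$span_bp, colour = .data$mark)) +
    ggplot2::geom_density() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "loop span (bp)", y = "density") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.chiahub_coexpr
#' @export
plot_coexpr_null <- function(object, ...) autoplot.chiahub_coexpr(object, ...)

#' Plot a co-expression null distribution
#'
#' Histogram of the null mean correlations with the observed mean marked.
#'
#' @param object A `chiahub_coexpr`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot chiahub_coexpr
#' @export
autoplot.chiahub_coexpr <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$null_mean_pcc)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed_mean_pcc,
                        colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "null mean PCC",
                  subtitle = sprintf("observed %.3f, empirical p = %.3g",
                                     object$observed_mean_pcc,
                                     object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot a contact matrix
#'
#' @param object A `chiahub_contact_matrix`.
#' @param ... Unused.
#' @return A ggplot heatmap on log1p counts.
#' @method autoplot chiahub_contact_matrix
#' @export
autoplot.chiahub_contact_matrix <- function(object, ...) {
  m <- object$matrix
  df <- tidyr::expand_grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  df$value <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j,
                                   fill = log1p(.data$value))) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$chrom, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot compartment calls
#'
#' @param object A `chiahub_compartments` tibble.
#' @param ... Unused.
#' @return A ggplot bar track of the eigenvector coloured by A/B label.
#' @method autoplot chiahub_compartments
#' @export
autoplot.chiahub_compartments <- function(object, ...) {
  df <- object[object$label != "masked", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start / 1e6,
                                   y = .data$eigenvector,
                                   fill = .data$label)) +
    ggplot2::geom_col(width = (df$end[1] - df$start[1]) / 1e6) +
    ggplot2::scale_fill_manual(values = c(A = "firebrick", B = "steelblue")) +
    ggplot2::labs(x = "position (Mb)", y = "eigenvector",
                  title = attr(object, "chrom")) +
    ggplot2::theme_minimal()
}

#' Plot hub change categories
#'
#' @param deltas Output of [compare_conditions()].
#' @return A ggplot bar chart of hub counts per category.
#' @export
plot_hub_deltas <- function(deltas) {
  df <- dplyr::count(deltas, category = factor(.data$category,
                                               c("stable", "PDH", "EDH", "FH")))
  ggplot2::ggplot(df, ggplot2::aes(.data$category, .data$n)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = NULL, y = "hubs") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
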