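#' Boxplots of biomarker distributions by group
#'
#' Descriptive per-dataset boxplots of one or more biomarkers, control
#' versus PD — the standard companion figure to the group-comparison tables.
#'
#' @param table Long biomarker table (see [run_extract()]).
#' @param metadata Subject metadata with `subject_id` and `group`.
#' @param biomarkers Biomarker names to plot (default: all present).
#' @param task Task class to plot (default: first present).
#' @return A ggplot object.
#' @export
plot_biomarker_distributions <- function(table, metadata, biomarkers = NULL,
                                         task = NULL) {
  df <- dplyr::inner_join(table, metadata[, c("subject_id", "group")],
                          by = "subject_id")
  task <- task %||% df$task[1]
  df <- df[df$task == task & !is.na(df$value), , drop = FALSE]
  if (!is.null(biomarkers)) df <- df[df$biomarker %in% biomarkers, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::facet_grid(biomarker ~ dataset, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Biomarker distributions by group (%s task)", task)) +
    ggplot2::theme_minimal()
}

#' Plot effect sizes of a biomarker analysis
#'
#' Dot plot of the H-based eta-squared per dataset and biomarker, with
#' significant cells emphasized.
#'
#' @param object A `biomarker_analysis`.
#' @param ... Unused.
#' @method autoplot biomarker_analysis
#' @export
autoplot.biomarker_analysis <- function(object, ...) {
  df <- object$tests
  ggplot2::ggplot(df, ggplot2::aes(x = .data$eta2, y = .data$biomarker,
                                   colour = .data$dataset,
                                   alpha = .data$significant)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.25)) +
    ggplot2::facet_wrap(~task) +
    ggplot2::labs(x = expression(eta^2), y = NULL,
                  alpha = "significant (FDR)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
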