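## ggplot2 displays for the main result types.

#' Plot association results (set-level significance)
#'
#' Bar/point display of `-log10 p_set` per SNP set with the screen
#' threshold.
#'
#' @param results tibble from [associate_sets()].
#' @param threshold screen threshold drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_associations <- function(results, threshold = 4e-4) {
  df <- results[!is.na(results$p_set), , drop = FALSE]
  df$set_label <- stats::reorder(df$set_label, -log10(df$p_set))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$set_label,
                                   y = -log10(.data$p_set))) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(threshold), linetype = 2) +
    ggplot2::labs(x = "SNP set", y = expression(-log[10]~p[set])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Heatmap of relation strength between SNP sets and temperament sets
#'
#' @param edges relation tibble from [relation_screen()].
#' @return A ggplot object.
#' @export
plot_relations <- function(edges) {
  ggplot2::ggplot(edges, ggplot2::aes(x = .data$temp_set_label,
                                      y = .data$snp_set_label,
                                      fill = -log10(.data$p_hyper))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression(-log[10]~p)) +
    ggplot2::labs(x = "temperament set", y = "SNP set") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @export
autoplot.h2_estimate <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$estimate), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$estimate - .data$std.error,
                   ymax = .data$estimate + .data$std.error),
      width = 0.15, na.rm = TRUE) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "heritability (R²)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.set_classifier <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$auc)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "cross-validated AUC") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
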