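# ggplot2 views of the result types.

#' @export
autoplot.prip_roc <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(colour = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate (1 - SP)",
                  y = "true positive rate (SN)",
                  title = sprintf("ROC (AUROC = %.3f)", attr(object, "auroc"))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.prip_scan <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$length, y = .data$auroc)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "window length", y = "mean cross-validated AUROC") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.prip_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(object$folds, -"fold",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, height = 0, colour = "#2166ac") +
    ggplot2::labs(x = NULL, y = "per-fold value") +
    ggplot2::theme_minimal()
}

residue_matrix_plot <- function(m, value_name, title) {
  df <- tidyr::expand_grid(row = rownames(m), col = colnames(m))
  df$value <- as.numeric(m[cbind(df$row, df$col)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = NULL, y = NULL, fill = value_name, title = title) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.relation_matrix <- function(object, ...) {
  residue_matrix_plot(unclass(object), "cosine",
                      paste0("semantic relations (", attr(object, "source"), ")")) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1))
}

#' @export
autoplot.pvalue_matrix <- function(object, ...) {
  residue_matrix_plot(unclass(object), "p-value", "semantic specificity") +
    ggplot2::scale_fill_gradient(low = "#b2182b", high = "white",
                                 limits = c(0, 1))
}

#' @export
autoplot.enrichment_table <- function(object, ...) {
  called <- unique(object$residue[object$call != "neither"])
  df <- object[object$residue %in% called, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$difference,
                                   fill = .data$call)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~residue) +
    ggplot2::scale_fill_manual(values = c(enriched = "#b2182b",
                                          depleted = "#2166ac",
                                          neither = "grey80")) +
    ggplot2::labs(x = "position relative to centre",
                  y = "positive - negative fraction") +
    ggplot2::theme_minimal()
}
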