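#' Selectivity plane: cross-tissue CV versus liver expression
#'
#' The candidate-selection scatter: every scored gene at (log10 liver TPM,
#' CV), with DEGs highlighted and, when supplied, the selected candidates
#' labelled. Liver-selective genes populate the top-right corner.
#'
#' @param scores Output of [classify_selective()] (or [tissue_cv()]).
#' @param deg_set Optional character vector of DEG ids to highlight.
#' @param candidates Optional `liversig_candidates` tibble to label.
#' @return A ggplot object.
#' @export
plot_selectivity <- function(scores, deg_set = NULL, candidates = NULL) {
  df <- dplyr::mutate(scores,
    status = dplyr::case_when(
      !is.null(candidates) & .data$gene_id %in% candidates$gene_id ~ "candidate",
      !is.null(deg_set) & .data$gene_id %in% deg_set ~ "DEG",
      TRUE ~ "background"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$liver_tpm + 0.5),
                                        y = .data$cv)) +
    ggplot2::geom_point(data = ~dplyr::filter(.x, .data$status == "background"),
                        colour = "grey70", size = 0.6) +
    ggplot2::geom_point(data = ~dplyr::filter(.x, .data$status == "DEG"),
                        colour = "darkgreen", size = 1.2) +
    ggplot2::labs(x = "liver expression, log10(TPM + 0.5)",
                  y = "coefficient of variation across tissues") +
    ggplot2::theme_minimal()
  if (!is.null(candidates) && nrow(candidates) > 0) {
    lab <- dplyr::filter(df, .data$status == "candidate")
    p <- p +
      ggplot2::geom_point(data = lab, colour = "red", size = 2) +
      ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$gene_id),
                         vjust = -0.8, size = 3)
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.liversig_pca <- function(object, ...) {
  ve <- object$var_explained
  ggplot2::ggplot(object$coords,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$nas_group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * ve[2]),
                  colour = "NAS group") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.liversig_de <- function(object, alpha = 0.05, ...) {
  df <- dplyr::mutate(as_tibble(object),
    status = dplyr::case_when(
      .data$padj < alpha & .data$log2fc > 0 ~ "up",
      .data$padj < alpha & .data$log2fc < 0 ~ "down",
      TRUE ~ "ns"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$p, 1e-300)),
                                   colour = .data$status)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(up = "darkgreen", down = "red",
                                            ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p") +
    ggplot2::theme_minimal()
}
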