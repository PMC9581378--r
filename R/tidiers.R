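#' @exportS3Method generics::tidy
tidy.liversig_de <- function(x, ...) {
  as_tibble(x) |>
    dplyr::mutate(contrast = attr(x, "contrast"),
                  reference = attr(x, "reference"))
}

#' @exportS3Method generics::glance
glance.liversig_de <- function(x, alpha = 0.05, ...) {
  tibble(contrast = attr(x, "contrast"), reference = attr(x, "reference"),
         n_genes = nrow(x),
         n_deg = sum(x$padj < alpha, na.rm = TRUE),
         n_up = sum(x$padj < alpha & x$log2fc > 0, na.rm = TRUE),
         n_down = sum(x$padj < alpha & x$log2fc < 0, na.rm = TRUE))
}

#' @exportS3Method generics::tidy
tidy.liversig_enrich <- function(x, ...) as_tibble(x)

#' @exportS3Method generics::glance
glance.liversig_enrich <- function(x, alpha = 0.05, ...) {
  tibble(n_sets = nrow(x),
         n_sig = sum(x$padj < alpha, na.rm = TRUE),
         n_up = sum(x$padj < alpha & x$direction == "up", na.rm = TRUE),
         n_down = sum(x$padj < alpha & x$direction == "down", na.rm = TRUE))
}

#' @exportS3Method generics::tidy
tidy.liversig_pca <- function(x, ...) x$coords

#' @exportS3Method generics::glance
glance.liversig_pca <- function(x, ...) {
  tibble(n_samples = nrow(x$coords),
         pc1_var = x$var_explained[1],
         pc2_var = x$var_explained[2])
}
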