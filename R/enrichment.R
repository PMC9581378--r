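#' Per-gene signed z-scores from DE results
#'
#' Converts each gene's two-sided p-value and fold-change sign into a signed
#' normal score, \eqn{z = \mathrm{sign}(\mathrm{log2fc}) \Phi^{-1}(1 - p/2)}.
#' This is the gene-level statistic the directional Stouffer set test
#' combines. Zero p-values are clipped to a tiny floor so the quantile stays
#' finite; genes with missing fold changes are skipped with a message.
#'
#' @param de A `liversig_de` tibble (or any data frame with `gene_id`,
#'   `log2fc`, `p`).
#' @param p_floor Clip for p = 0 (default `1e-300`).
#' @return Tibble `gene_id`, `z`.
#' @export
gene_level_z <- function(de, p_floor = 1e-300) {
  skipped <- is.na(de$log2fc) | is.na(de$p)
  if (any(skipped)) {
    rlang::inform(paste0("gene_level_z: skipping ", sum(skipped),
                         " gene(s) with missing statistics."))
  }
  de <- de[!skipped, , drop = FALSE]
  p <- pmax(de$p, p_floor)
  z <- sign(de$log2fc) * qnorm(p / 2, lower.tail = FALSE)
  tibble(gene_id = de$gene_id, z = z)
}

#' Directional Stouffer gene-set test
#'
#' For each gene set, member genes are intersected with the tested universe
#' and their signed z-scores combined as \eqn{Z = \sum z_i / \sqrt{n}}. Under
#' the null of no coordinated regulation Z is standard normal, giving a
#' two-sided p; Benjamini-Hochberg adjustment is applied across all tested
#' sets. Sets with fewer than `min_size` members in the universe are dropped.
#'
#' @param z Tibble from [gene_level_z()].
#' @param sets Named list of gene id vectors (e.g. from [read_gmt()]).
#' @param min_size Minimum post-intersection set size (default 3).
#' @return A `liversig_enrich` tibble: `set_name`, `n_genes_tested`,
#'   `stouffer_z`, `p`, `padj`, `direction`.
#' @export
stouffer_set_test <- function(z, sets, min_size = 3) {
  if (length(sets) == 0) abort("Empty gene-set collection.")
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    abort("Gene sets must carry unique names.")
  }
  zmap <- setNames(z$z, z$gene_id)
  rows <- purrr::map(names(sets), function(nm) {
    members <- intersect(unique(sets[[nm]]), names(zmap))
    n <- length(members)
    if (n < min_size) return(NULL)
    zc <- sum(zmap[members]) / sqrt(n)
    tibble(set_name = nm, n_genes_tested = n, stouffer_z = zc,
           p = 2 * pnorm(-abs(zc)))
  })
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0) {
    abort(paste0("No gene set reaches min_size = ", min_size,
                 " after intersection with the tested universe."))
  }
  res <- dplyr::mutate(res,
    padj = bh_adjust(.data$p),
    direction = ifelse(.data$stouffer_z >= 0, "up", "down"))
  structure(res, class = c("liversig_enrich", class(res)))
}
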