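#' Re-test candidate genes in an independent cohort
#'
#' Applies the same NB-Wald machinery as discovery — size factors and
#' dispersions estimated on the full validation matrix, contrast anchored to
#' the same NAS 0-1 reference — but reports statistics for the candidate
#' genes only, with Benjamini-Hochberg adjustment within the candidate set
#' (the question is confirmation of a fixed short list, not rediscovery).
#' Candidates missing from the dataset's gene universe are flagged
#' `present = FALSE`.
#'
#' @param candidates A `liversig_candidates` tibble (or a character vector of
#'   gene ids).
#' @param dataset A [count_matrix()] with NAS-comparable group labels.
#' @param contrast Contrast group label tested against the reference.
#' @param reference Reference group label (default `"NAS0-1"`).
#' @param dataset_id Identifier recorded in the output.
#' @return Tibble: `gene_id`, `dataset`, `contrast`, `present`, `log2fc`,
#'   `p`, `padj`.
#' @export
revalidate <- function(candidates, dataset, contrast, reference = "NAS0-1",
                       dataset_id = "validation") {
  ids <- if (is.data.frame(candidates)) candidates$gene_id else candidates
  if (length(ids) == 0) abort("No candidate genes supplied.")
  present <- ids %in% rownames(dataset$counts)
  if (!any(present)) {
    abort(paste0("No candidate gene present in dataset ", dataset_id, ": ",
                 paste(ids, collapse = ", ")))
  }
  sf <- size_factors(dataset)
  disp <- estimate_dispersion(dataset, sf)
  de <- wald_test(dataset, sf, disp, contrast = contrast,
                  reference = reference)
  hit <- de[match(ids, de$gene_id), ]
  out <- tibble(gene_id = ids, dataset = dataset_id, contrast = contrast,
                present = present & !is.na(hit$gene_id),
                log2fc = hit$log2fc, p = hit$p)
  out$padj <- NA_real_
  out$padj[out$present] <- bh_adjust(out$p[out$present])
  out$log2fc[!out$present] <- NA_real_
  out$p[!out$present] <- NA_real_
  out
}

#' Cross-dataset direction concordance
#'
#' For each candidate, the fraction of validation datasets whose estimated
#' fold change agrees in sign with the discovery estimate, among datasets
#' where the gene is present. Genes present in no dataset are flagged with
#' `NA` concordance.
#'
#' @param reports List (or row-bound tibble) of [revalidate()] outputs.
#' @param discovery A `liversig_candidates` tibble carrying the discovery
#'   `log2fc` per gene.
#' @return Tibble: `gene_id`, `n_datasets`, `n_concordant`,
#'   `direction_concordance`.
#' @export
concordance <- function(reports, discovery) {
  if (is.data.frame(reports)) reports <- list(reports)
  if (length(reports) < 1) abort("At least one validation report required.")
  long <- dplyr::bind_rows(reports)
  ref_sign <- setNames(sign(discovery$log2fc), discovery$gene_id)
  out <- long |>
    dplyr::filter(.data$gene_id %in% names(ref_sign)) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_datasets = sum(.data$present),
      n_concordant = sum(.data$present &
                           sign(.data$log2fc) == ref_sign[.data$gene_id[1]],
                         na.rm = TRUE),
      .groups = "drop") |>
    dplyr::mutate(direction_concordance = ifelse(
      .data$n_datasets > 0, .data$n_concordant / .data$n_datasets, NA_real_))
  absent <- out$gene_id[out$n_datasets == 0]
  if (length(absent) > 0) {
    warn(paste0("Gene(s) absent from every validation dataset: ",
                paste(absent, collapse = ", ")))
  }
  out
}
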