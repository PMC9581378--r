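#' Cross-tissue coefficient of variation
#'
#' Scores each gene for tissue-restricted expression: the coefficient of
#' variation (sample standard deviation / mean) of its TPM vector across all
#' tissues, liver included. A flat expression profile gives CV = 0; a gene
#' expressed in liver only reaches the maximum \eqn{\sqrt{T}} for T tissues
#' (5.745 at the 33 tissues of a consensus atlas). High CV combined with high
#' liver TPM places a gene in the "liver-selective" top-right corner of the
#' selectivity plane.
#'
#' @param atlas Data frame of per-gene TPM: column `gene_id` plus one numeric
#'   column per tissue, one of which must be named `liver`.
#' @return Tibble `gene_id`, `liver_tpm`, `cv`, `liver_is_max`. Genes with
#'   zero mean TPM have undefined CV and are dropped with a message.
#' @export
tissue_cv <- function(atlas) {
  atlas <- as_tibble(atlas)
  tissues <- setdiff(names(atlas), "gene_id")
  if (!"liver" %in% tissues) abort("Atlas has no `liver` column.")
  if (sum(tissues == "liver") != 1) abort("Atlas must have exactly one `liver` column.")
  if (length(tissues) < 3) {
    abort("At least 3 tissues are required for a meaningful CV.")
  }
  tpm <- as.matrix(atlas[, tissues])
  if (any(tpm < 0)) abort("Atlas TPM values must be non-negative.")
  mu <- rowMeans(tpm)
  drop <- mu <= 0
  if (any(drop)) {
    rlang::inform(paste0("tissue_cv: dropping ", sum(drop),
                         " gene(s) with zero expression in every tissue."))
  }
  s <- apply(tpm, 1, sd)
  tibble(gene_id = atlas$gene_id,
         liver_tpm = tpm[, "liver"],
         cv = s / mu,
         liver_is_max = tpm[, "liver"] >= apply(tpm, 1, max))[!drop, ]
}

#' Flag liver-selective genes
#'
#' A gene is called liver-selective when all three hold: liver TPM at or above
#' an absolute floor, CV at or above an empirical quantile of all scored
#' genes, and liver is the gene's maximally expressing tissue. Ranks order all
#' scored genes by descending CV with liver TPM breaking ties.
#'
#' @param scores Tibble from [tissue_cv()].
#' @param liver_tpm_floor Minimum liver expression in TPM (default 10).
#' @param cv_quantile Empirical CV quantile a selective gene must reach
#'   (default 0.90).
#' @return `scores` with added `selective` and `selectivity_rank`.
#' @export
classify_selective <- function(scores, liver_tpm_floor = 10, cv_quantile = 0.90) {
  if (nrow(scores) == 0) abort("No scored genes to classify.")
  if (cv_quantile <= 0 || cv_quantile >= 1) abort("`cv_quantile` must be in (0, 1).")
  cv_cut <- quantile(scores$cv, cv_quantile, names = FALSE)
  ord <- order(-scores$cv, -scores$liver_tpm, scores$gene_id)
  rank <- integer(nrow(scores))
  rank[ord] <- seq_len(nrow(scores))
  dplyr::mutate(scores,
    selective = .data$liver_tpm >= liver_tpm_floor &
      .data$cv >= cv_cut & .data$liver_is_max,
    selectivity_rank = rank)
}

#' Secretion evidence flags from three gene lists
#'
#' Membership in any of three evidence sources marks a gene product as
#' potentially circulating: secretion from cultured human hepatocytes,
#' detection in a human blood proteome dataset, or sequence-based secretion
#' prediction. Matching is case-insensitive exact symbol match; duplicates
#' within a list are deduplicated with a warning.
#'
#' @param genes Character vector of gene ids (the tested universe).
#' @param list_hepatocyte,list_blood,list_predicted Character vectors of gene
#'   symbols.
#' @return Tibble `gene_id`, `hepatocyte_secretome`, `blood_proteome`,
#'   `predicted_secreted`, `secreted` (the disjunction).
#' @export
secretion_flags <- function(genes, list_hepatocyte, list_blood, list_predicted) {
  norm_list <- function(x, nm) {
    x <- toupper(x)
    if (anyDuplicated(x)) {
      warn(paste0("Duplicate symbols in ", nm, " list; deduplicated."))
    }
    unique(x)
  }
  hep <- norm_list(list_hepatocyte, "hepatocyte secretome")
  blo <- norm_list(list_blood, "blood proteome")
  pre <- norm_list(list_predicted, "predicted secreted")
  up <- toupper(genes)
  tibble(gene_id = genes,
         hepatocyte_secretome = up %in% hep,
         blood_proteome = up %in% blo,
         predicted_secreted = up %in% pre) |>
    dplyr::mutate(secreted = .data$hepatocyte_secretome |
                    .data$blood_proteome | .data$predicted_secreted)
}

#' Assemble the candidate biomarker table
#'
#' Intersects three filters: differential expression (the DEG set), liver
#' selectivity, and secretion evidence. A non-secreted but liver-selective DEG
#' may still enter via `indirect_map` when its circulating catalytic product
#' is measurable (the MAT1A / S-adenosylmethionine situation); such rows carry
#' `marker_mode = "indirect_metabolite"` and the analyte name. Candidates are
#' ranked by the average of three ranks — padj ascending, |log2fc| descending,
#' CV descending — with lexicographic gene id as the final tie-break.
#'
#' @param deg_set Character vector of DEG ids.
#' @param de A `liversig_de` tibble supplying log2fc/padj for the candidates
#'   (use the contrast each gene was most significant in).
#' @param scores Output of [classify_selective()].
#' @param evidence Output of [secretion_flags()].
#' @param indirect_map Named character vector: gene id -> plasma metabolite
#'   measured as its surrogate. Default empty.
#' @return A `liversig_candidates` tibble; zero rows when no gene survives.
#' @export
select_candidates <- function(deg_set, de, scores, evidence,
                              indirect_map = character()) {
  sel <- scores$gene_id[scores$selective]
  sec <- evidence$gene_id[evidence$secreted]
  keep <- intersect(intersect(deg_set, sel),
                    union(sec, names(indirect_map)))
  if (length(keep) == 0) {
    res <- tibble(gene_id = character(), log2fc = numeric(),
                  padj = numeric(), cv = numeric(), liver_tpm = numeric(),
                  hepatocyte_secretome = logical(), blood_proteome = logical(),
                  predicted_secreted = logical(), secreted = logical(),
                  marker_mode = character(), metabolite_name = character(),
                  composite_rank = integer())
    return(structure(res, class = c("liversig_candidates", class(res))))
  }
  res <- tibble(gene_id = keep) |>
    dplyr::left_join(de[, c("gene_id", "log2fc", "padj")], by = "gene_id") |>
    dplyr::left_join(scores[, c("gene_id", "cv", "liver_tpm")], by = "gene_id") |>
    dplyr::left_join(evidence, by = "gene_id") |>
    dplyr::mutate(
      marker_mode = ifelse(.data$secreted, "direct", "indirect_metabolite"),
      metabolite_name = ifelse(.data$gene_id %in% names(indirect_map),
                               unname(indirect_map[.data$gene_id]),
                               NA_character_))
  score <- (rank(res$padj) + rank(-abs(res$log2fc)) + rank(-res$cv)) / 3
  ord <- order(score, res$gene_id)
  res$composite_rank <- integer(nrow(res))
  res$composite_rank[ord] <- seq_len(nrow(res))
  res <- dplyr::arrange(res, .data$composite_rank)
  structure(res, class = c("liversig_candidates", class(res)))
}

#' Count DEGs with secretion evidence
#'
#' The size of the intersection between the DEG set and the genes flagged as
#' secreted by any evidence source.
#'
#' @inheritParams select_candidates
#' @return Integer count.
#' @export
secreted_deg_count <- function(deg_set, evidence) {
  length(intersect(deg_set, evidence$gene_id[evidence$secreted]))
}
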