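#' Read and write pipeline files
#'
#' All on-disk formats are tab-separated text with `#`-prefixed comment lines
#' and gene ids in the first column. `read_counts()` pairs a gene x sample
#' count TSV with a sample sheet TSV (columns `sample_id`, `nas_group`, plus
#' any covariates) and returns a validated [count_matrix()]; `read_atlas()`
#' requires a `liver` column; `read_gene_list()` reads one symbol per line;
#' `read_gmt()` parses the standard gene-set format (set name, description,
#' then members, tab-separated).
#'
#' @param path,counts_path,samples_path File paths.
#' @return Typed objects; malformed input errors name the offending row or
#'   cell.
#' @name pipeline-io
NULL

read_tsv_quiet <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' @rdname pipeline-io
#' @export
read_counts <- function(counts_path, samples_path) {
  tab <- read_tsv_quiet(counts_path)
  genes <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1])
  if (!is.numeric(m)) abort("Count columns must be numeric.")
  rownames(m) <- genes
  samples <- read_tsv_quiet(samples_path)
  count_matrix(m, samples)
}

#' @rdname pipeline-io
#' @export
read_atlas <- function(path) {
  tab <- read_tsv_quiet(path)
  names(tab)[1] <- "gene_id"
  if (!"liver" %in% names(tab)) {
    abort("Atlas file has no `liver` column.")
  }
  if (anyDuplicated(tab$gene_id)) {
    abort(paste0("Duplicate gene id in atlas: ",
                 tab$gene_id[duplicated(tab$gene_id)][1]))
  }
  tab
}

#' @rdname pipeline-io
#' @export
read_sheet <- function(path) read_tsv_quiet(path)

#' @rdname pipeline-io
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x[!grepl("^#", x) & nzchar(trimws(x))])
  if (anyDuplicated(toupper(x))) {
    warn(paste0("Duplicate symbols in ", basename(path), "; deduplicated."))
    x <- x[!duplicated(toupper(x))]
  }
  x
}

#' @rdname pipeline-io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      abort(paste0("Malformed GMT line ", i, ": expected at least 3 ",
                   "tab-separated fields (name, description, members)."))
    }
    f
  })
  nms <- vapply(fields, `[`, character(1), 1)
  if (anyDuplicated(nms)) abort("Duplicate set names in GMT file.")
  setNames(lapply(fields, function(f) f[-(1:2)]), nms)
}

#' @rdname pipeline-io
#' @param cm A [count_matrix()] to write.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @export
write_counts <- function(cm, dir, prefix = "counts") {
  cp <- file.path(dir, paste0(prefix, ".tsv"))
  sp <- file.path(dir, paste0(prefix, "_samples.tsv"))
  tab <- dplyr::bind_cols(tibble(gene_id = rownames(cm$counts)),
                          as_tibble(cm$counts))
  readr::write_tsv(tab, cp)
  readr::write_tsv(cm$samples, sp)
  invisible(c(counts = cp, samples = sp))
}

#' Orchestrated discovery run
#'
#' Executes the full biomarker discovery pipeline on one input bundle:
#' median-of-ratios normalization, per-gene dispersion, NB-Wald contrasts of
#' each higher-NAS group against the NAS 0-1 reference, BH-FDR DEG sets and
#' their overlaps, optional Stouffer gene-set enrichment, cross-tissue CV
#' selectivity scoring, secretion-evidence flags, candidate selection and
#' ranking, optional re-validation in independent datasets, and the cohort
#' summary tables. With `bundle = NULL` a synthetic study is generated from
#' `config` — the fully self-contained benchmark mode.
#'
#' @param config A [sim_config()] (seeds and thresholds live here).
#' @param bundle A [simulate_study()]-shaped list of inputs, or `NULL` to
#'   generate one from `config`.
#' @param alpha DEG FDR cut-off (default 0.05).
#' @param liver_tpm_floor,cv_quantile Selectivity thresholds, see
#'   [classify_selective()].
#' @param gene_sets Optional named list of gene sets for enrichment.
#' @param validation_datasets Optional named list of [count_matrix()] objects
#'   to re-validate candidates in.
#' @param out_dir Optional directory; when given, every result table is
#'   written as TSV plus a JSON provenance sidecar (seed, config hash). On
#'   any stage failure partial outputs are removed.
#' @return List: `size_factors`, `dispersions`, `de` (per contrast), `degs`,
#'   `enrichment` (or NULL), `scores`, `evidence`, `candidates`,
#'   `validation` (or NULL), `cohort_summary`.
#' @export
run_discovery <- function(config = sim_config(), bundle = NULL,
                          alpha = 0.05, liver_tpm_floor = 10,
                          cv_quantile = 0.90, gene_sets = NULL,
                          validation_datasets = NULL, out_dir = NULL) {
  if (alpha <= 0 || alpha > 1) abort("`alpha` must lie in (0, 1].")
  if (is.null(bundle)) bundle <- simulate_study(config)
  stage <- "input"
  written <- character()
  result <- tryCatch({
    cm <- bundle$counts$data
    reference <- "NAS0-1"
    contrasts <- setdiff(unique(cm$samples$nas_group), reference)

    stage <- "diffexpr"
    sf <- size_factors(cm)
    disp <- estimate_dispersion(cm, sf)
    de <- lapply(contrasts, function(g) {
      wald_test(cm, sf, disp, contrast = g, reference = reference)
    })
    names(de) <- contrasts
    shared <- Reduce(intersect, lapply(de, function(d) d$gene_id))
    de_shared <- lapply(de, function(d) d[d$gene_id %in% shared, ])
    degs <- deg_sets(de_shared, alpha = alpha)
    deg_union <- sort(unique(unlist(degs$sets)))

    enrich <- NULL
    if (!is.null(gene_sets)) {
      stage <- "enrichment"
      enrich <- lapply(de, function(d) {
        stouffer_set_test(gene_level_z(d), gene_sets)
      })
    }

    stage <- "selectivity_secretome"
    scores <- classify_selective(tissue_cv(bundle$atlas$atlas),
                                 liver_tpm_floor = liver_tpm_floor,
                                 cv_quantile = cv_quantile)
    evidence <- secretion_flags(scores$gene_id,
                                bundle$lists$hepatocyte,
                                bundle$lists$blood,
                                bundle$lists$predicted)
    # per gene, carry the stats of the contrast it is most significant in
    de_best <- dplyr::bind_rows(de, .id = "contrast") |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::slice_min(.data$padj, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    candidates <- select_candidates(deg_union, de_best, scores, evidence,
                                    indirect_map = bundle$indirect_map)
    candidates <- dplyr::left_join(
      candidates, de_best[, c("gene_id", "contrast")], by = "gene_id")
    class(candidates) <- unique(c("liversig_candidates", class(candidates)))

    validation <- NULL
    if (!is.null(validation_datasets) && nrow(candidates) > 0) {
      stage <- "validation"
      reports <- purrr::imap(validation_datasets, function(ds, nm) {
        dplyr::bind_rows(lapply(unique(candidates$contrast), function(ct) {
          revalidate(candidates$gene_id[candidates$contrast == ct], ds,
                     contrast = ct, reference = reference, dataset_id = nm)
        }))
      })
      validation <- list(reports = dplyr::bind_rows(reports),
                         concordance = concordance(reports, candidates))
    }

    stage <- "cohortstats"
    cohort_summary <- summarize_cohort(bundle$cohort$sheet)

    out <- list(size_factors = sf, dispersions = disp, de = de, degs = degs,
                enrichment = enrich, scores = scores, evidence = evidence,
                candidates = candidates, validation = validation,
                cohort_summary = cohort_summary)

    if (!is.null(out_dir)) {
      stage <- "write"
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      w <- function(x, name) {
        p <- file.path(out_dir, paste0(name, ".tsv"))
        readr::write_tsv(as_tibble(x), p)
        written <<- c(written, p)
      }
      for (g in names(de)) w(de[[g]], paste0("de_", gsub("[^A-Za-z0-9]", "", g)))
      w(degs$overlaps, "deg_overlaps")
      w(scores, "selectivity_scores")
      w(evidence, "secretion_evidence")
      w(candidates, "candidates")
      if (!is.null(validation)) {
        w(validation$reports, "validation_reports")
        w(validation$concordance, "validation_concordance")
      }
      w(cohort_summary$continuous, "cohort_continuous")
      w(cohort_summary$frequencies, "cohort_frequencies")
      sidecar <- file.path(out_dir, "provenance.json")
      jsonlite::write_json(
        list(seed = config$seed, alpha = alpha,
             liver_tpm_floor = liver_tpm_floor, cv_quantile = cv_quantile,
             config_hash = rlang::hash(config),
             package_version = as.character(utils::packageVersion("liversig")),
             files = basename(written)),
        sidecar, auto_unbox = TRUE, pretty = TRUE)
      written <- c(written, sidecar)
    }
    out
  }, error = function(e) {
    unlink(written)
    abort(paste0("Discovery pipeline failed at stage `", stage, "`: ",
                 conditionMessage(e)))
  })
  result
}
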