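#' Construct a validated RNA-seq count container
#'
#' Bundles a gene x sample matrix of raw integer counts with its sample sheet.
#' This is the input boundary of the pipeline: alignment and quantification
#' happen upstream, and every downstream stage (normalization, dispersion,
#' Wald tests, PCA, validation) consumes this container.
#'
#' @param counts Non-negative integer matrix, genes as rows. Row names are the
#'   gene identifiers and must be unique; column names are the sample ids.
#' @param samples Data frame with one row per sample, columns `sample_id` and
#'   `nas_group` (the NAS severity group label, e.g. `"NAS0-1"`). Order is
#'   matched to the matrix columns by `sample_id`.
#' @return A `count_matrix` object: a list with elements `counts` (integer
#'   matrix) and `samples` (tibble).
#' @examples
#' m <- matrix(rpois(12, 10), nrow = 3,
#'             dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
#' cm <- count_matrix(m, data.frame(sample_id = paste0("S", 1:4),
#'                                  nas_group = rep(c("NAS0-1", "NAS4-6"), 2)))
#' cm
#' @export
count_matrix <- function(counts, samples) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must carry gene ids as row names and sample ids as column names.")
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- rownames(counts)[duplicated(rownames(counts))][1]
    abort(paste0("Duplicate gene id in counts: ", dup))
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(paste0("Counts must be non-negative integers; offending cell: gene ",
                 rownames(counts)[bad[1, 1]], ", sample ",
                 colnames(counts)[bad[1, 2]]))
  }
  samples <- as_tibble(samples)
  if (!all(c("sample_id", "nas_group") %in% names(samples))) {
    abort("`samples` needs columns `sample_id` and `nas_group`.")
  }
  missing <- setdiff(colnames(counts), samples$sample_id)
  if (length(missing) > 0) {
    abort(paste0("Samples without a group label: ",
                 paste(missing, collapse = ", ")))
  }
  samples <- samples[match(colnames(counts), samples$sample_id), ]
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  grp <- table(x$samples$nas_group)
  cat("<count_matrix> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples\n", sep = "")
  cat("  groups: ", paste(names(grp), grp, sep = "=", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

group_counts <- function(cm, label) {
  cm$counts[, cm$samples$nas_group == label, drop = FALSE]
}

check_group <- function(cm, label, min_n = 2L) {
  n <- sum(cm$samples$nas_group == label)
  if (n == 0) abort(paste0("Group not present in sample sheet: ", label))
  if (n < min_n) {
    abort(paste0("Group ", label, " has ", n,
                 " sample(s); at least ", min_n, " required."))
  }
  invisible(n)
}
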