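#' Median-of-ratios size factors
#'
#' Per-sample normalization constants correcting for sequencing depth. For each
#' sample the factor is the median, over reference genes, of the ratio between
#' the sample's count and the gene's geometric mean across all samples.
#' Reference genes are those with a nonzero count in every sample (the
#' geometric mean of a row containing a zero is zero and the ratio undefined).
#'
#' @param cm A [count_matrix()].
#' @return Named numeric vector of positive factors, one per sample.
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), nrow = 3,
#'             dimnames = list(paste0("G", 1:3), c("a", "b")))
#' cm <- count_matrix(m, data.frame(sample_id = c("a", "b"),
#'                                  nas_group = c("NAS0-1", "NAS4-6")))
#' size_factors(cm)  # (1/sqrt(2), sqrt(2))
#' @export
size_factors <- function(cm) {
  counts <- cm$counts
  ref <- rowSums(counts == 0) == 0
  if (!any(ref)) {
    abort(paste0(
      "Cannot compute size factors: no gene has nonzero counts in every ",
      "sample (", nrow(counts), " genes, ", ncol(counts), " samples). ",
      "Median-of-ratios needs at least one all-expressed reference gene."))
  }
  lg <- log(counts[ref, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(exp(lg - geo), 2, median)
  if (any(!is.finite(sf) | sf <= 0)) abort("Degenerate size factor computed.")
  sf
}

#' Method-of-moments negative-binomial dispersion
#'
#' A deliberately simple per-gene dispersion estimator for the NB variance
#' model \eqn{v = \mu + \alpha \mu^2}: counts are divided by their size
#' factors, the sample variance is pooled within NAS groups (so planted group
#' differences do not masquerade as dispersion), and the per-gene moments
#' estimate is \eqn{\hat\alpha = \max(\mathrm{floor}, (s^2 - \bar m)/\bar m^2)}.
#' At cohort-scale sample sizes the raw moments estimate is noisy, and that
#' noise makes the downstream Wald test anti-conservative, so by default the
#' per-gene estimates are moderated toward the mean dispersion across genes
#' with `prior_df` pseudo-degrees of freedom (a precision-weighted average, as
#' in moderated-statistics pipelines; no mean-dispersion trend is fitted).
#' `prior_df = 0` gives the raw per-gene moments estimate.
#'
#' @param cm A [count_matrix()].
#' @param sf Size factors from [size_factors()].
#' @param floor Lower bound for the estimate (Poisson-like genes hit it).
#' @param prior_df Weight (pseudo-df) of the across-gene mean dispersion in
#'   the moderated estimate; the per-gene estimate carries the pooled
#'   within-group residual df. Default 20.
#' @return Tibble with columns `gene_id`, `dispersion`, `excluded` (all-zero
#'   genes carry `NA` dispersion and `excluded = TRUE`).
#' @export
estimate_dispersion <- function(cm, sf, floor = 1e-8, prior_df = 20) {
  groups <- unique(cm$samples$nas_group)
  for (g in groups) check_group(cm, g)
  norm <- sweep(cm$counts, 2, sf, "/")
  ssq <- matrix(0, nrow(norm), 1)
  df <- 0
  grand <- rowMeans(norm)
  pooled_ss <- rep(0, nrow(norm))
  for (g in groups) {
    sub <- norm[, cm$samples$nas_group == g, drop = FALSE]
    mu_g <- rowMeans(sub)
    pooled_ss <- pooled_ss + rowSums((sub - mu_g)^2)
    df <- df + ncol(sub) - 1L
  }
  s2 <- pooled_ss / df
  raw <- (s2 - grand) / grand^2
  if (prior_df > 0) {
    abar <- mean(pmax(raw, 0)[is.finite(raw)], na.rm = TRUE)
    raw <- (prior_df * abar + df * raw) / (prior_df + df)
  }
  alpha <- pmax(floor, raw)
  excluded <- rowSums(cm$counts) == 0
  alpha[excluded] <- NA_real_
  tibble(gene_id = rownames(cm$counts), dispersion = alpha,
         excluded = excluded)
}

# Vectorized per-gene NB mean MLE within one group, in eta = log(mu).
# Score U(eta) = sum_j [y - (y+r) m/(m+r)], m = s_j exp(eta); strictly
# decreasing in eta, so Newton with step damping finds the unique root.
# Returns list(mu, info) with observed Fisher information at the MLE.
nb_group_fit <- function(y, s, alpha, mu_floor = 1e-8, max_iter = 50L) {
  r <- 1 / alpha
  tot <- rowSums(y)
  eta <- log(pmax(tot / sum(s), mu_floor))
  for (it in seq_len(max_iter)) {
    m <- exp(eta) %o% s
    U <- rowSums(y - (y + r) * m / (m + r))
    I <- rowSums((y + r) * m / (m + r)^2) * r
    step <- U / pmax(I, 1e-12)
    step <- pmin(pmax(step, -5), 5)
    eta <- eta + step
    if (max(abs(step)) < 1e-10) break
  }
  eta[tot == 0] <- log(mu_floor)
  mu <- exp(eta)
  m <- mu %o% s
  info <- rowSums((y + r) * m / (m + r)^2) * r
  list(mu = mu, info = info)
}

#' Negative-binomial Wald test between two NAS groups
#'
#' Per-gene group means are maximum-likelihood fitted under
#' NB(mean = size factor x mu, dispersion alpha), the log2 fold change is
#' `log2(mu_contrast / mu_ref)`, its standard error comes from the observed
#' Fisher information of the two independent group fits, and a two-sided
#' normal p-value is attached. Genes with zero counts in both contrast groups
#' are excluded.
#'
#' @param cm A [count_matrix()].
#' @param sf Size factors.
#' @param dispersions Tibble from [estimate_dispersion()] (or a named numeric
#'   vector of per-gene alphas).
#' @param contrast Group label tested against the reference.
#' @param reference Reference group label (default `"NAS0-1"`, the no/mild
#'   NAFLD group every comparison in the study is anchored to).
#' @return A `liversig_de` tibble: `gene_id`, `base_mean`, `log2fc`, `se`,
#'   `wald_stat`, `p`, `padj` (Benjamini-Hochberg over the tested genes).
#' @export
wald_test <- function(cm, sf, dispersions, contrast, reference = "NAS0-1") {
  check_group(cm, contrast)
  check_group(cm, reference)
  if (is.data.frame(dispersions)) {
    alpha <- setNames(dispersions$dispersion, dispersions$gene_id)
  } else {
    alpha <- dispersions
  }
  alpha <- alpha[rownames(cm$counts)]
  y_con <- group_counts(cm, contrast)
  y_ref <- group_counts(cm, reference)
  s_con <- sf[cm$samples$nas_group == contrast]
  s_ref <- sf[cm$samples$nas_group == reference]

  keep <- rowSums(y_con) + rowSums(y_ref) > 0 & !is.na(alpha)
  y_con <- y_con[keep, , drop = FALSE]
  y_ref <- y_ref[keep, , drop = FALSE]
  a <- pmax(alpha[keep], 1e-8)

  fit_con <- nb_group_fit(y_con, s_con, a)
  fit_ref <- nb_group_fit(y_ref, s_ref, a)

  log2fc <- unname(log2(fit_con$mu / fit_ref$mu))
  se <- unname(sqrt(1 / pmax(fit_con$info, 1e-12) +
                    1 / pmax(fit_ref$info, 1e-12))) / log(2)
  z <- log2fc / se
  p <- 2 * pnorm(-abs(z))
  norm <- cbind(sweep(y_ref, 2, s_ref, "/"), sweep(y_con, 2, s_con, "/"))
  res <- tibble(
    gene_id = rownames(y_con),
    base_mean = rowMeans(norm),
    log2fc = log2fc, se = se, wald_stat = z, p = p,
    padj = bh_adjust(p))
  structure(res, class = c("liversig_de", class(res)),
            contrast = contrast, reference = reference)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control; a validating wrapper around
#' [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Differentially expressed gene sets and their overlaps
#'
#' Genes with `padj < alpha` per contrast, plus every pairwise/triple
#' intersection count (the Venn layout comparing each NAS group against the
#' NAS 0-1 reference).
#'
#' @param results Named list of `liversig_de` tibbles, one per contrast.
#' @param alpha FDR cut-off (default 0.05).
#' @return List with `sets` (named list of gene id vectors) and `overlaps`
#'   (tibble of contrast combinations and intersection sizes).
#' @export
deg_sets <- function(results, alpha = 0.05) {
  stopifnot(length(results) >= 1)
  universes <- lapply(results, function(r) sort(r$gene_id))
  if (length(results) > 1 &&
      !all(vapply(universes[-1], identical, logical(1), universes[[1]]))) {
    abort("DE results do not share a gene universe; cannot form DEG sets.")
  }
  sets <- lapply(results, function(r) r$gene_id[!is.na(r$padj) & r$padj < alpha])
  combos <- unlist(lapply(seq_along(sets), function(k) {
    utils::combn(names(sets), k, simplify = FALSE)
  }), recursive = FALSE)
  overlaps <- purrr::map_dfr(combos, function(cc) {
    tibble(contrasts = paste(cc, collapse = " & "),
           n = length(Reduce(intersect, sets[cc])))
  })
  list(sets = sets, overlaps = overlaps)
}

#' PCA on the most variable genes
#'
#' Counts are normalized by median-of-ratios size factors, transformed to
#' `log2(x + 1)`, the `n_top` genes with the largest variance are retained,
#' and sample coordinates are computed by SVD of the centered submatrix.
#' Component signs follow a fixed convention: the loading with the largest
#' magnitude on each component is made positive, so identical inputs give
#' identical (not sign-flipped) plots.
#'
#' @param cm A [count_matrix()].
#' @param n_top Number of top-variance genes (default 500).
#' @return A `liversig_pca` list: `coords` (tibble of sample_id, nas_group,
#'   PC columns), `var_explained` (fraction per component), `sdev`.
#' @export
pca_top_variable <- function(cm, n_top = 500) {
  if (ncol(cm$counts) < 2) abort("PCA needs at least two samples.")
  if (n_top > nrow(cm$counts)) {
    abort("`n_top` exceeds the number of genes in the matrix.")
  }
  sf <- size_factors(cm)
  lg <- log2(sweep(cm$counts, 2, sf, "/") + 1)
  v <- apply(lg, 1, var)
  top <- order(v, decreasing = TRUE)[seq_len(n_top)]
  x <- t(lg[top, , drop = FALSE])
  x <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(x)
  # sign convention: largest-magnitude loading positive per component
  for (k in seq_along(sv$d)) {
    j <- which.max(abs(sv$v[, k]))
    if (sv$v[j, k] < 0) {
      sv$v[, k] <- -sv$v[, k]
      sv$u[, k] <- -sv$u[, k]
    }
  }
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  coords <- dplyr::bind_cols(
    tibble(sample_id = colnames(cm$counts),
           nas_group = cm$samples$nas_group),
    as_tibble(scores))
  var_explained <- sv$d^2 / sum(sv$d^2)
  structure(list(coords = coords, var_explained = var_explained,
                 sdev = sv$d / sqrt(max(1, nrow(x) - 1))),
            class = "liversig_pca")
}

#' @export
print.liversig_pca <- function(x, ...) {
  cat("<liversig_pca> ", nrow(x$coords), " samples; PC1 ",
      sprintf("%.1f%%", 100 * x$var_explained[1]), ", PC2 ",
      sprintf("%.1f%%", 100 * x$var_explained[2]), " of variance\n", sep = "")
  invisible(x)
}
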