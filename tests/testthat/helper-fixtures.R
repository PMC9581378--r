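# Shared fixtures and independent oracles. Everything here is deliberately
# written as plain, literal code (loops, explicit formulas) so it stays an
# independent check on the vectorized implementations.

toy_cm <- function(counts, groups, genes = NULL) {
  if (is.null(genes)) genes <- sprintf("G%03d", seq_len(nrow(counts)))
  dimnames(counts) <- list(genes, sprintf("S%02d", seq_len(ncol(counts))))
  count_matrix(counts, data.frame(sample_id = colnames(counts),
                                  nas_group = groups))
}

# A config with nothing planted: pure null counts, flat atlas, empty lists.
null_config <- function(seed, n_genes = 2000, ...) {
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  sim_config(
    seed = seed, n_genes = n_genes,
    planted_deg = tibble::tibble(gene_id = character(), group = character(),
                                 log2fc = numeric()),
    planted_liver_selective = character(),
    secretome_membership = tibble::tibble(
      gene_id = gene_ids, hepatocyte_secretome = FALSE,
      blood_proteome = FALSE, predicted_secreted = FALSE),
    indirect_map = character(), ...)
}

# Literal BH step-up: sort, take running minima of m * p_(i) / i from the
# top rank down, clip at 1, undo the sort.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- ps * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Tie-corrected Kruskal-Wallis H from first principles.
kw_brute <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, sum)^2 / tapply(r, groups, length)) -
    3 * (n + 1)
  ties <- table(r)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Brute-force Dunn z for one comparison against a reference group.
dunn_brute <- function(values, groups, g, ref) {
  r <- rank(values)
  n <- length(values)
  ties <- table(r)
  v <- n * (n + 1) / 12 - sum(ties^3 - ties) / (12 * (n - 1))
  ni <- sum(groups == g); nr <- sum(groups == ref)
  (mean(r[groups == g]) - mean(r[groups == ref])) /
    sqrt(v * (1 / ni + 1 / nr))
}
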