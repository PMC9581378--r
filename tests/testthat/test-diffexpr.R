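test_that("size factors satisfy the median-of-ratios identities", {
  # identical columns -> all factors 1
  m <- matrix(c(10, 40, 200), 3, 4)
  cm <- toy_cm(m, rep(c("NAS0-1", "NAS4-6"), 2))
  expect_equal(unname(size_factors(cm)), rep(1, 4))
  # doubling one column splits symmetrically around the geometric mean
  m2 <- cbind(c(10, 40, 200), c(20, 80, 400))
  cm2 <- toy_cm(m2, c("NAS0-1", "NAS4-6"))
  expect_equal(unname(size_factors(cm2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
})

test_that("size factors match a brute-force oracle and DESeq2 on a fixture", {
  m <- matrix(c(12, 5, 120,
                30, 9, 240,
                18, 2, 500), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2", "s3")))
  cm <- count_matrix(m, data.frame(sample_id = c("s1", "s2", "s3"),
                                   nas_group = c("NAS0-1", "NAS0-1", "NAS4-6")))
  # literal median-of-ratios
  geo <- apply(m, 1, function(x) exp(mean(log(x))))
  brute <- apply(m / geo, 2, median)
  expect_equal(size_factors(cm), brute, tolerance = 1e-12)
  ds <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(size_factors(cm)), unname(ds), tolerance = 1e-8)
})

test_that("size factors are gene-order invariant and scale equivariant", {
  set.seed(1)
  m <- matrix(rpois(60, 50) + 1, 10, 6)
  groups <- rep(c("NAS0-1", "NAS4-6"), 3)
  cm <- toy_cm(m, groups)
  perm <- sample(nrow(m))
  cm_perm <- toy_cm(m[perm, ], groups)
  expect_equal(unname(size_factors(cm)), unname(size_factors(cm_perm)))
  # scaling one sample by c multiplies its factor by c relative to the rest
  # (an overall rescaling of the geometric-mean reference is unavoidable)
  m3 <- m
  m3[, 2] <- m3[, 2] * 3L
  f0 <- size_factors(cm)
  f3 <- size_factors(toy_cm(m3, groups))
  expect_equal(f3[[2]] / f3[[1]], 3 * f0[[2]] / f0[[1]], tolerance = 1e-12)
})

test_that("size factors refuse a matrix with no all-expressed gene", {
  m <- matrix(c(0, 5, 5, 0), 2, 2)
  expect_error(size_factors(toy_cm(m, c("NAS0-1", "NAS4-6"))),
               "no gene has nonzero counts")
})

test_that("dispersion estimates follow the moments formula", {
  # variance <= mean (here: constant counts) drives the estimate to the floor
  m <- matrix(c(rep(20L, 8), rpois(8, 50)), 2, 8, byrow = TRUE)
  cm <- toy_cm(m, rep(c("NAS0-1", "NAS4-6"), each = 4))
  d <- estimate_dispersion(cm, setNames(rep(1, 8), colnames(m)), prior_df = 0)
  expect_equal(d$dispersion[1], 1e-8)
  # hand-computed moments estimate on an 8-sample single-group vector
  x <- c(12, 30, 19, 45, 8, 22, 60, 17)
  cm2 <- toy_cm(rbind(x, x + 1), rep("NAS0-1", 8))
  d2 <- estimate_dispersion(cm2, setNames(rep(1, 8), sprintf("S%02d", 1:8)),
                            prior_df = 0)
  expect_equal(d2$dispersion[1], max(1e-8, (var(x) - mean(x)) / mean(x)^2),
               tolerance = 1e-12)
})

test_that("dispersion is consistent at large n and flags all-zero genes", {
  set.seed(7)
  n <- 500
  y <- rbind(matrix(rnbinom(2 * n, mu = 100, size = 1 / 0.5), 1),
             rep(0L, 2 * n))
  cm <- toy_cm(y, rep(c("NAS0-1", "NAS4-6"), each = n))
  sf <- setNames(rep(1, 2 * n), colnames(cm$counts))
  d <- estimate_dispersion(cm, sf, prior_df = 0)
  expect_gt(d$dispersion[1], 0.35)
  expect_lt(d$dispersion[1], 0.65)
  expect_true(d$excluded[2])
  expect_true(is.na(d$dispersion[2]))
})

test_that("Wald test is symmetric and antisymmetric where it must be", {
  set.seed(2)
  block <- matrix(rpois(40, 30), 10, 4)
  m <- cbind(block, block)  # both groups see identical data
  cm <- toy_cm(m, rep(c("NAS0-1", "NAS4-6"), each = 4))
  sf <- setNames(rep(1, 8), colnames(cm$counts))
  disp <- estimate_dispersion(cm, sf)
  de <- wald_test(cm, sf, disp, contrast = "NAS4-6")
  expect_equal(de$log2fc, rep(0, 10), tolerance = 1e-8)
  expect_equal(de$p, rep(1, 10), tolerance = 1e-6)
  expect_equal(de$wald_stat, de$log2fc / de$se)
  # swapping contrast and reference negates the fold change
  set.seed(3)
  m2 <- matrix(rnbinom(120, mu = 50, size = 20), 10, 12)
  cm2 <- toy_cm(m2, rep(c("NAS0-1", "NAS4-6"), each = 6))
  sf2 <- size_factors(cm2)
  disp2 <- estimate_dispersion(cm2, sf2)
  fwd <- wald_test(cm2, sf2, disp2, contrast = "NAS4-6", reference = "NAS0-1")
  rev <- wald_test(cm2, sf2, disp2, contrast = "NAS0-1", reference = "NAS4-6")
  expect_equal(fwd$log2fc, -rev$log2fc, tolerance = 1e-6)
  expect_equal(fwd$p, rev$p, tolerance = 1e-6)
})

test_that("Wald test refuses an absent contrast group", {
  m <- matrix(rpois(20, 30), 5, 4)
  cm <- toy_cm(m, rep(c("NAS0-1", "NAS2-3"), 2))
  sf <- setNames(rep(1, 4), colnames(cm$counts))
  expect_error(wald_test(cm, sf, estimate_dispersion(cm, sf),
                         contrast = "NAS4-6"),
               "NAS4-6")
})

test_that("planted log2FC = 2 genes reach padj < 0.05 in nearly all replicates", {
  detected <- 0L
  n_rep <- 100L
  for (i in seq_len(n_rep)) {
    cfg <- null_config(seed = 2000L + i, n_genes = 50,
                       group_sizes = c("NAS0-1" = 8, "NAS4-6" = 12),
                       dispersion = 0.05)
    cfg$planted_deg <- tibble::tibble(gene_id = "G0001", group = "NAS4-6",
                                      log2fc = 2)
    out <- simulate_counts(cfg)
    sf <- size_factors(out$data)
    de <- wald_test(out$data, sf, estimate_dispersion(out$data, sf),
                    contrast = "NAS4-6")
    if (de$padj[de$gene_id == "G0001"] < 0.05) detected <- detected + 1L
  }
  expect_gte(detected / n_rep, 0.95)
})

test_that("BH adjustment equals the literal step-up procedure", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.9)), c(0.03, 0.03, 0.9))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(11)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-12)
  }
  # padj >= p, order preserved
  p <- runif(100)
  padj <- bh_adjust(p)
  expect_true(all(padj >= p))
  expect_equal(order(padj[order(p)]), seq_along(p))
})

test_that("DEG sets and overlaps follow the FDR cut-off", {
  set.seed(4)
  cfg <- sim_config(seed = 21)
  out <- simulate_counts(cfg)
  sf <- size_factors(out$data)
  disp <- estimate_dispersion(out$data, sf)
  de <- list("NAS2-3" = wald_test(out$data, sf, disp, contrast = "NAS2-3"),
             "NAS4-6" = wald_test(out$data, sf, disp, contrast = "NAS4-6"))
  ds <- deg_sets(de, alpha = 0.05)
  # genes planted in both contrasts populate the intersection
  shared <- cfg$planted_deg$gene_id[duplicated(cfg$planted_deg$gene_id)]
  inter <- intersect(ds$sets[["NAS2-3"]], ds$sets[["NAS4-6"]])
  expect_gt(length(intersect(shared, inter)) / length(shared), 0.9)
  expect_equal(ds$overlaps$n[ds$overlaps$contrasts == "NAS2-3 & NAS4-6"],
               length(inter))
  # alpha = 1 puts every tested gene in every set
  ds_all <- deg_sets(de, alpha = 1)
  expect_equal(sort(ds_all$sets[["NAS2-3"]]), sort(de[["NAS2-3"]]$gene_id))
  # no gene passes at an absurd threshold
  ds_none <- deg_sets(de, alpha = 1e-300)
  expect_true(all(lengths(ds_none$sets) == 0))
  # mismatched universes are refused
  de_bad <- de
  de_bad[["NAS4-6"]] <- de_bad[["NAS4-6"]][-1, ]
  expect_error(deg_sets(de_bad), "universe")
})

test_that("PCA coordinates respect duplication, variance and separation", {
  set.seed(5)
  m <- matrix(rpois(300, 40), 30, 10)
  m[, 10] <- m[, 9]  # duplicated sample
  cm <- toy_cm(m, rep(c("NAS0-1", "NAS4-6"), each = 5))
  pca <- pca_top_variable(cm, n_top = 20)
  expect_equal(unlist(pca$coords[9, -(1:2)]), unlist(pca$coords[10, -(1:2)]),
               tolerance = 1e-10)
  # component variances sum to the total variance of the log submatrix
  sf <- size_factors(cm)
  lg <- log2(sweep(cm$counts, 2, sf, "/") + 1)
  v <- apply(lg, 1, var)
  top <- order(v, decreasing = TRUE)[1:20]
  total_var <- sum(apply(t(lg[top, ]), 2, var))
  expect_equal(sum(pca$sdev^2), total_var, tolerance = 1e-10)
  expect_equal(sum(pca$var_explained), 1)
})

test_that("strongly separated groups give silhouette > 0.5 on PC1-2", {
  cfg <- null_config(seed = 8, n_genes = 500,
                     group_sizes = c("NAS0-1" = 8, "NAS4-6" = 8))
  cfg$planted_deg <- tibble::tibble(
    gene_id = sprintf("G%04d", 1:100), group = "NAS4-6",
    log2fc = rep(c(2, -2), 50))
  out <- simulate_counts(cfg)
  pca <- pca_top_variable(out$data, n_top = 200)
  d <- dist(as.matrix(pca$coords[, c("PC1", "PC2")]))
  sil <- cluster::silhouette(as.integer(factor(pca$coords$nas_group)), d)
  expect_gt(mean(sil[, "sil_width"]), 0.5)
})

test_that("PCA refuses n_top larger than the gene universe", {
  m <- matrix(rpois(40, 30), 10, 4)
  cm <- toy_cm(m, rep(c("NAS0-1", "NAS4-6"), 2))
  expect_error(pca_top_variable(cm, n_top = 50), "exceeds")
})
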