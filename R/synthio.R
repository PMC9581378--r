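#' Configuration for the synthetic study generator
#'
#' Builds the full parameterization of a synthetic NAFLD discovery study:
#' NB-distributed liver RNA-seq counts per NAS severity group with planted
#' fold changes, a cross-tissue expression atlas with planted liver-selective
#' genes, three secretion-evidence gene lists with planted membership, and a
#' clinical/plasma cohort sheet with a requested Spearman correlation
#' structure. Defaults mirror the discovery study's shape: 26 participants
#' split 8/12/6 across NAS 0-1 / 2-3 / 4-6, 2000 genes, a 33-tissue atlas,
#' and four planted candidate genes — three secreted and one whose product is
#' only measurable through its circulating metabolite.
#'
#' @param seed Integer seed; all generators are pure functions of the config
#'   (identical config, identical output).
#' @param n_genes Number of simulated genes.
#' @param group_sizes Named integer vector of samples per NAS group.
#' @param baseline_mean_log_range Bounds (log scale) for gene baseline means.
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2); scalar
#'   or per-gene vector.
#' @param planted_deg Tibble `gene_id`, `group`, `log2fc` of planted effects
#'   relative to the NAS 0-1 reference; `NULL` installs the default scenario
#'   (4 candidate genes at log2fc -2 in both higher-NAS groups, mirroring the
#'   robust downregulation of the discovered biomarkers, plus 40 planted DEGs
#'   that fail the selectivity or secretion filters).
#' @param n_tissues Number of atlas tissues, liver included (>= 3).
#' @param planted_liver_selective Gene ids planted as liver-selective; `NULL`
#'   installs the 4 candidates plus 10 liver-selective non-DE genes.
#' @param atlas_background_tpm Non-liver TPM of planted selective genes.
#' @param atlas_liver_tpm Liver TPM of planted selective genes.
#' @param atlas_noise_sd Log-normal noise sd on atlas TPM values.
#' @param secretome_membership Tibble `gene_id`, `hepatocyte_secretome`,
#'   `blood_proteome`, `predicted_secreted`; `NULL` installs the default
#'   scenario (candidates 1-3 in one list each, candidate 4 in none, a
#'   scattering of background genes so the lists are non-trivial).
#' @param indirect_map Named character vector gene -> metabolite for
#'   non-secreted candidates (default: the 4th candidate maps to
#'   S-adenosylmethionine, the MAT1A-style indirect marker).
#' @param clinical_rank_correlations Tibble `var1`, `var2`, `rho` of target
#'   Spearman correlations among cohort covariates (Gaussian copula).
#' @param group_shifts Named list: covariate -> per-group shift (latent sd
#'   units) planting severity trends (liver stiffness, transaminases,
#'   C-peptide rise with NAS by default).
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       group_sizes = c("NAS0-1" = 8L, "NAS2-3" = 12L,
                                       "NAS4-6" = 6L),
                       baseline_mean_log_range = log(c(10, 1000)),
                       dispersion = 0.05,
                       planted_deg = NULL,
                       n_tissues = 33L,
                       planted_liver_selective = NULL,
                       atlas_background_tpm = 1,
                       atlas_liver_tpm = 500,
                       atlas_noise_sd = 0.1,
                       secretome_membership = NULL,
                       indirect_map = NULL,
                       clinical_rank_correlations = NULL,
                       group_shifts = NULL) {
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  if (is.null(planted_deg)) planted_deg <- default_planted_deg(gene_ids)
  if (is.null(planted_liver_selective)) {
    planted_liver_selective <- default_selective(gene_ids)
  }
  if (is.null(secretome_membership)) {
    secretome_membership <- default_secretome(gene_ids)
  }
  if (is.null(indirect_map)) {
    indirect_map <- c(G0004 = "S-adenosylmethionine")
    indirect_map <- indirect_map[names(indirect_map) %in% gene_ids]
  }
  if (is.null(clinical_rank_correlations)) {
    clinical_rank_correlations <- default_clinical_correlations()
  }
  if (is.null(group_shifts)) {
    group_shifts <- list(
      te_kpa = c("NAS0-1" = 0, "NAS2-3" = 0.6, "NAS4-6" = 1.4),
      alt = c("NAS0-1" = 0, "NAS2-3" = 0.8, "NAS4-6" = 1.6),
      cpeptide = c("NAS0-1" = 0, "NAS2-3" = 0.7, "NAS4-6" = 1.3))
  }
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              gene_ids = gene_ids, group_sizes = group_sizes,
              baseline_mean_log_range = baseline_mean_log_range,
              dispersion = dispersion, planted_deg = as_tibble(planted_deg),
              n_tissues = as.integer(n_tissues),
              planted_liver_selective = planted_liver_selective,
              atlas_background_tpm = atlas_background_tpm,
              atlas_liver_tpm = atlas_liver_tpm,
              atlas_noise_sd = atlas_noise_sd,
              secretome_membership = as_tibble(secretome_membership),
              indirect_map = indirect_map,
              clinical_rank_correlations = as_tibble(clinical_rank_correlations),
              group_shifts = group_shifts)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  small <- cfg$group_sizes < 2
  if (any(small)) {
    abort(paste0("Differential expression needs replication: group(s) ",
                 paste(names(cfg$group_sizes)[small], collapse = ", "),
                 " have fewer than 2 samples."))
  }
  if (any(cfg$dispersion <= 0)) abort("Dispersion must be strictly positive.")
  planted <- unique(c(cfg$planted_deg$gene_id, cfg$planted_liver_selective,
                      cfg$secretome_membership$gene_id,
                      names(cfg$indirect_map)))
  outside <- setdiff(planted, cfg$gene_ids)
  if (length(outside) > 0) {
    abort(paste0("Planted gene id(s) outside the simulated universe: ",
                 paste(head(outside, 5), collapse = ", ")))
  }
  bad_groups <- setdiff(unique(cfg$planted_deg$group), names(cfg$group_sizes))
  if (length(bad_groups) > 0) {
    abort(paste0("Planted effects reference unknown group(s): ",
                 paste(bad_groups, collapse = ", ")))
  }
  if (any(abs(cfg$clinical_rank_correlations$rho) > 1)) {
    abort("Target Spearman correlations must lie in [-1, 1].")
  }
  invisible(cfg)
}

default_planted_deg <- function(gene_ids) {
  cand <- gene_ids[1:4]
  both <- gene_ids[5:24]
  only23 <- gene_ids[25:34]
  only46 <- gene_ids[35:44]
  dplyr::bind_rows(
    tidyr::expand_grid(gene_id = cand, group = c("NAS2-3", "NAS4-6")) |>
      dplyr::mutate(log2fc = -2),
    tidyr::expand_grid(gene_id = both, group = c("NAS2-3", "NAS4-6")) |>
      dplyr::mutate(log2fc = rep(c(1.5, -1.5), length.out = 2 * length(both))),
    tibble(gene_id = only23, group = "NAS2-3", log2fc = 1.5),
    tibble(gene_id = only46, group = "NAS4-6", log2fc = -1.5))
}

default_selective <- function(gene_ids) gene_ids[c(1:4, 45:54)]

default_secretome <- function(gene_ids) {
  n <- length(gene_ids)
  # candidates 1-3 carry one evidence source each; candidate 4 none;
  # planted non-selective DEGs 5-24 are blood-detected so the secreted-DEG
  # filter is non-trivial; a deterministic comb of background genes fills
  # the lists out.
  bg <- gene_ids[seq(100, n, by = 12)]
  thirds <- split(bg, rep_len(1:3, length(bg)))
  tibble(gene_id = gene_ids) |>
    dplyr::mutate(
      hepatocyte_secretome = .data$gene_id %in% c(gene_ids[1], thirds[[1]]),
      blood_proteome = .data$gene_id %in%
        c(gene_ids[2], gene_ids[5:24], thirds[[2]]),
      predicted_secreted = .data$gene_id %in% c(gene_ids[3], thirds[[3]]))
}

default_clinical_correlations <- function() {
  tibble(
    var1 = c("age", "cpeptide", "bmi", "fat_kg", "bmi", "weight_kg", "weight_kg"),
    var2 = c("plasma_igfbp1", "plasma_igfbp1", "plasma_sam", "plasma_sam",
             "fat_kg", "bmi", "fat_kg"),
    rho = c(0.47, -0.48, 0.51, 0.56, 0.60, 0.50, 0.50))
}

#' Simulate a liver RNA-seq count matrix with planted fold changes
#'
#' Counts are drawn gene-wise from a negative binomial with variance
#' \eqn{\mu + \alpha \mu^2}: group means are the gene's baseline (log-uniform
#' across `baseline_mean_log_range`) times `2^log2fc` for planted effects,
#' scaled by per-sample library size factors drawn log-uniform in
#' \[0.7, 1.4\] so normalization is exercised non-trivially.
#'
#' @param config A [sim_config()].
#' @return List: `data` (a [count_matrix()]), `truth` (tibble of every
#'   planted effect: `gene_id`, `group`, `log2fc`, `sign`), `size_factors`
#'   (the true per-sample scaling used).
#' @export
simulate_counts <- function(config) {
  validate_sim_config(config)
  gs <- config$group_sizes
  n_samp <- sum(gs)
  groups <- rep(names(gs), gs)
  withr::with_seed(config$seed, {
    base <- exp(runif(config$n_genes, config$baseline_mean_log_range[1],
                      config$baseline_mean_log_range[2]))
    sf <- exp(runif(n_samp, log(0.7), log(1.4)))
    lfc <- matrix(0, config$n_genes, n_samp,
                  dimnames = list(config$gene_ids, NULL))
    if (nrow(config$planted_deg) > 0) {
      for (i in seq_len(nrow(config$planted_deg))) {
        row <- config$planted_deg[i, ]
        lfc[row$gene_id, groups == row$group] <- row$log2fc
      }
    }
    mu <- (base * 2^lfc) %*% diag(sf)
    alpha <- rep_len(config$dispersion, config$n_genes)
    counts <- matrix(
      rnbinom(length(mu), mu = as.vector(mu),
              size = rep(1 / alpha, times = n_samp)),
      nrow = config$n_genes,
      dimnames = list(config$gene_ids,
                      sprintf("S%02d", seq_len(n_samp))))
  })
  samples <- tibble(sample_id = colnames(counts), nas_group = groups)
  truth <- dplyr::mutate(config$planted_deg, sign = sign(.data$log2fc))
  list(data = count_matrix(counts, samples), truth = truth,
       size_factors = sf)
}

atlas_tissue_names <- function(n) {
  pool <- c("liver", "brain", "heart", "kidney", "lung", "pancreas", "spleen",
            "stomach", "colon", "duodenum", "small_intestine", "esophagus",
            "gallbladder", "adipose", "skeletal_muscle", "smooth_muscle",
            "skin", "adrenal_gland", "thyroid", "parathyroid", "pituitary",
            "salivary_gland", "tonsil", "lymph_node", "bone_marrow",
            "appendix", "urinary_bladder", "testis", "ovary", "prostate",
            "endometrium", "placenta", "breast", "fallopian_tube", "cervix",
            "seminal_vesicle", "epididymis", "retina", "cerebellum")
  if (n <= length(pool)) return(pool[seq_len(n)])
  c(pool, sprintf("tissue_%02d", seq_len(n - length(pool))))
}

#' Simulate a cross-tissue expression atlas with planted liver-selective genes
#'
#' Planted genes get `atlas_liver_tpm` in the liver column and
#' `atlas_background_tpm` elsewhere; all other genes get a per-gene baseline
#' TPM shared across tissues. Every value carries multiplicative log-normal
#' noise of sd `atlas_noise_sd` (a zero background stays exactly zero).
#'
#' @param config A [sim_config()].
#' @return List: `atlas` (tibble, `gene_id` plus one TPM column per tissue,
#'   including `liver`), `truth` (planted liver-selective gene ids).
#' @export
simulate_atlas <- function(config) {
  validate_sim_config(config)
  if (config$n_tissues < 3) {
    abort("At least 3 tissues are required; cross-tissue CV is meaningless below that.")
  }
  if (config$atlas_liver_tpm <= config$atlas_background_tpm) {
    abort("atlas_liver_tpm must exceed atlas_background_tpm.")
  }
  tissues <- atlas_tissue_names(config$n_tissues)
  n <- config$n_genes
  withr::with_seed(config$seed + 1L, {
    base <- exp(rnorm(n, log(20), 1))
    tpm <- base * matrix(exp(rnorm(n * config$n_tissues, 0,
                                   config$atlas_noise_sd)),
                         n, config$n_tissues)
    sel <- config$gene_ids %in% config$planted_liver_selective
    if (any(sel)) {
      noise <- matrix(exp(rnorm(sum(sel) * config$n_tissues, 0,
                                config$atlas_noise_sd)),
                      sum(sel), config$n_tissues)
      block <- matrix(config$atlas_background_tpm, sum(sel),
                      config$n_tissues)
      block[, tissues == "liver"] <- config$atlas_liver_tpm
      tpm[sel, ] <- block * noise
    }
  })
  colnames(tpm) <- tissues
  atlas <- dplyr::bind_cols(tibble(gene_id = config$gene_ids), as_tibble(tpm))
  list(atlas = atlas, truth = config$gene_ids[sel])
}

#' Materialize the three secretion-evidence gene lists
#'
#' Converts the planted membership table into the three plain gene lists the
#' selection stage consumes (hepatocyte secretome, blood proteome detection,
#' predicted secreted). The union of the lists is exactly the planted
#' "secreted" truth set.
#'
#' @param config A [sim_config()].
#' @return List of three character vectors: `hepatocyte`, `blood`,
#'   `predicted`, plus `truth` (the union).
#' @export
simulate_secretome_lists <- function(config) {
  validate_sim_config(config)
  m <- config$secretome_membership
  lists <- list(hepatocyte = m$gene_id[m$hepatocyte_secretome],
                blood = m$gene_id[m$blood_proteome],
                predicted = m$gene_id[m$predicted_secreted])
  lists$truth <- sort(unique(unlist(lists)))
  lists
}

cohort_marginals <- function() {
  list(
    age = function(u) qnorm(u, 48, 9),
    weight_kg = function(u) qnorm(u, 145, 15),
    bmi = function(u) qnorm(u, 47, 5),
    fat_kg = function(u) stats::qlnorm(u, log(70), 0.15),
    bone_kg = function(u) qnorm(u, 3.5, 0.4),
    cpeptide = function(u) stats::qlnorm(u, log(900), 0.4),
    alt = function(u) stats::qlnorm(u, log(35), 0.4),
    te_kpa = function(u) stats::qlnorm(u, log(8), 0.4),
    fib4 = function(u) stats::qlnorm(u, log(0.6), 0.35),
    nfs = function(u) qnorm(u, -1, 0.8),
    plasma_lpa = function(u) stats::qlnorm(u, log(100), 0.6),
    plasma_igfbp1 = function(u) stats::qlnorm(u, log(30), 0.5),
    plasma_a2ap = function(u) qnorm(u, 100, 15),
    plasma_sam = function(u) stats::qlnorm(u, log(120), 0.3))
}

# Factor a correlation matrix allowing the comonotone boundary (eigenvalue 0).
copula_factor <- function(R, pairs) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < -1e-8) {
    worst <- pairs[which.max(abs(pairs$rho)), ]
    abort(paste0(
      "Requested rank-correlation structure is not positive semi-definite ",
      "after copula conversion; most extreme pair: ", worst$var1, " ~ ",
      worst$var2, " (rho = ", worst$rho, ")."))
  }
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(R))
}

#' Simulate the clinical cohort sheet and plasma analyte table
#'
#' Per-participant histology sub-scores are drawn consistently with the
#' participant's NAS group (total NAS uniform within the group's range, split
#' into steatosis/inflammation/ballooning with steatosis-weighted
#' compositions, matching steatosis being the dominant driver of grouping);
#' fibrosis stages follow group-specific frequencies, stage-1 biopsies
#' carrying a random 1a/1b/1c sub-label. Continuous covariates are drawn
#' through a Gaussian copula hitting the requested Spearman structure, with
#' planted severity shifts on liver stiffness, ALT and C-peptide.
#'
#' @param config A [sim_config()].
#' @return List: `sheet` (tibble, one row per participant) and `plasma`
#'   (long tibble `participant_id`, `analyte`, `value`).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  gs <- config$group_sizes
  groups <- rep(names(gs), gs)
  n <- length(groups)
  marg <- cohort_marginals()
  vars <- names(marg)
  pairs <- config$clinical_rank_correlations
  bad_vars <- setdiff(unique(c(pairs$var1, pairs$var2)), vars)
  if (length(bad_vars) > 0) {
    abort(paste0("Unknown covariate(s) in correlation targets: ",
                 paste(bad_vars, collapse = ", ")))
  }
  R <- diag(length(vars))
  dimnames(R) <- list(vars, vars)
  for (i in seq_len(nrow(pairs))) {
    r <- 2 * sin(pi * pairs$rho[i] / 6)   # Spearman -> Pearson on the copula
    R[pairs$var1[i], pairs$var2[i]] <- r
    R[pairs$var2[i], pairs$var1[i]] <- r
  }
  A <- copula_factor(R, pairs)
  group_ranges <- list("NAS0-1" = 0:1, "NAS2-3" = 2:3, "NAS4-6" = 4:6)
  fib_probs <- list("NAS0-1" = c(1, 0, 0, 0, 0),
                    "NAS2-3" = c(0.75, 0.25, 0, 0, 0),
                    "NAS4-6" = c(1, 2, 2, 1, 0) / 6)
  withr::with_seed(config$seed + 2L, {
    z <- matrix(rnorm(n * length(vars)), n) %*% t(A)
    colnames(z) <- vars
    for (v in names(config$group_shifts)) {
      z[, v] <- z[, v] + config$group_shifts[[v]][groups]
    }
    covars <- purrr::imap_dfc(marg, function(f, v) {
      tibble("{v}" := f(pnorm(z[, v])))
    })
    histo <- purrr::map_dfr(groups, function(g) {
      rng <- group_ranges[[g]]
      if (is.null(rng)) abort(paste0("No NAS range defined for group ", g))
      total <- if (length(rng) == 1) rng else sample(rng, 1)
      triples <- expand.grid(steatosis = 0:3, lobular_inflammation = 0:3,
                             ballooning = 0:2)
      triples <- triples[rowSums(triples) == total, , drop = FALSE]
      w <- (triples$steatosis + 1)^2
      triples[sample(nrow(triples), 1, prob = w), ]
    })
    fib <- vapply(groups, function(g) {
      stage <- sample(0:4, 1, prob = fib_probs[[g]])
      if (stage == 1) sample(c("1a", "1b", "1c"), 1) else as.character(stage)
    }, character(1))
  })
  sheet <- dplyr::bind_cols(
    tibble(participant_id = sprintf("P%02d", seq_len(n))),
    as_tibble(histo), covars) |>
    dplyr::mutate(
      fibrosis_stage_label = fib,
      fibrosis_stage = collapse_fibrosis(fib),
      nas_total = .data$steatosis + .data$lobular_inflammation +
        .data$ballooning,
      nas_group = nas_group(.data$nas_total),
      nash = nash_classify(.data$steatosis, .data$lobular_inflammation,
                           .data$ballooning))
  plasma <- sheet |>
    dplyr::select("participant_id", dplyr::starts_with("plasma_")) |>
    tidyr::pivot_longer(-"participant_id", names_to = "analyte",
                        values_to = "value") |>
    dplyr::mutate(analyte = sub("^plasma_", "", .data$analyte))
  list(sheet = sheet, plasma = plasma)
}

#' Generate the complete synthetic study bundle
#'
#' Runs all four generators under one config and returns every input the
#' discovery pipeline consumes, together with the planted truth tables.
#'
#' @param config A [sim_config()].
#' @return List: `counts` (with `$data`, `$truth`), `atlas`, `lists`,
#'   `cohort`, `indirect_map`.
#' @export
simulate_study <- function(config = sim_config()) {
  list(counts = simulate_counts(config),
       atlas = simulate_atlas(config),
       lists = simulate_secretome_lists(config),
       cohort = simulate_cohort(config),
       indirect_map = config$indirect_map)
}
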