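#' Collapse fibrosis sub-stages
#'
#' Kleiner/CRN staging splits stage 1 into 1a/1b/1c; for group comparisons the
#' sub-stages are collapsed to a single F1.
#'
#' @param stage Character (or integer) vector with values among
#'   `0, 1a, 1b, 1c, 1, 2, 3, 4`.
#' @return Integer vector of stages 0-4.
#' @export
collapse_fibrosis <- function(stage) {
  stage <- as.character(stage)
  allowed <- c("0", "1a", "1b", "1c", "1", "2", "3", "4")
  bad <- setdiff(unique(stage[!is.na(stage)]), allowed)
  if (length(bad) > 0) {
    abort(paste0("Unknown fibrosis stage label(s): ",
                 paste(bad, collapse = ", ")))
  }
  out <- ifelse(stage %in% c("1a", "1b", "1c"), "1", stage)
  as.integer(out)
}

#' NAS severity group label
#'
#' Participants are grouped by total NAFLD activity score: 0-1 (no/mild),
#' 2-3 (moderate), 4-6 (more advanced). Totals of 7-8, although arithmetically
#' possible, fall outside the defined grouping and raise an error rather than
#' being silently binned.
#'
#' @param nas_total Integer vector, each value in 0-8.
#' @return Character vector of labels `NAS0-1`, `NAS2-3`, `NAS4-6`.
#' @export
nas_group <- function(nas_total) {
  if (any(nas_total < 0 | nas_total > 8 | nas_total != round(nas_total),
          na.rm = TRUE)) {
    abort("NAS totals must be integers in 0-8.")
  }
  if (any(nas_total >= 7, na.rm = TRUE)) {
    abort(paste0("NAS total of 7-8 is outside the defined severity groups ",
                 "(0-1, 2-3, 4-6)."))
  }
  dplyr::case_when(nas_total <= 1 ~ "NAS0-1",
                   nas_total <= 3 ~ "NAS2-3",
                   TRUE ~ "NAS4-6")
}

#' Histological NASH classification
#'
#' NASH requires the joint presence of steatosis, hepatocellular ballooning
#' and lobular inflammation (each sub-score at least 1), with or without
#' fibrosis.
#'
#' @param steatosis Integer 0-3.
#' @param inflammation Lobular inflammation, integer 0-3.
#' @param ballooning Integer 0-2.
#' @return Logical vector.
#' @export
nash_classify <- function(steatosis, inflammation, ballooning) {
  if (any(steatosis < 0 | steatosis > 3 | inflammation < 0 | inflammation > 3 |
          ballooning < 0 | ballooning > 2, na.rm = TRUE)) {
    abort("Histology sub-scores out of range (steatosis 0-3, inflammation 0-3, ballooning 0-2).")
  }
  steatosis >= 1 & ballooning >= 1 & inflammation >= 1
}

#' Fibrosis-risk eligibility screen
#'
#' Inclusion requires evidence of potential NASH with fibrosis on at least one
#' of three non-invasive scores: FIB-4 >= 1.30, NAFLD fibrosis score >=
#' -1.455, or transient elastography >= 7.0 kPa (all inclusive). The score
#' formulas themselves are upstream inputs.
#'
#' @param fib4,nfs,te_kpa Numeric vectors (NA = not measured).
#' @return Logical vector; errors if a participant has all three missing.
#' @export
eligibility <- function(fib4, nfs, te_kpa) {
  all_missing <- is.na(fib4) & is.na(nfs) & is.na(te_kpa)
  if (any(all_missing)) {
    abort("Eligibility undecidable: participant(s) with all three scores missing.")
  }
  (fib4 >= 1.30 & !is.na(fib4)) |
    (nfs >= -1.455 & !is.na(nfs)) |
    (te_kpa >= 7.0 & !is.na(te_kpa))
}

#' DXA-derived body composition
#'
#' Lean body mass is total weight minus fat and bone mass; fat percentage is
#' fat mass over total weight.
#'
#' @param weight_kg,fat_kg,bone_kg Numeric vectors in kilograms.
#' @return Tibble `lean_kg`, `fat_pct`.
#' @export
body_composition <- function(weight_kg, fat_kg, bone_kg) {
  if (any(weight_kg <= 0, na.rm = TRUE)) abort("Body weight must be positive.")
  if (any(fat_kg + bone_kg > weight_kg, na.rm = TRUE)) {
    abort("Inconsistent masses: fat + bone exceeds total body weight.")
  }
  tibble(lean_kg = weight_kg - fat_kg - bone_kg,
         fat_pct = 100 * fat_kg / weight_kg)
}

#' Kruskal-Wallis rank test
#'
#' One-way nonparametric comparison of two or more groups with midranks for
#' ties and the standard tie correction; p from the chi-square approximation
#' with k - 1 degrees of freedom. A thin validating wrapper around
#' [stats::kruskal.test()].
#'
#' @param values Numeric vector of observations.
#' @param groups Group label per observation (or pass a list of numeric
#'   vectors as `values` and omit `groups`).
#' @return Tibble `statistic` (H), `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups = NULL) {
  if (is.list(values) && is.null(groups)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) abort("At least two non-empty groups required.")
  if (length(unique(values)) == 1) {
    abort("All observations identical; the tie-corrected H statistic is degenerate.")
  }
  kt <- stats::kruskal.test(values, groups)
  tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p = kt$p.value)
}

# Midranks, tie-corrected rank variance and group mean ranks shared by the
# Dunn z computation.
rank_setup <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  v <- n * (n + 1) / 12 - tie_term / (12 * (n - 1))
  list(mean_ranks = tapply(r, groups, mean),
       sizes = tapply(r, groups, length), var = v)
}

#' Dunn's post hoc comparisons against a reference group
#'
#' After a Kruskal-Wallis test, each non-reference group's mean rank is
#' compared with the reference group's using the tie-corrected rank variance;
#' two-sided normal p-values are Benjamini-Hochberg adjusted across the
#' reference comparisons only (the study design compares every group against
#' NAS 0-1, not all pairs).
#'
#' @inheritParams kruskal_wallis
#' @param reference Reference group label.
#' @return Tibble `comparison`, `z`, `p`, `padj`.
#' @export
dunn_posthoc <- function(values, groups, reference) {
  groups <- as.character(groups)
  if (!reference %in% groups) {
    abort(paste0("Reference group not present: ", reference))
  }
  rs <- rank_setup(values, groups)
  others <- setdiff(names(rs$mean_ranks), reference)
  z <- vapply(others, function(g) {
    (rs$mean_ranks[[g]] - rs$mean_ranks[[reference]]) /
      sqrt(rs$var * (1 / rs$sizes[[g]] + 1 / rs$sizes[[reference]]))
  }, numeric(1))
  p <- 2 * pnorm(-abs(z))
  tibble(comparison = paste(others, "vs", reference),
         z = unname(z), p = unname(p), padj = bh_adjust(unname(p)))
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks, with a two-sided p-value from the
#' t approximation on n - 2 degrees of freedom. For small samples
#' (`exact = TRUE`, n <= 9) an exact permutation p-value is computed by full
#' enumeration instead.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @param exact Use full-enumeration permutation p (n <= 9 only).
#' @return Tibble `rho`, `p`, `n`.
#' @export
spearman <- function(x, y, exact = FALSE) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4 || length(y) != n) abort("Need equal-length vectors with n >= 4.")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    abort("Spearman correlation undefined for a constant vector.")
  }
  rho <- cor(rank(x), rank(y))
  if (exact) {
    if (n > 9) abort("Exact permutation p only supported for n <= 9.")
    rx <- rank(x); ry <- rank(y)
    perms <- permutations_of(n)
    null_rho <- apply(perms, 1, function(idx) cor(rx, ry[idx]))
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  tibble(rho = rho, p = min(p, 1), n = n)
}

# All n! permutations of 1..n as rows (n <= 9).
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[row:(row + nrow(sub) - 1L), ] <- cbind(k, matrix(rest[sub], nrow(sub)))
    row <- row + nrow(sub)
  }
  out
}

#' Cohort summary tables
#'
#' Per-group medians with interquartile range (linear-interpolation quantiles)
#' and a Kruskal-Wallis p-value for each continuous variable, plus frequency
#' rows (counts per grade per group) for the histology grades — the layout of
#' a clinical characteristics table and its companion frequency table.
#'
#' @param sheet Cohort data frame with a `nas_group` column.
#' @param continuous Character vector of continuous variable names to
#'   summarize; defaults to all numeric columns except histology grades.
#' @param grades Character vector of ordinal columns for the frequency table.
#' @return List with `continuous` (tibble: variable, group, median, q1, q3,
#'   n, plus per-variable KW `p`) and `frequencies` (tibble: variable, grade,
#'   group, count).
#' @export
summarize_cohort <- function(sheet,
                             continuous = NULL,
                             grades = c("steatosis", "lobular_inflammation",
                                        "ballooning", "nas_total",
                                        "fibrosis_stage", "nash")) {
  sheet <- as_tibble(sheet)
  if (!"nas_group" %in% names(sheet)) abort("Cohort sheet needs a `nas_group` column.")
  grades <- intersect(grades, names(sheet))
  if (is.null(continuous)) {
    continuous <- setdiff(names(sheet)[vapply(sheet, is.numeric, logical(1))],
                          c(grades, "participant_id"))
  }
  cont_rows <- purrr::map(continuous, function(v) {
    x <- sheet[[v]]
    if (all(is.na(x))) {
      warn(paste0("Variable ", v, " has no non-missing values; skipped."))
      return(NULL)
    }
    per_group <- sheet |>
      dplyr::filter(!is.na(.data[[v]])) |>
      dplyr::group_by(.data$nas_group) |>
      dplyr::summarise(
        median = median(.data[[v]]),
        q1 = quantile(.data[[v]], 0.25, names = FALSE),
        q3 = quantile(.data[[v]], 0.75, names = FALSE),
        n = dplyr::n(), .groups = "drop")
    ok <- !is.na(x)
    p <- tryCatch(
      kruskal_wallis(x[ok], sheet$nas_group[ok])$p,
      error = function(e) NA_real_)
    dplyr::mutate(per_group, variable = v, p = p)
  })
  cont <- dplyr::bind_rows(cont_rows) |>
    dplyr::relocate("variable")
  empty_freq <- tibble(variable = character(), grade = character(),
                       group = character(), count = integer())
  freq <- purrr::map_dfr(grades, function(v) {
    sheet |>
      dplyr::count(grade = as.character(.data[[v]]), .data$nas_group,
                   name = "count") |>
      dplyr::mutate(variable = v) |>
      dplyr::rename(group = "nas_group")
  })
  freq <- if (nrow(freq) == 0) empty_freq else
    dplyr::relocate(freq, "variable", "grade", "group", "count")
  list(continuous = cont, frequencies = freq)
}

#' Count participants matching a predicate
#'
#' Counts either rows of a cohort sheet satisfying a predicate over its
#' columns, or — when given a long frequency table (`variable`, `grade`,
#' `group`, `count` columns) — sums the counts of the rows matching a
#' predicate over `variable`, `grade` and `group`. This is how printed
#' frequency tables are interrogated (e.g. participants with fibrosis stage
#' >= 1, or with a NASH diagnosis).
#'
#' @param data A cohort sheet or frequency tibble.
#' @param predicate Unquoted logical expression over the columns.
#' @return Integer count.
#' @examples
#' freq <- histology_frequencies()
#' filter_count(freq, variable == "fibrosis_stage" & as.integer(grade) >= 1)
#' @export
filter_count <- function(data, predicate) {
  q <- enquo(predicate)
  vars <- all.vars(rlang::get_expr(q))
  unknown <- setdiff(vars, c(names(data), ls(baseenv())))
  unknown <- unknown[!vapply(unknown, function(v)
    exists(v, envir = rlang::quo_get_env(q)), logical(1))]
  if (length(unknown) > 0) {
    abort(paste0("Predicate references unknown column(s): ",
                 paste(unknown, collapse = ", ")))
  }
  if (nrow(data) == 0) return(0L)
  keep <- rlang::eval_tidy(q, data = data)
  keep[is.na(keep)] <- FALSE
  if ("count" %in% names(data)) {
    as.integer(sum(data$count[keep]))
  } else {
    as.integer(sum(keep))
  }
}
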