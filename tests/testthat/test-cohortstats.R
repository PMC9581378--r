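test_that("fibrosis sub-stages collapse to F1 and others pass through", {
  expect_equal(collapse_fibrosis(c("1a", "1b", "1c")), c(1L, 1L, 1L))
  expect_equal(collapse_fibrosis(c("0", "1", "2", "3", "4")), 0:4)
  expect_error(collapse_fibrosis("5"), "Unknown fibrosis stage")
})

test_that("NAS grouping covers 0-6 and refuses 7-8", {
  expect_equal(nas_group(c(0, 1)), c("NAS0-1", "NAS0-1"))
  expect_equal(nas_group(c(2, 3)), c("NAS2-3", "NAS2-3"))
  expect_equal(nas_group(c(4, 5, 6)), rep("NAS4-6", 3))
  expect_error(nas_group(7), "outside the defined severity groups")
  expect_error(nas_group(8), "outside the defined severity groups")
  expect_error(nas_group(-1), "0-8")
})

test_that("NASH requires all three histological components", {
  expect_true(nash_classify(2, 1, 1))
  expect_false(nash_classify(0, 1, 1))  # no steatosis
  expect_false(nash_classify(1, 1, 0))  # no ballooning
  expect_false(nash_classify(1, 0, 1))  # no inflammation
  expect_error(nash_classify(4, 0, 0), "out of range")
})

test_that("eligibility is an inclusive any-of-three rule", {
  expect_true(eligibility(1.40, -2.0, 5.0))   # FIB-4 arm
  expect_false(eligibility(1.0, -2.0, 6.9))   # all below
  expect_true(eligibility(1.0, -2.0, 7.0))    # boundary is inclusive
  expect_true(eligibility(1.30, NA, NA))
  expect_true(eligibility(NA, -1.455, NA))
  expect_false(eligibility(1.29, -1.456, 6.99))
  expect_error(eligibility(NA, NA, NA), "missing")
})

test_that("body composition arithmetic and guards", {
  bc <- body_composition(100, 40, 5)
  expect_equal(bc$lean_kg, 55)
  expect_equal(bc$fat_pct, 40)
  bc0 <- body_composition(150, 0, 0)
  expect_equal(bc0$lean_kg, 150)
  expect_equal(bc0$fat_pct, 0)
  expect_error(body_composition(100, 90, 20), "Inconsistent")
  expect_error(body_composition(0, 0, 0), "positive")
})

test_that("Kruskal-Wallis H matches hand computation and refuses degenerate input", {
  expect_equal(kruskal_wallis(list(c(1, 2), c(1, 2)))$statistic, 0)
  expect_equal(kruskal_wallis(list(c(1, 2), c(3, 4)))$statistic, 2.4,
               tolerance = 1e-12)
  expect_error(kruskal_wallis(list(c(2, 2), c(2, 2))), "identical")
  expect_error(kruskal_wallis(list(1:5)), "two non-empty groups")
  # independent brute-force H on a tied fixture
  v <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8)
  g <- rep(c("a", "b", "c"), each = 4)
  expect_equal(kruskal_wallis(v, g)$statistic, kw_brute(v, g),
               tolerance = 1e-12)
})

test_that("KW is invariant under strictly monotone transforms", {
  withr::with_seed(17, {
    v <- rnorm(18)
    g <- rep(c("a", "b", "c"), 6)
    h1 <- kruskal_wallis(v, g)$statistic
    h2 <- kruskal_wallis(exp(v), g)$statistic
    h3 <- kruskal_wallis(rank(v)^3, g)$statistic
  })
  expect_equal(h1, h2, tolerance = 1e-12)
  expect_equal(h1, h3, tolerance = 1e-12)
})

test_that("chi-square p is close to the exact permutation p at small n", {
  # full enumeration over assignments of 12 values to groups of 4/4/4.
  # The chi-square approximation tracks the permutation null closely in the
  # tail where decisions are made; mid-range p (0.4-0.7) can deviate by up
  # to ~0.04 at these sizes, so the fixture sits in the decision-relevant
  # region.
  v <- c(1.2, 0.5, 2.2, 3.3, 3.4, 2.8, 1.7, 0.9, 5.1, 4.4, 1.0, 4.0)
  g <- rep(c("a", "b", "c"), each = 4)
  obs <- kruskal_wallis(v, g)
  idx <- seq_along(v)
  combs_a <- utils::combn(idx, 4, simplify = FALSE)
  count <- 0L; total <- 0L
  for (a in combs_a) {
    rest <- setdiff(idx, a)
    for (b in utils::combn(rest, 4, simplify = FALSE)) {
      gg <- character(12)
      gg[a] <- "a"; gg[b] <- "b"; gg[setdiff(rest, b)] <- "c"
      h <- kw_brute(v, gg)
      total <- total + 1L
      if (h >= obs$statistic - 1e-12) count <- count + 1L
    }
  }
  p_exact <- count / total
  expect_lt(abs(obs$p - p_exact), 0.02)
})

test_that("Dunn z matches brute force and its k = 2 identity with KW", {
  v <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8, 7, 2)
  g <- rep(c("NAS0-1", "NAS2-3"), 7)
  d <- dunn_posthoc(v, g, reference = "NAS0-1")
  expect_equal(d$z, dunn_brute(v, g, "NAS2-3", "NAS0-1"), tolerance = 1e-12)
  # duplicated data in both groups -> z = 0, p = 1
  vv <- c(1, 2, 3, 1, 2, 3)
  gg <- rep(c("r", "s"), each = 3)
  d0 <- dunn_posthoc(vv, gg, reference = "r")
  expect_equal(d0$z, 0)
  expect_equal(d0$p, 1)
  # with two groups and no ties, z^2 equals the KW H statistic
  withr::with_seed(23, {
    for (i in 1:5) {
      v2 <- sample(100, 12)
      g2 <- rep(c("r", "s"), times = c(5, 7))
      z2 <- dunn_posthoc(v2, g2, reference = "r")$z^2
      h <- kruskal_wallis(v2, g2)$statistic
      expect_equal(z2, h, tolerance = 1e-10)
    }
  })
  expect_error(dunn_posthoc(v, g, reference = "NAS9"), "not present")
})

test_that("|z| grows monotonically as one group is shifted away", {
  withr::with_seed(29, {
    base <- rnorm(10)
    other <- rnorm(8)
  })
  zs <- vapply(c(0, 1, 2, 4, 8), function(shift) {
    abs(dunn_posthoc(c(base, other + shift),
                     rep(c("r", "s"), c(10, 8)), reference = "r")$z)
  }, numeric(1))
  expect_true(all(diff(zs) >= 0))
})

test_that("Spearman rho is the rank Pearson correlation with a t-approximate p", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(spearman(x, x^3)$rho, 1)        # monotone map
  expect_equal(spearman(x, -x^3)$rho, -1)      # reversed
  # tied fixture against brute-force rank Pearson
  xt <- c(1, 2, 2, 3, 4, 4)
  yt <- c(2, 1, 4, 4, 3, 5)
  s <- spearman(xt, yt)
  expect_equal(s$rho, cor(rank(xt), rank(yt)), tolerance = 1e-12)
  tstat <- s$rho * sqrt((6 - 2) / (1 - s$rho^2))
  expect_equal(s$p, 2 * pt(-abs(tstat), df = 4), tolerance = 1e-12)
  expect_error(spearman(c(1, 1, 1, 1), 1:4), "constant")
  expect_error(spearman(1:3, 1:3), "n >= 4")
})

test_that("exact permutation p agrees with the enumeration oracle", {
  x <- c(0.3, 1.2, 0.8, 2.0, 1.5, 0.1)
  y <- c(10, 30, 15, 60, 35, 8)
  s <- spearman(x, y, exact = TRUE)
  # independent enumeration
  rx <- rank(x); ry <- rank(y)
  perms <- combinat_perms <- NULL
  all_p <- NULL
  obs <- cor(rx, ry)
  cnt <- 0L; tot <- 0L
  rec <- function(left, acc) {
    if (length(left) == 0) {
      tot <<- tot + 1L
      if (abs(cor(rx, ry[acc])) >= abs(obs) - 1e-12) cnt <<- cnt + 1L
      return(invisible())
    }
    for (k in left) rec(setdiff(left, k), c(acc, k))
  }
  rec(seq_along(x), integer())
  expect_equal(s$p, cnt / tot, tolerance = 1e-12)
})

test_that("cohort summaries respect conservation and planted shifts", {
  cfg <- null_config(seed = 14,
                     group_sizes = c("NAS0-1" = 20, "NAS2-3" = 20,
                                     "NAS4-6" = 20))
  sheet <- simulate_cohort(cfg)$sheet
  summ <- summarize_cohort(sheet)
  # frequency rows sum to the group sizes for every histology variable
  sums <- summ$frequencies |>
    dplyr::group_by(variable, group) |>
    dplyr::summarise(n = sum(count), .groups = "drop")
  expect_true(all(sums$n == 20))
  # the planted severity shift on liver stiffness is detected
  expect_lt(summ$continuous$p[summ$continuous$variable == "te_kpa"][1], 0.05)
  # medians/IQR match direct computation for one variable/group
  ref <- sheet$age[sheet$nas_group == "NAS0-1"]
  row <- summ$continuous[summ$continuous$variable == "age" &
                           summ$continuous$nas_group == "NAS0-1", ]
  expect_equal(row$median, median(ref))
  expect_equal(row$q1, quantile(ref, 0.25, names = FALSE))
  expect_equal(row$q3, quantile(ref, 0.75, names = FALSE))
})

test_that("single-participant groups give degenerate but valid summaries", {
  sheet <- tibble::tibble(participant_id = c("P1", "P2", "P3"),
                          nas_group = c("NAS0-1", "NAS2-3", "NAS2-3"),
                          age = c(50, 40, 44))
  summ <- summarize_cohort(sheet, continuous = "age", grades = character())
  row <- summ$continuous[summ$continuous$nas_group == "NAS0-1", ]
  expect_equal(row$median, 50)
  expect_equal(row$q1, 50)
  expect_equal(row$q3, 50)
})

test_that("filter_count reproduces the printed cohort frequencies", {
  freq <- histology_frequencies()
  expect_equal(filter_count(freq, variable == "fibrosis_stage" &
                              grade %in% c("1", "2", "3", "4")), 8L)
  expect_equal(filter_count(freq, variable == "nash" & grade == "yes"), 5L)
  # fibrosis by group, stage >= 1: 0 / 3 / 5
  expect_equal(filter_count(freq, variable == "fibrosis_stage" &
                              grade %in% c("1", "2", "3", "4") & group == "NAS2-3"), 3L)
  expect_equal(filter_count(freq, variable == "fibrosis_stage" &
                              grade %in% c("1", "2", "3", "4") & group == "NAS4-6"), 5L)
  com <- comorbidity_counts()
  expect_equal(filter_count(com, variable == "type_2_diabetes"), 10L)
  expect_equal(filter_count(com, variable == "hypertension"), 12L)
  expect_equal(filter_count(com, variable == "dyslipidemia"), 12L)
  # sheet-level counting and guards
  sheet <- tibble::tibble(nas_total = c(0, 2, 5), nash = c(FALSE, FALSE, TRUE))
  expect_equal(filter_count(sheet, nash), 1L)
  expect_equal(filter_count(sheet[0, ], nash), 0L)
  expect_error(filter_count(sheet, not_a_column > 1), "unknown column")
})
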