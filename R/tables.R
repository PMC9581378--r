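#' Bundled cohort frequency tables
#'
#' The published histology frequency table of the 26-participant discovery
#' cohort (grades of steatosis, lobular inflammation, ballooning, total NAS,
#' fibrosis stage and NASH status per NAS severity group), and the comorbidity
#' counts from the clinical characteristics table. These are the printed
#' summaries the raw cohort data reduce to; [filter_count()] interrogates
#' them.
#'
#' @return A tibble in long format: `variable`, `grade`/`group`, `count`.
#' @examples
#' filter_count(histology_frequencies(), variable == "nash" & grade == "yes")
#' @export
histology_frequencies <- function() {
  readr::read_tsv(system.file("extdata", "histology_frequencies.tsv",
                              package = "liversig"),
                  col_types = readr::cols(
                    variable = "c", grade = "c", group = "c", count = "i"))
}

#' @rdname histology_frequencies
#' @export
comorbidity_counts <- function() {
  readr::read_tsv(system.file("extdata", "comorbidity_counts.tsv",
                              package = "liversig"),
                  col_types = readr::cols(variable = "c", group = "c",
                                          count = "i"))
}
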