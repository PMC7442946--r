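#' Parse p-values as printed in report tables
#'
#' Published correlation and significance tables print p-values rounded to
#' two or three decimals, with values below the printing resolution shown as
#' `"<.001"`. This helper maps such strings to numerics usable in
#' [equality_fraction()]: a censored `"<x"` entry becomes `x / 2` (any value
#' below the censoring point behaves identically under two-decimal
#' thresholding).
#'
#' @param p Character vector like `c(".02", "<.001", ".05")`.
#' @return Numeric vector.
#' @examples
#' parse_printed_p(c(".05", "<.001"))
#' @export
parse_printed_p <- function(p) {
  censored <- grepl("^<", p)
  out <- as.numeric(sub("^<", "", p))
  out[censored] <- out[censored] / 2
  out
}

#' Path to a bundled example table
#'
#' The package ships the printed summary tables of two published EMA/PeerMA
#' feasibility studies (engagement, per-person profiles, dyad correlations,
#' and signed-rank p-values) as plain CSV, for worked examples and
#' verification: `study_a_engagement.csv`, `study_b_engagement.csv`,
#' `study_a_profiles.csv`, `study_b_profiles.csv`,
#' `study_a_correlations.csv`, `study_b_correlations.csv`,
#' `study_a_wilcoxon.csv`, `study_b_wilcoxon.csv`.
#'
#' @param file File name; with no argument, lists the available files.
#' @return Full path, or a character vector of file names.
#' @examples
#' peerma_example()
#' head(readr::read_csv(peerma_example("study_a_engagement.csv"),
#'                      show_col_types = FALSE))
#' @export
peerma_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "peerma")))
  }
  path <- system.file("extdata", file, package = "peerma")
  if (path == "") stop("no bundled file '", file, "'", call. = FALSE)
  path
}
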