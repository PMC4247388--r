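#' Curated differential-expression statistic tables
#'
#' Per-gene summary statistics (log2 fold-change, raw and
#' Benjamini-Hochberg adjusted P-values, B statistic) for three
#' published one-vs-rest contrasts in comparative mammalian
#' transcriptomics: bowhead whale liver versus other mammals, bowhead
#' whale kidney versus other mammals, and whale (bowhead plus minke)
#' heart versus terrestrial mammals. Every row in these tables was
#' reported as differentially expressed under the triple threshold
#' `|logFC| >= 2`, adjusted `P <= 0.05`, `B >= 2.945`, which makes them
#' a convenient worked example for [call_differential()]: re-applying
#' the thresholds must flag every row.
#'
#' @param tissue One of `"liver"`, `"kidney"`, `"heart"`, or `"all"`
#'   (default) for a single tibble with a `tissue` column.
#' @return A tibble with columns `tissue` (when `"all"`), `gene`,
#'   `transcript`, `logFC`, `p_value`, `p_adj`, `B`.
#' @export
#' @examples
#' de <- study_de_tables("liver")
#' sum(call_differential(de)$flagged)
study_de_tables <- function(tissue = c("all", "liver", "kidney", "heart")) {
  tissue <- match.arg(tissue)
  files <- c(
    liver = "de_stats_bowhead_liver.tsv",
    kidney = "de_stats_bowhead_kidney.tsv",
    heart = "de_stats_whale_heart.tsv"
  )
  read_one <- function(t) {
    path <- system.file("extdata", files[[t]], package = "orthoscan",
                        mustWork = TRUE)
    readr::read_tsv(path, show_col_types = FALSE)
  }
  if (tissue != "all") return(read_one(tissue))
  bind_rows(lapply(names(files), function(t) {
    dplyr::bind_cols(tibble(tissue = t), read_one(t))
  }))
}
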