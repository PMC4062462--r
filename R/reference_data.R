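#' Published distal 3'UTR window compositions for 18 species
#'
#' Species-level base compositions of the DISTAL50 window (the 50-base slice
#' of the 3'UTR lying 50 bases upstream of the poly(A) site), compiled from
#' published NCBI-mRNA-based mappings of eleven animal and seven plant
#' species. Used by the worked examples: feeding each row to [ua_ratio()]
#' reproduces the published U/A column, and an equal-variance t-test on the
#' ratios separates plants from animals.
#'
#' @return Data frame with columns `species`, `group` (mammal / non_mammal /
#'   dicot / monocot), `supergroup` (animal / plant), `pct_A`, `pct_C`,
#'   `pct_G`, `pct_U`.
#' @export
distal_utr50_table <- function() {
  path <- system.file("extdata", "distal_utr50_composition.tsv",
                      package = "polyAcomp", mustWork = TRUE)
  utils::read.delim(path, check.names = FALSE)
}

#' U/A ratios for a distal-window composition table
#'
#' Builds a `base_composition` from each row of a table shaped like
#' [distal_utr50_table()] and computes its U/A ratio.
#'
#' @param tab Data frame with columns `pct_A`, `pct_C`, `pct_G`, `pct_U`.
#' @return Numeric vector of full-precision U/A ratios, named by species
#'   when a `species` column is present.
#' @export
table_ua_ratios <- function(tab) {
  r <- vapply(seq_len(nrow(tab)), function(i) {
    ua_ratio(base_composition(tab$pct_A[i], tab$pct_C[i], tab$pct_G[i],
                              tab$pct_U[i], alphabet = "RNA"))
  }, numeric(1))
  if (!is.null(tab$species)) names(r) <- tab$species
  r
}
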