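#' Junction-relative window specifications
#'
#' The four named windows used throughout the analysis, as inclusive
#' junction-relative bounds:
#' \describe{
#'   \item{UTR100}{-100..-1, the 100 transcript bases upstream of the
#'     junction (the anchor).}
#'   \item{COR100}{+1..+100, the 100 genomic bases downstream of, and
#'     excluding, the poly(A) tail starting position. With
#'     `cor_includes_site = TRUE` the window shifts to 0..+99, the reading in
#'     which the cleaved-off region starts at the site base itself.}
#'   \item{DISTAL50}{-100..-51, the distal half of the 3'UTR window, used to
#'     measure composition away from near-site A/U-rich motifs.}
#'   \item{SIXBASE}{0..+5, the site base and the five bases immediately
#'     downstream, the window whose A content diagnoses internal priming.}
#' }
#'
#' @param name One of `"UTR100"`, `"COR100"`, `"DISTAL50"`, `"SIXBASE"`.
#' @param cor_includes_site Shift COR100 to 0..+99 (default `FALSE`).
#' @return List with `name`, `lo`, `hi`.
#' @export
window_spec <- function(name = c("UTR100", "COR100", "DISTAL50", "SIXBASE"),
                        cor_includes_site = FALSE) {
  name <- match.arg(name)
  bounds <- switch(name,
    UTR100 = c(-100L, -1L),
    COR100 = if (cor_includes_site) c(0L, 99L) else c(1L, 100L),
    DISTAL50 = c(-100L, -51L),
    SIXBASE = c(0L, 5L)
  )
  list(name = name, lo = bounds[1L], hi = bounds[2L])
}

#' Per-position base counts across all sites
#'
#' Builds the junction-relative composition profile of a deduplicated site
#' set: for each position from `-anchor_len` to +100, the number of sites
#' whose transcript-orientation base at that position is A, C, G or T
#' (201 positions for 100-base anchors; 181 for 80-base read-mode anchors).
#' Every site contributes exactly one base per position, so each row sums to
#' the number of sites.
#'
#' @param sites Unique site table with complete `utr_window`, `site_base`,
#'   `cor_window`, all anchors the same length.
#' @return Object of class `composition_profile`: list with `counts`
#'   (positions x 4 matrix, rows named by junction-relative position,
#'   columns A/C/G/T), `n_sites`, and `utr_len`.
#' @export
positional_profile <- function(sites) {
  if (nrow(sites) == 0L) {
    stop("degenerate input: cannot profile an empty site set", call. = FALSE)
  }
  utr_len <- unique(nchar(sites$utr_window))
  if (length(utr_len) != 1L) {
    stop("all sites must share one anchor length", call. = FALSE)
  }
  width <- utr_len + 101L
  seqs <- paste0(sites$utr_window, sites$site_base, sites$cor_window)
  if (any(nchar(seqs) != width)) {
    stop("all sites must carry complete ", width, "-base windows",
         call. = FALSE)
  }
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(seqs), ncol = width, byrow = TRUE)
  counts <- vapply(c("A", "C", "G", "T"),
                   function(b) .colSums(chars == b, nrow(chars), width),
                   numeric(width))
  rownames(counts) <- as.character(seq(-utr_len, 100L))
  structure(list(counts = counts, n_sites = nrow(sites), utr_len = utr_len),
            class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat("composition_profile:", nrow(x$counts), "positions (-", x$utr_len,
      "..+100), ", x$n_sites, " site(s)\n", sep = "")
  invisible(x)
}

profile_rows <- function(profile, lo, hi) {
  idx <- (lo:hi) + profile$utr_len + 1L
  if (any(idx < 1L) || any(idx > nrow(profile$counts))) {
    stop("window ", lo, "..", hi, " outside the profiled range -",
         profile$utr_len, "..+100", call. = FALSE)
  }
  profile$counts[idx, , drop = FALSE]
}

#' Pooled base composition of a junction-relative window
#'
#' Percentages pooled over every position in the window and every site
#' (denominator = n_sites x window length), reported on the RNA alphabet
#' (U in place of T) since the windows describe transcript-orientation
#' sequence.
#'
#' @param profile A `composition_profile`.
#' @param window A [window_spec()].
#' @return A `base_composition` with `alphabet = "RNA"`.
#' @export
window_composition <- function(profile, window) {
  stopifnot(inherits(profile, "composition_profile"))
  cts <- colSums(profile_rows(profile, window$lo, window$hi))
  composition_from_counts(cts, alphabet = "RNA")
}

#' Region/genome composition ratios
#'
#' Each base's region percentage divided by the matched whole-genome
#' percentage (U matched to T). Ratios are computed per species; group-level
#' summaries average these per-species ratios, never ratios of group means.
#'
#' @param region A `base_composition` (RNA) for the region.
#' @param background A `base_composition` (DNA) for the same species' genome.
#' @param region_name,species_id Labels carried into the result.
#' @return Object of class `ratio_table`: list with `ratio` (named A/C/G/TU
#'   vector, `NA` where the genome percentage is 0), `undefined` (logical
#'   vector), `region_name`, `species_id`.
#' @export
region_genome_ratio <- function(region, background,
                                region_name = NA_character_,
                                species_id = NA_character_) {
  stopifnot(inherits(region, "base_composition"),
            inherits(background, "base_composition"))
  undef <- background$pct == 0
  ratio <- ifelse(undef, NA_real_, region$pct / background$pct)
  names(ratio) <- names(region$pct)
  structure(list(ratio = ratio, undefined = undef,
                 region_name = region_name, species_id = species_id),
            class = "ratio_table")
}

#' @export
print.ratio_table <- function(x, digits = 2, ...) {
  cat(sprintf("ratio_table [%s/%s genome]: A=%s C=%s G=%s U=%s\n",
              x$species_id, x$region_name,
              round_half_up(x$ratio[["A"]], digits),
              round_half_up(x$ratio[["C"]], digits),
              round_half_up(x$ratio[["G"]], digits),
              round_half_up(x$ratio[["TU"]], digits)))
  invisible(x)
}

#' Per-position region/genome ratio track
#'
#' For one base, the ratio of its per-position frequency (as a percentage of
#' sites) to its whole-genome percentage, across all 201 junction-relative
#' positions — the single-base positional overrepresentation track.
#'
#' @param profile A `composition_profile`.
#' @param background A `base_composition` (DNA).
#' @param base One of `"A"`, `"C"`, `"G"`, `"U"` (or `"T"`).
#' @return Named numeric vector (names = positions -100..100).
#' @export
per_position_ratio <- function(profile, background, base) {
  stopifnot(inherits(profile, "composition_profile"), profile$n_sites > 0)
  base <- toupper(base)
  col <- if (base %in% c("U", "T")) "T" else match.arg(base, c("A", "C", "G"))
  key <- if (col == "T") "TU" else col
  bg <- background$pct[[key]]
  if (bg == 0) {
    stop("genome percentage of ", base, " is 0; ratio undefined", call. = FALSE)
  }
  (profile$counts[, col] / profile$n_sites * 100) / bg
}

#' U/A ratio of a window composition
#'
#' Uracil percentage divided by adenine percentage; the statistic that
#' separates plant from animal distal 3'UTR windows. Full precision is
#' returned; round at the reporting layer (2 decimals, half-up).
#'
#' @param comp A `base_composition`.
#' @return The ratio, or `NA` (flagged with a warning) when `pct_A` is 0.
#' @export
ua_ratio <- function(comp) {
  stopifnot(inherits(comp, "base_composition"))
  if (comp$pct[["A"]] == 0) {
    warning("pct_A is 0: U/A ratio undefined")
    return(NA_real_)
  }
  comp$pct[["TU"]] / comp$pct[["A"]]
}

#' Write a composition profile as TSV
#'
#' @param profile A `composition_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  df <- data.frame(
    position = as.integer(rownames(profile$counts)),
    count_A = profile$counts[, "A"],
    count_C = profile$counts[, "C"],
    count_G = profile$counts[, "G"],
    count_T = profile$counts[, "T"],
    n_sites = profile$n_sites
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write region/genome ratios as TSV
#'
#' @param ratios List of `ratio_table` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ratio_tsv <- function(ratios, path) {
  df <- do.call(rbind, lapply(ratios, function(r) {
    data.frame(species = r$species_id, region = r$region_name,
               base = c("A", "C", "G", "U"), ratio = unname(r$ratio))
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
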