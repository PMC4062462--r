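#' Read a (possibly gzipped) multi-record FASTA file
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that validates the file
#' up front so that malformed input produces an error naming the offending
#' line, and that normalises records for downstream exact matching: sequences
#' are uppercased, carriage returns stripped, and the record id is the header
#' token before the first whitespace.
#'
#' @param path Path to a FASTA file (plain text or gzip).
#' @return Named character vector of uppercase sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    stop("FASTA format error in '", path, "': file is empty", call. = FALSE)
  }
  first <- nonblank[1L]
  if (!startsWith(lines[first], ">")) {
    stop("FASTA format error in '", path, "' at line ", first,
         ": expected a '>' header before any sequence", call. = FALSE)
  }
  headers <- which(startsWith(lines, ">"))
  empty_hdr <- headers[!nzchar(trimws(sub("^>", "", lines[headers])))]
  if (length(empty_hdr) > 0L) {
    stop("FASTA format error in '", path, "' at line ", empty_hdr[1L],
         ": header has no identifier", call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(gsub("[\r ]", "", as.character(set)))
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1), 1L)
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-fold width (bases per line).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    if (n == 0L) next
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Build a genome store with whole-genome base tallies
#'
#' The store keeps every chromosome (or scaffold) as an uppercase forward
#' strand sequence, together with the genome-wide A/C/G/T tallies that serve
#' as the background composition. Non-ACGT letters (N and other IUPAC codes)
#' are retained in the sequence but excluded from both the numerator and the
#' denominator of composition percentages. Coordinates everywhere in this
#' package are 0-based half-open on the deposited forward strand.
#'
#' @param x A FASTA path, a named character vector of sequences, or a
#'   [Biostrings::DNAStringSet].
#' @return An object of class `genome_store` with elements `records` (named
#'   uppercase character vector), `seq` (`DNAStringSet` for matching),
#'   `base_counts` (named A/C/G/T counts), `counted_bases` and `n_excluded`.
#' @export
genome_store <- function(x) {
  if (is.character(x) && length(x) == 1L && is.null(names(x)) && file.exists(x)) {
    x <- read_fasta(x)
  }
  if (methods::is(x, "XStringSet")) {
    recs <- toupper(as.character(x))
  } else if (is.character(x)) {
    if (is.null(names(x))) stop("genome sequences must be named", call. = FALSE)
    recs <- toupper(x)
  } else {
    stop("cannot build a genome_store from class ", class(x)[1L], call. = FALSE)
  }
  dss <- Biostrings::DNAStringSet(recs)
  freq <- Biostrings::letterFrequency(dss, letters = c("A", "C", "G", "T"))
  counts <- colSums(freq)
  total <- sum(Biostrings::width(dss))
  structure(
    list(
      records = recs,
      seq = dss,
      base_counts = counts,
      counted_bases = sum(counts),
      n_excluded = total - sum(counts)
    ),
    class = "genome_store"
  )
}

#' @export
print.genome_store <- function(x, ...) {
  cat("genome_store:", length(x$records), "record(s),",
      format(x$counted_bases, big.mark = ","), "counted bases (",
      x$n_excluded, "non-ACGT excluded )\n")
  invisible(x)
}

#' Construct a base composition
#'
#' A base composition holds the four base percentages (with T and U unified
#' as `TU`), the number of bases behind them, and an alphabet tag controlling
#' whether the fourth base is reported as T (DNA) or U (RNA). Percentages
#' derived from counts sum to 100 exactly; user-supplied published
#' percentages are accepted if they sum to 100 within 0.05 (printed tables
#' carry rounding error).
#'
#' @param pct_A,pct_C,pct_G,pct_TU Percentages in \[0, 100\].
#' @param n_bases Number of bases the percentages are computed from (`NA` for
#'   published values).
#' @param alphabet `"DNA"` or `"RNA"`.
#' @return An object of class `base_composition`.
#' @export
base_composition <- function(pct_A, pct_C, pct_G, pct_TU,
                             n_bases = NA_integer_, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  pct <- c(A = pct_A, C = pct_C, G = pct_G, TU = pct_TU)
  if (any(!is.finite(pct)) || any(pct < 0)) {
    stop("percentages must be finite and non-negative", call. = FALSE)
  }
  tol <- if (is.na(n_bases)) 0.05 else 1e-9
  if (abs(sum(pct) - 100) > tol) {
    stop("base percentages must sum to 100 (got ", format(sum(pct)), ")",
         call. = FALSE)
  }
  structure(list(pct = pct, n_bases = n_bases, alphabet = alphabet),
            class = "base_composition")
}

## percentages from raw A/C/G/T counts; the only route used internally
composition_from_counts <- function(counts, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  stopifnot(all(c("A", "C", "G", "T") %in% names(counts)))
  counts <- counts[c("A", "C", "G", "T")]
  n <- sum(counts)
  if (n == 0) {
    stop("degenerate input: no A/C/G/T bases to compute a composition from",
         call. = FALSE)
  }
  pct <- 100 * counts / n
  structure(
    list(pct = c(A = unname(pct["A"]), C = unname(pct["C"]),
                 G = unname(pct["G"]), TU = unname(pct["T"])),
         n_bases = n, alphabet = alphabet),
    class = "base_composition"
  )
}

#' @export
print.base_composition <- function(x, digits = 2, ...) {
  lab4 <- if (x$alphabet == "RNA") "U" else "T"
  cat(sprintf("base_composition (%s, n=%s): A=%s C=%s G=%s %s=%s\n",
              x$alphabet, format(x$n_bases),
              round_half_up(x$pct[["A"]], digits),
              round_half_up(x$pct[["C"]], digits),
              round_half_up(x$pct[["G"]], digits),
              lab4, round_half_up(x$pct[["TU"]], digits)))
  invisible(x)
}

#' Whole-genome background base composition
#'
#' Percentage of A, C, G and T over all chromosomes of the store, counting
#' only unambiguous A/C/G/T letters. With `symmetrize = TRUE` the A/T and
#' C/G percentages are averaged, giving a strand-symmetric background; the
#' default uses the deposited strand as-is.
#'
#' @param genome A `genome_store`.
#' @param symmetrize Average complementary bases (default `FALSE`).
#' @return A `base_composition` with `alphabet = "DNA"`.
#' @export
genome_composition <- function(genome, symmetrize = FALSE) {
  stopifnot(inherits(genome, "genome_store"))
  comp <- composition_from_counts(genome$base_counts, alphabet = "DNA")
  if (symmetrize) {
    at <- mean(comp$pct[c("A", "TU")])
    cg <- mean(comp$pct[c("C", "G")])
    comp$pct <- c(A = at, C = cg, G = cg, TU = at)
  }
  comp
}

#' Round half away from zero
#'
#' Reporting-layer rounding matching the half-up convention of published
#' tables (base R's `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Write a composition report as TSV
#'
#' One row per (dataset, region) with percentages at full precision.
#'
#' @param rows Data frame with columns `dataset`, `region`, and
#'   `base_composition` objects in a list column `comp`, or a pre-built data
#'   frame with columns `dataset`, `region`, `A`, `C`, `G`, `T_or_U`,
#'   `n_bases`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_composition_tsv <- function(rows, path) {
  if (!is.null(rows$comp)) {
    rows <- data.frame(
      dataset = rows$dataset,
      region = rows$region,
      A = vapply(rows$comp, function(c) c$pct[["A"]], numeric(1)),
      C = vapply(rows$comp, function(c) c$pct[["C"]], numeric(1)),
      G = vapply(rows$comp, function(c) c$pct[["G"]], numeric(1)),
      T_or_U = vapply(rows$comp, function(c) c$pct[["TU"]], numeric(1)),
      n_bases = vapply(rows$comp, function(c) as.numeric(c$n_bases), numeric(1))
    )
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
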