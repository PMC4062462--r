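#' Detect a poly(A) tail at the 3' end of a sequence
#'
#' A transcript is considered polyadenylated when it ends in a run of at
#' least `min_tail` consecutive A's. The tail is the *maximal* trailing A-run:
#' trimming maximally prevents genome-templated A's at the junction from
#' being counted both as tail and as anchor sequence (the consequence — calls
#' shift upstream past templated terminal A's — is handled by the simulator,
#' which never places an A as the last templated base). Input U's are treated
#' as T's and the comparison is case-insensitive.
#'
#' @param seq A single nucleotide string.
#' @param min_tail Minimum run length to call a tail (default 12).
#' @return Integer tail length, or `NA_integer_` when the trailing run is
#'   shorter than `min_tail`.
#' @export
detect_tail <- function(seq, min_tail = 12L) {
  if (length(seq) != 1L || !is.character(seq) || is.na(seq) || !nzchar(seq)) {
    stop("detect_tail() requires a single non-empty sequence", call. = FALSE)
  }
  n <- tail_run_lengths(seq)
  if (n >= min_tail) as.integer(n) else NA_integer_
}

## vectorised maximal trailing A-run length (U counted as A-complement input:
## U is normalised to T, so only literal A's extend the tail)
tail_run_lengths <- function(seqs) {
  seqs <- normalize_dna(seqs)
  m <- regexpr("A+$", seqs)
  ifelse(m > 0L, attr(m, "match.length"), 0L)
}

normalize_dna <- function(seqs) {
  chartr("u", "T", chartr("U", "T", toupper(seqs)))
}

#' Extract the fixed-length anchor upstream of a poly(A) tail
#'
#' The anchor is the `anchor_len` bases immediately preceding the trailing
#' A-run; it is the sequence used for zero-mismatch genome placement and for
#' deduplication, so anchors containing ambiguity codes are rejected (an N
#' can never exact-match).
#'
#' @param seq A single nucleotide string with a detected tail.
#' @param tail_len Tail length as returned by [detect_tail()].
#' @param anchor_len Anchor length (default 100; 80 in read mode).
#' @param source_id Identifier carried through to the result.
#' @return A list with `source_id`, `anchor`, `tail_len` (class
#'   `anchored_transcript`), or `NULL` when rejected (too few bases upstream
#'   of the tail, or ambiguity codes in the anchor). [screen_transcripts()]
#'   counts rejections by category.
#' @export
extract_anchor <- function(seq, tail_len, anchor_len = 100L, source_id = NA_character_) {
  seq <- normalize_dna(seq)
  upstream <- nchar(seq) - tail_len
  if (upstream < anchor_len) {
    return(NULL)
  }
  anchor <- substr(seq, upstream - anchor_len + 1L, upstream)
  if (grepl("[^ACGT]", anchor)) {
    return(NULL)
  }
  structure(
    list(source_id = source_id, anchor = anchor, tail_len = as.integer(tail_len)),
    class = "anchored_transcript"
  )
}

#' Deduplicate anchored transcripts by anchor sequence
#'
#' Keeps exactly one transcript per distinct anchor string — the first in
#' input order — so that duplicated gene copies or resubmitted sequences do
#' not overcontribute to composition profiles.
#'
#' @param items Data frame with columns `source_id`, `anchor`, `tail_len`
#'   (as produced by [screen_transcripts()]), or a list of
#'   `anchored_transcript` objects.
#' @return A list with `items` (the unique data frame, first-occurrence
#'   order) and `n_duplicates`.
#' @export
dedupe_by_anchor <- function(items) {
  if (is.list(items) && !is.data.frame(items)) {
    items <- do.call(rbind, lapply(items, function(x) {
      data.frame(source_id = x$source_id, anchor = x$anchor,
                 tail_len = x$tail_len, stringsAsFactors = FALSE)
    }))
    if (is.null(items)) {
      items <- data.frame(source_id = character(), anchor = character(),
                          tail_len = integer())
    }
  }
  if (nrow(items) > 0L && length(unique(nchar(items$anchor))) > 1L) {
    stop("all anchors must have the same length", call. = FALSE)
  }
  keep <- !duplicated(items$anchor)
  list(items = items[keep, , drop = FALSE],
       n_duplicates = sum(!keep))
}

#' Screen a transcript set for poly(A) tails and unique anchors
#'
#' Runs the tail/anchor stage over a whole FASTA-derived set: optional
#' id-pattern exclusion (e.g. to drop computationally predicted mRNA
#' accessions), tail detection at `min_tail`, anchor extraction at
#' `anchor_len`, and deduplication by anchor. Rejections are counted by
#' category, never silently dropped.
#'
#' @param seqs Named character vector of transcript/read sequences.
#' @param min_tail Minimum poly(A) tail length (default 12).
#' @param anchor_len Anchor length (default 100).
#' @param id_exclude_pattern Optional regex; matching ids are excluded before
#'   screening (default `NULL`, no filter).
#' @return A list with `anchors` (data frame `source_id`, `anchor`,
#'   `tail_len`, one row per unique anchor, first-occurrence order) and
#'   `report` (named counts: `n_input`, `n_id_excluded`, `n_no_tail`,
#'   `n_too_short`, `n_ambiguous`, `n_tailed`, `n_anchored`, `n_duplicates`,
#'   `n_unique_anchors`).
#' @export
screen_transcripts <- function(seqs, min_tail = 12L, anchor_len = 100L,
                               id_exclude_pattern = NULL) {
  stopifnot(is.character(seqs))
  n_input <- length(seqs)
  if (!is.null(id_exclude_pattern) && nzchar(id_exclude_pattern)) {
    drop <- grepl(id_exclude_pattern, names(seqs))
    seqs <- seqs[!drop]
    n_id_excluded <- sum(drop)
  } else {
    n_id_excluded <- 0L
  }
  seqs <- normalize_dna(seqs)
  runs <- tail_run_lengths(seqs)
  tailed <- runs >= min_tail
  n_no_tail <- sum(!tailed)
  n_tailed <- sum(tailed)
  seqs <- seqs[tailed]
  runs <- runs[tailed]

  upstream <- nchar(seqs) - runs
  long_enough <- upstream >= anchor_len
  n_too_short <- sum(!long_enough)
  seqs <- seqs[long_enough]
  runs <- runs[long_enough]
  upstream <- upstream[long_enough]

  anchors <- substr(seqs, upstream - anchor_len + 1L, upstream)
  clean <- !grepl("[^ACGT]", anchors)
  n_ambiguous <- sum(!clean)

  df <- data.frame(
    source_id = names(seqs)[clean],
    anchor = anchors[clean],
    tail_len = as.integer(runs[clean]),
    stringsAsFactors = FALSE
  )
  dd <- dedupe_by_anchor(df)
  list(
    anchors = dd$items,
    report = c(
      n_input = n_input,
      n_id_excluded = n_id_excluded,
      n_no_tail = n_no_tail,
      n_too_short = n_too_short,
      n_ambiguous = n_ambiguous,
      n_tailed = n_tailed,
      n_anchored = nrow(df),
      n_duplicates = dd$n_duplicates,
      n_unique_anchors = nrow(dd$items)
    )
  )
}

#' Write the screening report as TSV
#'
#' @param report Named counts from [screen_transcripts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(report, path) {
  utils::write.table(
    data.frame(stage = names(report), count = as.integer(report)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
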