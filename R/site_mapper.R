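## Junction-relative coordinate convention (see also the package vignette):
##   positions -100..-1  = 3'UTR window (the anchor itself)
##   position 0          = site base: the genomic base under the first tail A
##   positions +1..+100  = 3'COR window
## `junction` is the 0-based forward-assembly coordinate of the last
## templated (anchor) base. On the minus strand all reported window
## sequences are reverse-complemented so they read 5'->3' in transcript
## orientation.

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Exact-match an anchor on both strands of a genome
#'
#' Reports every zero-mismatch occurrence of `anchor` on the forward strand
#' and of its reverse complement on the forward strand (i.e. transcripts from
#' the minus strand). The result must equal a naive scan of every offset on
#' both strands; any indexing scheme is acceptable as long as that contract
#' holds.
#'
#' @param anchor A pure-ACGT string.
#' @param genome A `genome_store`.
#' @return Data frame with columns `chrom`, `strand` (`"+"`/`"-"`), and
#'   `junction` (0-based forward coordinate of the last templated base),
#'   sorted by (chrom, junction, strand). Zero rows when unmapped.
#' @export
match_anchor <- function(anchor, genome) {
  stopifnot(inherits(genome, "genome_store"))
  if (grepl("[^ACGT]", anchor)) {
    stop("anchor must contain only A/C/G/T", call. = FALSE)
  }
  L <- nchar(anchor)
  pat_fwd <- Biostrings::DNAString(anchor)
  pat_rev <- Biostrings::reverseComplement(pat_fwd)
  out <- vector("list", 2L * length(genome$seq))
  k <- 0L
  for (i in seq_along(genome$seq)) {
    chrom <- names(genome$seq)[i]
    subject <- genome$seq[[i]]
    fwd <- Biostrings::start(Biostrings::matchPattern(pat_fwd, subject,
                                                      max.mismatch = 0))
    rev <- Biostrings::start(Biostrings::matchPattern(pat_rev, subject,
                                                      max.mismatch = 0))
    if (length(fwd) > 0L) {
      k <- k + 1L
      ## 1-based start s: anchor spans [s-1, s+L-2] 0-based; junction = s+L-2
      out[[k]] <- data.frame(chrom = chrom, strand = "+",
                             junction = fwd + L - 2L)
    }
    if (length(rev) > 0L) {
      k <- k + 1L
      ## reverse-complement anchor at 1-based start s: in transcript
      ## orientation the last templated base sits at forward 0-based s-1
      out[[k]] <- data.frame(chrom = chrom, strand = "-",
                             junction = rev - 1L)
    }
  }
  if (k == 0L) {
    return(data.frame(chrom = character(), strand = character(),
                      junction = integer()))
  }
  hits <- do.call(rbind, out[seq_len(k)])
  hits <- hits[order(hits$chrom, hits$junction, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Call a poly(A) site from an anchor hit
#'
#' Extracts the junction-relative windows and artifact statistics for one
#' genomic placement: the site base (position 0), the 100-base 3'COR window
#' (+1..+100), the downstream A-run in transcript orientation starting at
#' position 0, the A count among positions 0..+5, and the internal-priming
#' flag (`downstream_A_run >= ip_min_run`). Returns `NULL` when fewer than
#' 101 genomic bases exist downstream of the junction, since the COR window
#' must be complete; [map_anchors()] counts such hits as incomplete.
#'
#' @param chrom,strand,junction A hit as returned by [match_anchor()].
#' @param anchor The anchor string (transcript orientation).
#' @param genome A `genome_store`.
#' @param tail_len Tail length observed on the supporting transcript.
#' @param ip_min_run Downstream A-run length that flags internal priming
#'   (default 12, the tail-calling threshold).
#' @return One-row data frame with columns `chrom`, `junction`, `strand`,
#'   `tail_len`, `site_base`, `utr_window`, `cor_window`,
#'   `downstream_A_run`, `six_base_A_count`, `ip_flag`; or `NULL`.
#' @export
call_site <- function(chrom, strand, junction, anchor, genome,
                      tail_len = NA_integer_, ip_min_run = 12L) {
  stopifnot(inherits(genome, "genome_store"))
  idx <- match(chrom, names(genome$records))
  if (is.na(idx)) {
    stop("chromosome '", chrom, "' absent from genome store", call. = FALSE)
  }
  seq <- genome$records[[idx]]
  n <- nchar(seq)
  if (strand == "+") {
    ## downstream positions 0..+100 are forward 0-based junction+1..junction+101
    if (junction + 101L > n - 1L) {
      return(NULL)
    }
    down <- substr(seq, junction + 2L, junction + 102L)
  } else {
    ## downstream positions 0..+100 are forward 0-based junction-101..junction-1
    if (junction - 101L < 0L) {
      return(NULL)
    }
    down <- revcomp(substr(seq, junction - 100L, junction))
  }
  site_base <- substr(down, 1L, 1L)
  cor_window <- substr(down, 2L, 101L)
  m <- regexpr("^A+", down)
  run <- if (m > 0L) attr(m, "match.length") else 0L
  six <- lengths(regmatches(substr(down, 1L, 6L),
                            gregexpr("A", substr(down, 1L, 6L), fixed = TRUE)))
  data.frame(
    chrom = chrom, junction = as.integer(junction), strand = strand,
    tail_len = as.integer(tail_len),
    site_base = site_base, utr_window = anchor, cor_window = cor_window,
    downstream_A_run = as.integer(run),
    six_base_A_count = as.integer(six),
    ip_flag = run >= ip_min_run,
    stringsAsFactors = FALSE
  )
}

#' Deduplicate poly(A) sites by upstream sequence
#'
#' Keeps one site per distinct 100-base upstream window (the anchor): the
#' retained representative is the site with the lexicographically smallest
#' (chrom, junction, strand) triple, which makes multi-locus anchors
#' deterministic. The output is sorted by that same triple.
#'
#' @param sites Data frame of sites from [call_site()].
#' @return A list with `sites` (unique, sorted) and `n_collapsed`.
#' @export
dedupe_sites <- function(sites) {
  if (nrow(sites) == 0L) {
    return(list(sites = sites, n_collapsed = 0L))
  }
  ord <- order(sites$chrom, sites$junction, sites$strand)
  sites <- sites[ord, , drop = FALSE]
  keep <- !duplicated(sites$utr_window)
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(sites = out, n_collapsed = sum(!keep))
}

#' Map a screened anchor table to unique poly(A) sites
#'
#' Convenience stage runner: maps every unique anchor with [match_anchor()],
#' calls each hit with [call_site()], and deduplicates with
#' [dedupe_sites()]. Anchors with no exact hit are counted as unmapped;
#' hits too close to a contig edge for a complete COR window are counted as
#' incomplete.
#'
#' @param anchors Data frame with columns `source_id`, `anchor`, `tail_len`.
#' @param genome A `genome_store`.
#' @param ip_min_run Internal-priming run threshold (default 12).
#' @return List with `sites` (unique site table), `n_mapped_anchors`,
#'   `n_unmapped`, `n_incomplete`, `n_collapsed`.
#' @export
map_anchors <- function(anchors, genome, ip_min_run = 12L) {
  site_rows <- list()
  n_unmapped <- 0L
  n_incomplete <- 0L
  n_mapped <- 0L
  for (i in seq_len(nrow(anchors))) {
    hits <- match_anchor(anchors$anchor[i], genome)
    if (nrow(hits) == 0L) {
      n_unmapped <- n_unmapped + 1L
      next
    }
    any_site <- FALSE
    for (j in seq_len(nrow(hits))) {
      s <- call_site(hits$chrom[j], hits$strand[j], hits$junction[j],
                     anchor = anchors$anchor[i], genome = genome,
                     tail_len = anchors$tail_len[i], ip_min_run = ip_min_run)
      if (is.null(s)) {
        n_incomplete <- n_incomplete + 1L
      } else {
        site_rows[[length(site_rows) + 1L]] <- s
        any_site <- TRUE
      }
    }
    if (any_site) n_mapped <- n_mapped + 1L
  }
  sites <- if (length(site_rows) > 0L) {
    do.call(rbind, site_rows)
  } else {
    data.frame(chrom = character(), junction = integer(), strand = character(),
               tail_len = integer(), site_base = character(),
               utr_window = character(), cor_window = character(),
               downstream_A_run = integer(), six_base_A_count = integer(),
               ip_flag = logical(), stringsAsFactors = FALSE)
  }
  dd <- dedupe_sites(sites)
  list(sites = dd$sites, n_mapped_anchors = n_mapped,
       n_unmapped = n_unmapped, n_incomplete = n_incomplete,
       n_collapsed = dd$n_collapsed)
}

#' Write the unique-site table as TSV
#'
#' @param sites Site data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_tsv <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export junctions as BED6
#'
#' One feature per unique site: `chromStart` is the 0-based junction
#' coordinate, half-open (`chromEnd = junction + 1`), strand as called.
#'
#' @param sites Site data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(sites, path) {
  bed <- data.frame(
    chrom = sites$chrom,
    chromStart = sites$junction,
    chromEnd = sites$junction + 1L,
    name = sprintf("site_%04d", seq_len(nrow(sites))),
    score = 0L,
    strand = sites$strand
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
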