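#' Simulation configuration for synthetic genomes and transcripts
#'
#' Defines the generative model the pipeline is validated against: an
#' i.i.d.-background genome with planted, stranded cleavage junctions whose
#' upstream (3'UTR) and downstream (3'COR) windows carry region-specific
#' base biases; poly(A)-tailed transcripts supporting each junction; optional
#' internal-priming artifacts (planted genomic A-runs that masquerade as
#' tails); optional verbatim duplicates; and optional fragmentation to short
#' reads.
#'
#' Default compositions emulate the A+T-rich genomes and the U-rich, C-poor
#' junction-proximal regions seen across animal and plant species: background
#' 30/20/20/30 (A/C/G/T), 3'UTR window 28/17/18/37, 3'COR window 30/17/19/34.
#'
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @param n_chroms,chrom_len Number and length of chromosomes.
#' @param n_sites Number of planted junctions (artifacts included).
#' @param background_probs,utr_probs,cor_probs Length-4 probability vectors
#'   (A, C, G, T order) summing to 1.
#' @param tail_len_range Inclusive range of poly(A) tail lengths (min >= 12).
#' @param frac_internal_priming Fraction of planted sites that are
#'   internal-priming artifacts (transcripts ending inside a planted genomic
#'   A-run of length 12-20).
#' @param frac_duplicates Fraction of transcripts emitted again as verbatim
#'   copies.
#' @param read_mode `"off"` or `"fragmented"`.
#' @param read_len_range Fragment length range when `read_mode = "fragmented"`.
#' @param upstream_context Extra transcript bases upstream of the 3'UTR
#'   window (makes transcripts longer than the anchor, as real mRNA is).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_len = 50000L,
                       n_sites = 100L,
                       background_probs = c(A = 0.30, C = 0.20, G = 0.20, T = 0.30),
                       utr_probs = c(A = 0.28, C = 0.17, G = 0.18, T = 0.37),
                       cor_probs = c(A = 0.30, C = 0.17, G = 0.19, T = 0.34),
                       tail_len_range = c(12L, 30L),
                       frac_internal_priming = 0,
                       frac_duplicates = 0,
                       read_mode = c("off", "fragmented"),
                       read_len_range = c(100L, 200L),
                       upstream_context = 50L) {
  read_mode <- match.arg(read_mode)
  for (p in list(background_probs, utr_probs, cor_probs)) {
    if (length(p) != 4L || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("probability vectors must be length 4, non-negative, and sum to 1",
           call. = FALSE)
    }
  }
  if (tail_len_range[1L] < 12L) {
    stop("minimum tail length must be >= 12", call. = FALSE)
  }
  if (n_sites * 250 >= n_chroms * chrom_len) {
    stop("infeasible packing: need n_sites x 250 < total genome length",
         call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
         chrom_len = as.integer(chrom_len), n_sites = as.integer(n_sites),
         background_probs = background_probs, utr_probs = utr_probs,
         cor_probs = cor_probs, tail_len_range = as.integer(tail_len_range),
         frac_internal_priming = frac_internal_priming,
         frac_duplicates = frac_duplicates, read_mode = read_mode,
         read_len_range = as.integer(read_len_range),
         upstream_context = as.integer(upstream_context)),
    class = "sim_config"
  )
}

## uniform integers in [lo, hi]; safe when lo == hi (unlike sample(lo:hi, n))
sample_int_range <- function(lo, hi, n = 1L) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

rand_dna <- function(n, probs) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

## draw one base that is not A (used for the last templated base, so that
## maximal tail trimming recovers the planted junction exactly)
rand_non_A <- function(probs) {
  p <- probs[c("C", "G", "T")]
  sample(c("C", "G", "T"), 1L, prob = p / sum(p))
}

#' Generate a synthetic genome, transcript set and ground truth
#'
#' Chromosome sequences are drawn i.i.d. from `background_probs`; at each
#' planted junction the transcript-orientation window -100..-1 is drawn from
#' `utr_probs` and +1..+100 from `cor_probs`, with strands assigned ~50/50
#' and the 201-base window written (reverse-complemented on the minus
#' strand) into the forward assembly. Two guards keep planted truth exactly
#' recoverable by maximal-tail trimming and zero-mismatch mapping: the last
#' templated base (position -1) is never an A, and a non-artifact downstream
#' window opening with >= 12 A's is redrawn. Artifact sites instead plant a
#' genomic A-run of length 12-20 starting at position 0; their "transcripts"
#' end inside that run, so the poly(A) tail is genome-templated.
#'
#' Sites are planted non-overlapping with >= 250 bp separation (windows never
#' collide — a simplification relative to real genomes).
#'
#' @param config A [sim_config()].
#' @return List of class `sim_dataset`: `genome` (named character),
#'   `transcripts` (named character), `truth` (data frame: `site_id`,
#'   `chrom`, `strand`, `junction`, `utr_window`, `site_base`, `cor_window`,
#'   `tail_len`, `is_artifact`), and `config`. The truth windows are
#'   self-checked against the emitted genome before return.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  bases <- c("A", "C", "G", "T")

  chrom_ids <- sprintf("chr%d", seq_len(config$n_chroms))
  genome <- vapply(chrom_ids, function(id) {
    rand_dna(config$chrom_len, config$background_probs)
  }, character(1))

  ## non-overlapping slots of 250 bp; junction placed mid-slot so both the
  ## 201-base window and the transcript upstream context fit
  margin <- 110L + config$upstream_context
  slots_per_chrom <- (config$chrom_len - 2L * margin) %/% 250L
  slot_tab <- data.frame(
    chrom = rep(chrom_ids, each = slots_per_chrom),
    start = rep(margin + 250L * (seq_len(slots_per_chrom) - 1L),
                times = config$n_chroms)
  )
  if (nrow(slot_tab) < config$n_sites) {
    stop("infeasible packing: not enough non-overlapping slots", call. = FALSE)
  }
  pick <- sort(sample.int(nrow(slot_tab), config$n_sites))
  n_art <- round(config$frac_internal_priming * config$n_sites)
  is_artifact <- rep(FALSE, config$n_sites)
  if (n_art > 0L) {
    is_artifact[sample.int(config$n_sites, n_art)] <- TRUE
  }
  strands <- sample(c("+", "-"), config$n_sites, replace = TRUE)

  truth <- vector("list", config$n_sites)
  transcripts <- character(config$n_sites)
  tails <- integer(config$n_sites)

  for (s in seq_len(config$n_sites)) {
    chrom <- slot_tab$chrom[pick[s]]
    utr <- paste0(
      rand_dna(99L, config$utr_probs),
      rand_non_A(config$utr_probs)
    )
    if (is_artifact[s]) {
      run_len <- sample_int_range(12L, 20L)
      rest <- paste0(rand_non_A(config$cor_probs),
                     rand_dna(100L - run_len, config$cor_probs))
      down <- paste0(strrep("A", run_len), rest)
    } else {
      repeat {
        down <- rand_dna(101L, config$cor_probs)
        if (tail_run_at_start(down) < 12L) break
      }
    }
    window <- paste0(utr, down) # 201 transcript-orientation bases

    ## write the window into the forward assembly around an anchor point;
    ## on '+' transcript position p sits at forward coord anchor_point + p,
    ## on '-' at anchor_point - p, so the last templated base (p = -1) is at
    ## anchor_point - 1 resp. anchor_point + 1
    anchor_point <- slot_tab$start[pick[s]] + 100L
    chrom_seq <- genome[[chrom]]
    lo <- anchor_point - 100L # forward 0-based start of the 201-base window
    if (strands[s] == "+") {
      junction <- anchor_point - 1L
      substr(chrom_seq, lo + 1L, lo + 201L) <- window
    } else {
      junction <- anchor_point + 1L
      substr(chrom_seq, lo + 1L, lo + 201L) <- revcomp(window)
    }
    genome[[chrom]] <- chrom_seq

    if (is_artifact[s]) {
      ## transcript ends inside the planted genomic A-run
      run_here <- tail_run_at_start(down)
      tails[s] <- sample_int_range(12L, run_here)
      transcripts[s] <- paste0(upstream_ctx(chrom_seq, strands[s], anchor_point,
                                            config$upstream_context),
                               utr, strrep("A", tails[s]))
    } else {
      tails[s] <- sample_int_range(config$tail_len_range[1L], config$tail_len_range[2L])
      transcripts[s] <- paste0(upstream_ctx(chrom_seq, strands[s], anchor_point,
                                            config$upstream_context),
                               utr, strrep("A", tails[s]))
    }
    truth[[s]] <- data.frame(
      site_id = sprintf("site_%04d", s), chrom = chrom, strand = strands[s],
      junction = as.integer(junction),
      utr_window = utr, site_base = substr(down, 1L, 1L),
      cor_window = substr(down, 2L, 101L),
      tail_len = tails[s], is_artifact = is_artifact[s],
      stringsAsFactors = FALSE
    )
  }
  truth <- do.call(rbind, truth)
  names(transcripts) <- truth$site_id

  n_dup <- round(config$frac_duplicates * length(transcripts))
  if (n_dup > 0L) {
    dup_idx <- sample.int(length(transcripts), n_dup, replace = n_dup > length(transcripts))
    dups <- transcripts[dup_idx]
    names(dups) <- sprintf("dup_%04d", seq_len(n_dup))
    transcripts <- c(transcripts, dups)
  }

  out <- structure(
    list(genome = genome, transcripts = transcripts, truth = truth,
         config = config),
    class = "sim_dataset"
  )
  validate_truth(out)
  out
}

## transcript-orientation context immediately upstream of the 3'UTR window;
## coordinates are relative to the anchor point (forward coord of the site
## base on '+', of its mirror on '-')
upstream_ctx <- function(chrom_seq, strand, anchor_point, len) {
  if (len == 0L) return("")
  if (strand == "+") {
    lo <- anchor_point - 100L - len # 0-based
    substr(chrom_seq, lo + 1L, lo + len)
  } else {
    lo <- anchor_point + 101L # 0-based start of context on forward strand
    revcomp(substr(chrom_seq, lo + 1L, lo + len))
  }
}

tail_run_at_start <- function(x) {
  m <- regexpr("^A+", x)
  if (m > 0L) attr(m, "match.length") else 0L
}

#' Validate a truth table against its emitted genome
#'
#' Recomputes every truth window from the genome at the recorded
#' coordinates, in transcript orientation, and stops on any disagreement.
#'
#' @param dataset A `sim_dataset` (or a list with `genome` and `truth`).
#' @return `TRUE`, invisibly.
#' @export
validate_truth <- function(dataset) {
  gs <- genome_store(dataset$genome)
  tr <- dataset$truth
  for (i in seq_len(nrow(tr))) {
    s <- call_site(tr$chrom[i], tr$strand[i], tr$junction[i],
                   anchor = tr$utr_window[i], genome = gs,
                   tail_len = tr$tail_len[i])
    if (is.null(s) || s$site_base != tr$site_base[i] ||
        s$cor_window != tr$cor_window[i]) {
      stop("truth self-check failed for ", tr$site_id[i], call. = FALSE)
    }
    ## the recorded upstream window must be genome-templated too
    seq <- gs$records[[match(tr$chrom[i], names(gs$records))]]
    utr_obs <- if (tr$strand[i] == "+") {
      substr(seq, tr$junction[i] - 98L, tr$junction[i] + 1L)
    } else {
      revcomp(substr(seq, tr$junction[i] + 1L, tr$junction[i] + 100L))
    }
    if (utr_obs != tr$utr_window[i]) {
      stop("truth upstream window mismatch for ", tr$site_id[i], call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Fragment transcripts into short reads
#'
#' Emulates library fragmentation: every transcript contributes its
#' 3'-terminal fragment (so true tails stay detectable), plus `n_internal`
#' fragments whose 3' ends fall at random internal positions across the
#' pooled transcripts (sequencing-depth style sampling). Internal fragments
#' ending just after an A-rich stretch present fragmentation-created false
#' tails, exactly the artifact deep-sequencing reads suffer from.
#'
#' @param transcripts Named character vector of transcript sequences.
#' @param config A `sim_config` with `read_mode = "fragmented"`; fragment
#'   lengths are drawn uniformly from `read_len_range`, whose minimum must
#'   be at least 92 (an 80-base anchor plus a 12-base tail).
#' @param n_internal Number of internal fragments to sample (default
#'   `2 * length(transcripts)`).
#' @return Named character vector of reads.
#' @export
fragment_reads <- function(transcripts, config,
                           n_internal = 2L * length(transcripts)) {
  stopifnot(inherits(config, "sim_config"))
  if (config$read_mode != "fragmented") {
    stop("config$read_mode must be 'fragmented'", call. = FALSE)
  }
  if (config$read_len_range[1L] < 92L) {
    stop("fragment length must be >= anchor length (80) + minimum tail (12)",
         call. = FALSE)
  }
  lens_t <- nchar(transcripts)
  n_t <- length(transcripts)

  ## guaranteed 3'-terminal fragments
  term_len <- pmin(lens_t,
                   sample_int_range(config$read_len_range[1L],
                                    config$read_len_range[2L], n_t))
  terminal <- substr(transcripts, lens_t - term_len + 1L, lens_t)
  names(terminal) <- paste0(names(transcripts), "_3p")

  if (n_internal > 0L) {
    idx <- sample.int(n_t, n_internal, replace = TRUE, prob = lens_t)
    ends <- 1L + floor(stats::runif(n_internal) * lens_t[idx])
    flen <- sample_int_range(config$read_len_range[1L],
                             config$read_len_range[2L], n_internal)
    starts <- pmax(1L, ends - flen + 1L)
    internal <- substr(transcripts[idx], starts, ends)
    names(internal) <- sprintf("frag_%06d", seq_len(n_internal))
    reads <- c(terminal, internal)
  } else {
    reads <- terminal
  }
  reads[nchar(reads) > 0L]
}

#' Write a simulated dataset to FASTA + TSV files
#'
#' @param dataset A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths (`genome`,
#'   `transcripts`, `truth`), invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    transcripts = file.path(dir, "transcripts.fa"),
    truth = file.path(dir, "truth.tsv")
  )
  write_fasta(dataset$genome, paths[["genome"]])
  write_fasta(dataset$transcripts, paths[["transcripts"]])
  utils::write.table(dataset$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
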