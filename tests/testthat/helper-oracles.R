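# Independent oracles used across the suite. These deliberately re-derive
# results by brute force / literal stepping, sharing no code with the
# package implementation they check.

random_seq <- function(n, alphabet = c("A", "C", "G", "T"), probs = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = probs), collapse = "")
}

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# quadratic-time scan of every offset on both strands
oracle_match_scan <- function(pattern, records) {
  L <- nchar(pattern)
  rc <- oracle_revcomp(pattern)
  hits <- list()
  for (chrom in names(records)) {
    seq <- records[[chrom]]
    n <- nchar(seq)
    if (n < L) next
    for (off in seq_len(n - L + 1L)) {
      piece <- substr(seq, off, off + L - 1L)
      if (piece == pattern) {
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = chrom, strand = "+", junction = off + L - 2L)
      }
      if (piece == rc) {
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = chrom, strand = "-", junction = off - 1L)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(chrom = character(), strand = character(),
                      junction = integer()))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$chrom, out$junction, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-letter tally of a composition, counting only ACGT
oracle_tally <- function(x) {
  chars <- strsplit(paste(x, collapse = ""), "")[[1]]
  counts <- vapply(c("A", "C", "G", "T"), function(b) sum(chars == b),
                   numeric(1))
  counts
}

# literal protected Duncan stepping on summary statistics: raw range tests
# first, then protection propagated to a fixpoint, letters from the pair
# relation
oracle_duncan <- function(means, ns, mse, dfe, alpha = 0.05) {
  k <- length(means)
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  nn <- ns[ord]
  raw_ns <- matrix(FALSE, k, k)
  diag(raw_ns) <- TRUE
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) {
      p <- j - i + 1
      if (mse == 0) {
        raw_ns[i, j] <- (m[i] - m[j]) == 0
      } else {
        q <- qtukey((1 - alpha)^(p - 1), p, dfe)
        nh <- 2 / (1 / nn[i] + 1 / nn[j])
        raw_ns[i, j] <- (m[i] - m[j]) <= q * sqrt(mse / nh)
      }
    }
  }
  ns_mat <- raw_ns
  repeat {
    changed <- FALSE
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        if (!ns_mat[i, j]) {
          wider <- FALSE
          for (a in 1:i) {
            for (b in j:k) {
              if ((a < i || b > j) && ns_mat[a, b]) wider <- TRUE
            }
          }
          if (wider) {
            ns_mat[i, j] <- TRUE
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  pair_ns <- function(i, j) ns_mat[min(i, j), max(i, j)]
  list(order = names(m), means = m, pair_ns = Vectorize(pair_ns))
}

# do two groups share at least one letter in a duncan_mrt table?
share_letter <- function(tab, g1, g2) {
  l1 <- strsplit(tab$letters[tab$group == g1], "")[[1]]
  l2 <- strsplit(tab$letters[tab$group == g2], "")[[1]]
  length(intersect(l1, l2)) > 0
}

# raw samples with exact group means and exact MSE = target_mse (n per group
# must be 4): per-group pattern contributes SS = 5 * a^2
exact_groups <- function(means, target_mse = 1) {
  k <- length(means)
  dfe <- k * 3L
  a <- sqrt(target_mse * dfe / (5 * k))
  out <- lapply(means, function(m) m + c(-1.5, -0.5, 0.5, 1.5) * a)
  names(out) <- names(means)
  out
}
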