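#' One-way fixed-effects ANOVA
#'
#' Classical sums-of-squares decomposition across k groups. Implemented
#' directly (rather than through a model fit) so it can drive thousands of
#' small simulated analyses cheaply; equivalence with `anova(lm(...))` is
#' pinned by a test.
#'
#' @param groups Named list of numeric vectors, one per group.
#' @return List with `F`, `p`, `mse` (within-group mean square), `df_between`,
#'   `df_within`, `means`, `n` (per-group sizes), and `degenerate` (`TRUE`
#'   when both the between- and within-group sums of squares are zero, in
#'   which case `F` and `p` are `NA`).
#' @export
anova_oneway <- function(groups) {
  check_group_samples(groups, min_groups = 2L)
  n <- vapply(groups, length, integer(1))
  if (sum(n) <= length(groups)) {
    stop("total observations must exceed the number of groups", call. = FALSE)
  }
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(n * means) / sum(n)
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(seq_along(groups),
                    function(i) sum((groups[[i]] - means[i])^2), numeric(1)))
  df_b <- length(groups) - 1L
  df_w <- sum(n) - length(groups)
  mse <- ssw / df_w
  if (ssb == 0 && ssw == 0) {
    return(list(F = NA_real_, p = NA_real_, mse = 0, df_between = df_b,
                df_within = df_w, means = means, n = n, degenerate = TRUE))
  }
  f <- (ssb / df_b) / mse
  p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  list(F = f, p = p, mse = mse, df_between = df_b, df_within = df_w,
       means = means, n = n, degenerate = FALSE)
}

check_group_samples <- function(groups, min_groups = 1L) {
  if (!is.list(groups) || length(groups) < min_groups) {
    stop("need a list of at least ", min_groups, " group sample(s)",
         call. = FALSE)
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  bad <- vapply(groups, function(g) length(g) == 0L || any(!is.finite(g)),
                logical(1))
  if (any(bad)) {
    stop("group samples must be non-empty and finite: ",
         paste(names(groups)[bad], collapse = ", "), call. = FALSE)
  }
  invisible(groups)
}

## Duncan critical range for a span of p ranked means: the studentized-range
## quantile at the per-span level 1-(1-alpha)^(p-1), scaled by sqrt(MSE/n_h)
## with n_h the harmonic mean of the two compared group sizes (Kramer
## extension for unequal n).
duncan_lsr <- function(p, df_error, mse, n_i, n_j, alpha) {
  alpha_p <- 1 - (1 - alpha)^(p - 1)
  q <- stats::qtukey(alpha_p, nmeans = p, df = df_error, lower.tail = FALSE)
  n_h <- 2 / (1 / n_i + 1 / n_j)
  q * sqrt(mse / n_h)
}

## Protected stepwise range decisions over means sorted in descending order.
## Returns a logical k x k matrix nonsig[i, j] (i <= j in rank order).
## Spans are processed widest first; any span contained in a non-significant
## wider span is declared non-significant without testing (protection).
duncan_decisions <- function(means_sorted, ns_sorted, mse, df_error, alpha) {
  k <- length(means_sorted)
  nonsig <- matrix(FALSE, k, k)
  diag(nonsig) <- TRUE
  if (k == 1L) return(nonsig)
  for (width in k:2) {
    for (i in seq_len(k - width + 1L)) {
      j <- i + width - 1L
      contained <- FALSE
      if (width < k) {
        ## containers have width+1 here because we sweep widest-first and
        ## containment is transitive
        if (i > 1L && nonsig[i - 1L, j]) contained <- TRUE
        if (j < k && nonsig[i, j + 1L]) contained <- TRUE
      }
      if (contained) {
        nonsig[i, j] <- TRUE
      } else {
        diff <- means_sorted[i] - means_sorted[j]
        if (mse == 0) {
          nonsig[i, j] <- diff == 0
        } else {
          lsr <- duncan_lsr(width, df_error, mse, ns_sorted[i], ns_sorted[j],
                            alpha)
          nonsig[i, j] <- diff <= lsr
        }
      }
    }
  }
  nonsig
}

## letters from the staircase of maximal non-significant spans
duncan_letters <- function(nonsig) {
  k <- nrow(nonsig)
  reach <- vapply(seq_len(k), function(i) max(which(nonsig[i, ])), integer(1))
  ## maximal intervals [i, reach[i]] not contained in an earlier interval
  spans <- list()
  best <- 0L
  for (i in seq_len(k)) {
    if (reach[i] > best || (i > best)) {
      spans[[length(spans) + 1L]] <- c(i, reach[i])
      best <- max(best, reach[i])
    }
  }
  letters_out <- character(k)
  for (s in seq_along(spans)) {
    rng <- spans[[s]][1]:spans[[s]][2]
    letters_out[rng] <- paste0(letters_out[rng], LETTERS[s])
  }
  letters_out
}

#' Duncan's multiple range test with letter display
#'
#' Protected stepwise comparison of ranked group means using studentized-range
#' critical values that widen with the span of means compared, at the
#' span-specific significance level `1-(1-alpha)^(p-1)`. Unequal group sizes
#' use the harmonic mean of the two compared groups (Kramer extension).
#' Groups sharing a letter are not significantly different at `alpha`.
#'
#' @param groups Named list of numeric vectors, one per group.
#' @param alpha Familywise step level (default 0.05).
#' @return Object of class `duncan_mrt`: list with `table` (data frame
#'   `group`, `n`, `mean`, `letters`, in descending-mean order), `alpha`,
#'   `mse`, `df_error`, and `nonsig` (the rank-order decision matrix).
#' @export
duncan_mrt <- function(groups, alpha = 0.05) {
  groups <- check_group_samples(groups, min_groups = 2L)
  av <- anova_oneway(groups)
  ord <- order(av$means, decreasing = TRUE)
  means_sorted <- av$means[ord]
  ns_sorted <- av$n[ord]
  nonsig <- duncan_decisions(means_sorted, ns_sorted, av$mse, av$df_within,
                             alpha)
  letters_out <- duncan_letters(nonsig)
  structure(
    list(
      table = data.frame(group = names(means_sorted), n = unname(ns_sorted),
                         mean = unname(means_sorted), letters = letters_out,
                         stringsAsFactors = FALSE),
      alpha = alpha, mse = av$mse, df_error = av$df_within, nonsig = nonsig
    ),
    class = "duncan_mrt"
  )
}

#' @export
print.duncan_mrt <- function(x, digits = 2, ...) {
  cat("Duncan's multiple range test (alpha =", x$alpha, ")\n")
  tab <- x$table
  tab$mean <- round_half_up(tab$mean, digits)
  print(tab, row.names = FALSE)
  cat("Means with the same letter are not significantly different.\n")
  invisible(x)
}

#' Two-sample equal-variance (pooled) t-test, two-tailed
#'
#' Pooled-variance Student's t with `df = n_a + n_b - 2`. When the pooled
#' variance is zero and the means are equal, returns `t = 0, p = 1` flagged
#' as degenerate rather than erroring.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List with `t`, `df`, `p`, `mean_a`, `mean_b`, `degenerate`.
#' @export
t_test_equal_var <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L,
            all(is.finite(a)), all(is.finite(b)))
  df <- length(a) + length(b) - 2L
  pooled <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df
  if (pooled == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = df, p = 1, mean_a = mean(a), mean_b = mean(b),
                  degenerate = TRUE))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = df, p = 0,
                mean_a = mean(a), mean_b = mean(b), degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(a), mean_b = mean(b), degenerate = FALSE)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Observed vs product-marginal expected counts, 1 degree of freedom,
#' without continuity correction (spreadsheet CHITEST semantics).
#'
#' @param counts 2x2 matrix of non-negative counts.
#' @return List with `chi2`, `df`, `p`, `expected`.
#' @export
chi_square_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L)) || any(counts < 0) ||
      any(!is.finite(counts))) {
    stop("counts must be a 2x2 matrix of non-negative numbers", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("all row and column marginals must be positive", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = ct$expected)
}

#' Run the group-comparison battery on a long-format values table
#'
#' Utility behind the `stats` entry point: one-way ANOVA plus Duncan letters
#' over the `group` factor and, when a 2-level `supergroup` column is
#' present, an equal-variance t-test between the supergroups.
#'
#' @param df Data frame with columns `value`, `group`, and optionally
#'   `supergroup`.
#' @param alpha Significance level for the Duncan display.
#' @return List with `anova`, `duncan`, and (optionally) `t_test`.
#' @export
group_stats_table <- function(df, alpha = 0.05) {
  stopifnot(all(c("value", "group") %in% names(df)))
  groups <- split(df$value, df$group)
  out <- list(anova = anova_oneway(groups),
              duncan = duncan_mrt(groups, alpha = alpha))
  if ("supergroup" %in% names(df)) {
    lev <- unique(df$supergroup)
    if (length(lev) == 2L) {
      out$t_test <- t_test_equal_var(df$value[df$supergroup == lev[1L]],
                                     df$value[df$supergroup == lev[2L]])
      out$t_test$levels <- lev
    }
  }
  out
}
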