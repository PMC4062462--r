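test_that("anova_oneway reproduces hand-computed sums of squares", {
  same <- anova_oneway(list(g1 = c(1, 2, 3), g2 = c(1, 2, 3)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)

  shifted <- anova_oneway(list(g1 = c(1, 2, 3), g2 = c(4, 5, 6)))
  expect_equal(shifted$F, 13.5) # SSB = 13.5, MSW = 1
  expect_equal(shifted$mse, 1)
  expect_equal(shifted$df_between, 1L)
  expect_equal(shifted$df_within, 4L)

  degen <- anova_oneway(list(g1 = c(2, 2), g2 = c(2, 2)))
  expect_true(degen$degenerate)
  expect_true(is.na(degen$F))

  expect_error(anova_oneway(list(g1 = c(1, 2))), "at least 2")
  expect_error(anova_oneway(list(g1 = 1, g2 = 2)), "exceed")
})

test_that("anova_oneway agrees with anova(lm()) on random unbalanced data", {
  set.seed(301)
  for (rep in 1:5) {
    k <- sample(3:5, 1)
    groups <- lapply(seq_len(k), function(i) rnorm(sample(3:8, 1), mean = i / 2))
    names(groups) <- paste0("g", seq_len(k))
    df <- data.frame(y = unlist(groups),
                     g = rep(names(groups), lengths(groups)))
    ref <- anova(lm(y ~ g, data = df))
    got <- anova_oneway(groups)
    expect_equal(got$F, ref$`F value`[1])
    expect_equal(got$p, ref$`Pr(>F)`[1])
    expect_equal(got$mse, ref$`Mean Sq`[2])
  }
})

test_that("two-group ANOVA satisfies F = t^2", {
  set.seed(302)
  for (rep in 1:10) {
    a <- rnorm(sample(3:10, 1))
    b <- rnorm(sample(3:10, 1), mean = 0.5)
    av <- anova_oneway(list(a = a, b = b))
    tt <- t_test_equal_var(a, b)
    expect_equal(av$F, tt$t^2)
    expect_equal(av$p, tt$p)
  }
})

test_that("duncan_mrt matches hand-stepped fixtures", {
  # k = 5, n = 4, raw data constructed so group means are exact and MSE = 1
  # (error df = 15); stepped by hand with studentized-range critical values
  fix1 <- exact_groups(c(T1 = 9.8, T2 = 15.4, T3 = 17.6, T4 = 21.6, T5 = 10.8))
  d1 <- duncan_mrt(fix1)
  expect_equal(d1$mse, 1, tolerance = 1e-12)
  expect_identical(d1$table$group, c("T4", "T3", "T2", "T5", "T1"))
  expect_identical(d1$table$letters, c("A", "B", "C", "D", "D"))

  # only the top mean separates; the other four form one letter group
  fix2 <- exact_groups(c(A = 24.8, B = 24.3, C = 26.7, D = 23.2, E = 24.0))
  d2 <- duncan_mrt(fix2)
  expect_identical(d2$table$group, c("C", "A", "B", "E", "D"))
  expect_identical(d2$table$letters, c("A", "B", "B", "B", "B"))
})

test_that("duncan_mrt letter display is consistent with pairwise decisions", {
  set.seed(303)
  for (rep in 1:8) {
    k <- sample(3:6, 1)
    means <- rnorm(k, sd = sample(c(0.5, 1, 2), 1))
    names(means) <- paste0("g", seq_len(k))
    groups <- lapply(means, function(m) m + rnorm(sample(3:6, 1), sd = 0.8))
    d <- duncan_mrt(groups)
    av <- anova_oneway(groups)
    orc <- oracle_duncan(vapply(groups, mean, numeric(1)),
                         lengths(groups), av$mse, av$df_within)
    expect_identical(d$table$group, orc$order)
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        expect_equal(share_letter(d$table, orc$order[i], orc$order[j]),
                     unname(orc$pair_ns(i, j)),
                     info = sprintf("rep %d pair %d-%d", rep, i, j))
      }
    }
  }
})

test_that("duncan_mrt handles degenerate and forced cases", {
  allsame <- duncan_mrt(list(g1 = c(5, 5, 5), g2 = c(5, 5, 5)))
  expect_identical(allsame$table$letters, c("A", "A"))

  far <- duncan_mrt(list(lo = rnorm(5, 0, 0.01), hi = rnorm(5, 100, 0.01)))
  expect_identical(far$table$letters, c("A", "B"))

  expect_error(duncan_mrt(list(g1 = c(1, 2, 3))), "at least 2")
})

test_that("duncan letters are invariant to relabeling and shifts", {
  set.seed(304)
  groups <- lapply(c(a = 0, b = 1.5, c = 0.2), function(m) m + rnorm(5))
  d0 <- duncan_mrt(groups)
  shifted <- lapply(groups, function(g) g + 100)
  d1 <- duncan_mrt(shifted)
  expect_identical(d0$table$letters, d1$table$letters)
  expect_identical(d0$table$group, d1$table$group)
  relabeled <- stats::setNames(groups, c("x", "y", "z"))
  d2 <- duncan_mrt(relabeled)
  expect_identical(d0$table$letters, d2$table$letters)
})

test_that("balanced two-mean step equals the Duncan-adjusted LSD", {
  # exact fixture (k = 3, n = 4, MSE = 1, dfe = 9): the full 2.4 range
  # exceeds its critical value, so the adjacent p = 2 comparisons are
  # tested, and must coincide with an LSD using the Duncan critical value
  groups <- exact_groups(c(g1 = 0, g2 = 1.2, g3 = 2.4))
  av <- anova_oneway(groups)
  d <- duncan_mrt(groups)
  m <- sort(vapply(groups, mean, numeric(1)), decreasing = TRUE)
  lsd <- qtukey(0.95, 2, av$df_within) * sqrt(av$mse / 4)
  expect_false(d$nonsig[1, 3])
  expect_equal(unname(!d$nonsig[1, 2]), unname((m[[1]] - m[[2]]) > lsd))
  expect_equal(unname(!d$nonsig[2, 3]), unname((m[[2]] - m[[3]]) > lsd))
})

test_that("null data share a single letter at the protected level", {
  # two groups from one generator: the p = 2 Duncan step runs at exactly
  # alpha = 0.05, so a shared letter is expected in 95% of replicates
  set.seed(306)
  reps <- 400
  single <- 0
  for (r in seq_len(reps)) {
    d <- duncan_mrt(list(g1 = rnorm(5), g2 = rnorm(5)))
    if (all(d$table$letters == "A")) single <- single + 1
  }
  expect_gte(single / reps, 0.93)
})

test_that("t_test_equal_var is a pooled two-tailed t-test", {
  x <- c(1, 2, 3, 4)
  same <- t_test_equal_var(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  set.seed(307)
  a <- rnorm(6)
  b <- rnorm(9, 1)
  ab <- t_test_equal_var(a, b)
  ba <- t_test_equal_var(b, a)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p, ba$p)
  expect_equal(ab$df, 13L)

  degen <- t_test_equal_var(c(2, 2), c(2, 2))
  expect_true(degen$degenerate)
  expect_equal(degen$p, 1)
})

test_that("chi_square_2x2 uses Pearson expected counts without correction", {
  res <- chi_square_2x2(matrix(c(90, 10, 60, 40), 2, byrow = TRUE))
  expect_equal(res$chi2, 24) # expected counts 75/25/75/25
  expect_equal(res$df, 1L)
  expect_equal(res$p, pchisq(24, 1, lower.tail = FALSE))

  null <- chi_square_2x2(matrix(c(30, 70, 30, 70), 2, byrow = TRUE))
  expect_equal(null$chi2, 0)
  expect_equal(null$p, 1)

  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "marginals")
  expect_error(chi_square_2x2(matrix(c(-1, 5, 5, 5), 2)), "non-negative")
})

test_that("chi-square p-values are near-uniform under equal A rates", {
  set.seed(308)
  ps <- replicate(200, {
    a1 <- rbinom(1, 600, 0.3)
    a2 <- rbinom(1, 600, 0.3)
    chi_square_2x2(matrix(c(a1, 600 - a1, a2, 600 - a2), 2, byrow = TRUE))$p
  })
  expect_gt(mean(ps), 0.40)
  expect_lt(mean(ps), 0.60)
  expect_lt(mean(ps < 0.05), 0.11)
})

test_that("group_stats_table runs the battery from a long table", {
  tab <- distal_utr50_table()
  df <- data.frame(value = table_ua_ratios(tab), group = tab$group,
                   supergroup = tab$supergroup)
  res <- group_stats_table(df)
  expect_s3_class(res$duncan, "duncan_mrt")
  expect_equal(res$t_test$df, 16L)
  expect_lt(res$t_test$p, 0.05)
})
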