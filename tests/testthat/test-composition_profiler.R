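# construct a site-table row directly from known window strings
fake_site <- function(utr, site_base, cor, chrom = "c1", junction = 500L,
                      strand = "+") {
  data.frame(chrom = chrom, junction = junction, strand = strand,
             tail_len = 12L, site_base = site_base,
             utr_window = utr, cor_window = cor,
             downstream_A_run = 0L, six_base_A_count = 0L, ip_flag = FALSE,
             stringsAsFactors = FALSE)
}

random_sites <- function(n) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    fake_site(random_seq(100), random_seq(1), random_seq(100),
              junction = 500L + 300L * i)
  }))
}

test_that("positional_profile counts one base per site per position", {
  set.seed(201)
  one <- fake_site(strrep("G", 100), "T", strrep("C", 100))
  p <- positional_profile(one)
  expect_equal(dim(p$counts), c(201L, 4L))
  expect_true(all(rowSums(p$counts) == 1))
  expect_equal(unname(p$counts["-1", ]), c(0, 0, 1, 0))
  expect_equal(unname(p$counts["0", ]), c(0, 0, 0, 1))
  expect_equal(unname(p$counts["1", ]), c(0, 1, 0, 0))

  two <- rbind(one, one)
  p2 <- positional_profile(two)
  expect_equal(p2$counts, 2 * p$counts)

  expect_error(positional_profile(one[0, ]), "degenerate")
})

test_that("positional_profile equals an independent per-site loop", {
  set.seed(202)
  sites <- random_sites(50)
  p <- positional_profile(sites)
  seqs <- paste0(sites$utr_window, sites$site_base, sites$cor_window)
  for (pos in c(-100, -37, -1, 0, 1, 55, 100)) {
    col <- pos + 101
    expected <- table(factor(substr(seqs, col, col),
                             levels = c("A", "C", "G", "T")))
    expect_equal(unname(p$counts[as.character(pos), ]),
                 as.numeric(expected))
  }
  expect_true(all(rowSums(p$counts) == 50))
})

test_that("profiles are additive over site sets", {
  set.seed(203)
  a <- random_sites(8)
  b <- random_sites(5)
  pa <- positional_profile(a)
  pb <- positional_profile(b)
  pc <- positional_profile(rbind(a, b))
  expect_equal(pc$counts, pa$counts + pb$counts)
  expect_equal(pc$n_sites, pa$n_sites + pb$n_sites)
})

test_that("window_composition pools counts over the window", {
  set.seed(204)
  s <- fake_site(random_seq(100), "G", strrep("A", 100))
  p <- positional_profile(s)
  cor <- window_composition(p, window_spec("COR100"))
  expect_equal(cor$pct[["A"]], 100)
  expect_equal(cor$n_bases, 100)
  expect_identical(cor$alphabet, "RNA")

  # four percentages always sum to 100
  sites <- random_sites(20)
  p <- positional_profile(sites)
  for (w in c("UTR100", "COR100", "DISTAL50", "SIXBASE")) {
    comp <- window_composition(p, window_spec(w))
    expect_equal(sum(comp$pct), 100, tolerance = 1e-12)
  }

  # SIXBASE A percentage agrees with the per-site 6-base A counts
  seqs6 <- paste0(sites$site_base, substr(sites$cor_window, 1, 5))
  six_counts <- vapply(strsplit(seqs6, ""), function(x) sum(x == "A"),
                       numeric(1))
  sx <- window_composition(p, window_spec("SIXBASE"))
  expect_equal(sx$pct[["A"]], 100 * sum(six_counts) / (6 * nrow(sites)))
})

test_that("cor_includes_site shifts the COR window to 0..+99", {
  s <- fake_site(random_seq(100), "A", paste0(strrep("G", 99), "T"))
  p <- positional_profile(s)
  excl <- window_composition(p, window_spec("COR100"))
  incl <- window_composition(p, window_spec("COR100", cor_includes_site = TRUE))
  expect_equal(excl$pct[["A"]], 0)
  expect_equal(incl$pct[["A"]], 1)
  expect_equal(incl$pct[["TU"]], 0) # trailing T at +100 now outside
})

test_that("region/genome ratios divide matched bases, U to T", {
  region <- base_composition(25, 15, 10, 50)
  genome <- base_composition(25, 25, 25, 25, n_bases = 400, alphabet = "DNA")
  rt <- region_genome_ratio(region, genome)
  expect_equal(unname(rt$ratio), c(1, 0.6, 0.4, 2))

  same <- region_genome_ratio(genome, genome)
  expect_equal(unname(same$ratio), c(1, 1, 1, 1))
})

test_that("group summaries average per-species ratios, not ratios of means", {
  # two species where the two orders of operation differ
  r1 <- region_genome_ratio(base_composition(25, 25, 10, 40),
                            base_composition(25, 25, 30, 20, 100, "DNA"))
  r2 <- region_genome_ratio(base_composition(25, 25, 40, 10),
                            base_composition(25, 25, 10, 40, 100, "DNA"))
  mean_of_ratios <- mean(c(r1$ratio[["TU"]], r2$ratio[["TU"]]))
  ratio_of_means <- mean(c(40, 10)) / mean(c(20, 40))
  expect_false(isTRUE(all.equal(mean_of_ratios, ratio_of_means)))
  expect_equal(mean_of_ratios, (40 / 20 + 10 / 40) / 2)
})

test_that("per-position ratio track matches single-position recomputation", {
  set.seed(206)
  genome <- base_composition(25, 25, 25, 25, n_bases = 1000, alphabet = "DNA")
  sites <- random_sites(30)
  sites$cor_window <- paste0(substr(sites$cor_window, 1, 2), "T",
                             substr(sites$cor_window, 4, 100))
  p <- positional_profile(sites)
  track <- per_position_ratio(p, genome, "U")
  expect_equal(unname(track[["3"]]), 4) # all sites U at +3, genome T = 25%
  expect_length(track, 201)
  for (pos in c(-50, 0, 3, 80)) {
    cnt <- p$counts[as.character(pos), "T"]
    expect_equal(unname(track[[as.character(pos)]]),
                 (cnt / p$n_sites * 100) / 25)
  }

  # uniform sites over a uniform genome hover near 1
  big <- random_sites(400)
  trackA <- per_position_ratio(positional_profile(big), genome, "A")
  expect_true(all(abs(trackA - 1) < 0.35))
})

test_that("ua_ratio reproduces published distal-window U/A values", {
  tab <- distal_utr50_table()
  ratios <- table_ua_ratios(tab)
  expect_equal(unname(round_half_up(ratios[["Solanum tuberosum"]], 2)), 1.60)
  expect_equal(unname(round_half_up(ratios[["Caenorhabditis elegans"]], 2)), 1.54)
  expect_equal(unname(round_half_up(ratios[["Zea mays"]], 2)), 1.38)
  expect_equal(unname(round_half_up(ratios[["Apis mellifera"]], 2)), 0.96)

  expect_equal(ua_ratio(base_composition(30, 20, 20, 30)), 1)
  expect_warning(r0 <- ua_ratio(base_composition(0, 30, 30, 40)), "undefined")
  expect_true(is.na(r0))
})

test_that("half-up rounding matches published table conventions", {
  # ties go away from zero (base round() would give 0.12 / 1.2)
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(1.25, 1), 1.3)
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_equal(round_half_up(1.604, 2), 1.60)
})
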