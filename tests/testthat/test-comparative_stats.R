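# Profiles, rank-sum machinery, group comparisons, trends, localization.

mk_metadata <- function(n, kingdom = "EUBACTERIA", oxygen = "AEROBIC",
                        habitat = "MULTIPLE", gram = "NEGATIVE", size = 5) {
  data.frame(taxon_id = sprintf("t%03d", seq_len(n)), organism = "o",
             kingdom = kingdom, phylum = "Firmicutes", gram = gram,
             habitat = habitat, oxygen = oxygen, genome_size_mb = size,
             stringsAsFactors = FALSE)
}

mk_profiles <- function(counts, ...) {
  md <- mk_metadata(length(counts), ...)
  md$n_pdz_proteins <- counts
  md$n_pdz_domains <- counts
  md
}

test_that("profiles count proteins, domains, multidomain and localization", {
  arch <- data.frame(
    protein_id = c("pa", "pb"), taxon_id = "t001",
    architecture = c("PDZ-PDZ", "PDZ-Trypsin"), n_domains = 2L,
    n_other_domains = c(0L, 1L), tandem_pdz_count = c(2L, 1L),
    has_pdz = TRUE, pdz_flavor = "CANONICAL", stringsAsFactors = FALSE)
  loc <- data.frame(protein_id = "pa", category = "TM",
                    stringsAsFactors = FALSE)
  md <- mk_metadata(2)
  prof <- build_profiles(arch, loc, md)
  p1 <- prof[prof$taxon_id == "t001", ]
  expect_equal(p1$n_pdz_proteins, 2L)
  expect_equal(p1$n_pdz_domains, 3L)
  # the PDZ-repeat-only protein is not multidomain
  expect_equal(p1$n_multidomain, 1L)
  expect_equal(p1$loc_TM, 1L)
  expect_equal(p1$loc_NAN, 1L)   # pb has no localization call
  # genome without PDZ proteins gets zero counts
  p2 <- prof[prof$taxon_id == "t002", ]
  expect_equal(p2$n_pdz_proteins, 0L)
  # localization tallies always sum to the protein count
  locsum <- rowSums(prof[, paste0("loc_", c("TM", "SP", "TMSP", "CYT", "NAN"))])
  expect_equal(unname(locsum), prof$n_pdz_proteins)

  bad <- arch; bad$taxon_id <- "t999"
  expect_error(build_profiles(bad, loc, md), "t999")
})

test_that("exact enumeration reproduces known tail probabilities", {
  expect_equal(exact_rank_sum_p(c(1, 2), c(3, 4), "less"), 1 / 6)
  expect_equal(exact_rank_sum_p(c(5), c(1), "greater"), 0.5)
  # bound: p can never undercut one over the number of labelings
  set.seed(7)
  for (i in 1:20) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    p <- exact_rank_sum_p(x, y, sample(c("greater", "less", "two.sided"), 1))
    expect_gte(p, 1 / choose(n1 + n2, n1))
    expect_lte(p, 1)
  }
  expect_error(exact_rank_sum_p(rnorm(10), rnorm(10)), "<= 14")
})

test_that("exact enumeration agrees with the distribution-based oracle", {
  set.seed(13)
  for (i in 1:25) {
    n1 <- sample(3:7, 1); n2 <- sample(3:7, 1)
    v <- sample(10000, n1 + n2)   # tie-free
    x <- v[1:n1]; y <- v[-(1:n1)]
    for (alt in c("greater", "less", "two.sided")) {
      expect_equal(exact_rank_sum_p(x, y, alt),
                   stats::wilcox.test(x, y, alternative = alt,
                                      exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
  }
})

test_that("rank-sum test: method selection, statistics, degenerate input", {
  r <- rank_sum_test(c(1, 2), c(3, 4), alternative = "less")
  expect_equal(r$method, "EXACT")
  expect_equal(r$p, 1 / 6)
  expect_equal(r$U, 0)
  expect_equal(r$n1 + r$n2, 4L)

  tied <- rank_sum_test(c(1, 1, 2, 5), c(1, 2, 2, 7), "two.sided")
  expect_equal(tied$method, "NORMAL")
  expect_true(r$U >= 0 && r$U <= r$n1 * r$n2)

  same <- rank_sum_test(c(1, 2, 3), c(1, 2, 3), "two.sided")
  expect_gte(same$p, 0.99)
  const <- rank_sum_test(rep(2, 5), rep(2, 5), "greater")
  expect_equal(const$p, 1)
  expect_error(rank_sum_test(numeric(), 1:3), "non-empty")
})

test_that("normal approximation matches the reference implementation", {
  set.seed(19)
  for (i in 1:40) {
    x <- rpois(sample(5:40, 1), 5); y <- rpois(sample(5:40, 1), 6)
    for (alt in c("greater", "less", "two.sided")) {
      ours <- rank_sum_test(x, y, alt, exact_max = 0L)
      ref <- stats::wilcox.test(x, y, alternative = alt, exact = FALSE,
                                correct = TRUE)
      expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
      expect_equal(ours$U, unname(ref$statistic))
    }
  }
})

test_that("group comparisons detect a planted oxygen effect directionally", {
  set.seed(29)
  prof <- mk_profiles(c(rpois(30, 8), rpois(30, 3)),
                      oxygen = rep(c("AEROBIC", "ANAEROBIC"), each = 30))
  res <- compare_groups(prof, "OXYGEN")
  expect_equal(nrow(res), 1L)
  expect_equal(res$group_hi, "AEROBIC")
  expect_lt(res$p, 0.05)
  expect_true(res$significant)

  # NA-category genomes are excluded, small groups skipped with a warning
  prof$oxygen[1] <- NA
  expect_silent(compare_groups(prof, "OXYGEN"))
  tiny <- mk_profiles(c(5, 6, 1), gram = c("NEGATIVE", "NEGATIVE", "POSITIVE"))
  expect_warning(res2 <- compare_groups(tiny, "GRAM"), "fewer than 2")
  expect_equal(nrow(res2), 0L)
})

test_that("habitat panel compares adjacent ordered categories", {
  set.seed(37)
  habs <- c("SPECIALIZED", "HOST_ASSOCIATED", "MULTIPLE", "AQUATIC",
            "TERRESTRIAL")
  prof <- mk_profiles(rpois(50, rep(c(2, 3, 5, 8, 9), each = 10)),
                      habitat = rep(habs, each = 10))
  res <- compare_groups(prof, "HABITAT")
  expect_equal(nrow(res), 4L)
  expect_equal(res$group_lo, habs[-5])
  expect_equal(res$group_hi, habs[-1])
  allp <- compare_groups(prof, "HABITAT", all_pairs = TRUE)
  expect_equal(nrow(allp), choose(5, 2))
  adj <- compare_groups(prof, "HABITAT", adjust = "BH")
  expect_true(all(adj$p >= res$p - 1e-12))
})

test_that("size trend: perfect, planted, and permuted relations", {
  prof <- mk_profiles(1:12, size = seq(2, 9, length.out = 12))
  tr <- size_trend(prof, "EUBACTERIA")
  expect_equal(tr$rho, 1)
  expect_lt(tr$p, 0.01)

  set.seed(51)
  prof$n_pdz_proteins <- sample(prof$n_pdz_proteins)
  tr2 <- size_trend(prof, "EUBACTERIA")
  expect_lt(abs(tr2$rho), 0.6)

  flat <- mk_profiles(rep(3L, 6))
  expect_error(size_trend(flat, "EUBACTERIA"), "constant")
  expect_error(size_trend(prof[1:3, ], "EUBACTERIA"), "at least 4")
})

test_that("localization fractions normalize over known categories", {
  prof <- mk_profiles(c(10, 2))
  prof$loc_TM <- c(5L, 0L); prof$loc_SP <- c(3L, 0L)
  prof$loc_TMSP <- c(1L, 0L); prof$loc_CYT <- c(1L, 0L)
  prof$loc_NAN <- c(0L, 2L)
  lf <- localization_fractions(prof, "ALL")
  expect_equal(lf$frac_CYT, 0.1)
  expect_equal(lf$n_known, 10)
  expect_equal(lf$frac_TM + lf$frac_SP + lf$frac_TMSP + lf$frac_CYT, 1,
               tolerance = 1e-9)
  by_k <- localization_fractions(prof, "KINGDOM")
  expect_equal(by_k$group, "EUBACTERIA")
  none <- prof; none[, paste0("loc_", c("TM", "SP", "TMSP", "CYT"))] <- 0L
  expect_error(localization_fractions(none, "ALL"), "known localization")
})
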