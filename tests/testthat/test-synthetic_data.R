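# The cohort generator: determinism, planted truth, validation.

test_that("config validation rejects inconsistent mixes and rates", {
  expect_error(cohort_config(kingdom_mix = c(EUBACTERIA = 0.7, ARCHAEA = 0.2,
                                             FUNGI = 0.2)), "sum to 1")
  expect_error(cohort_config(tandem_rate = 1.5), "tandem_rate")
  expect_error(cohort_config(n_genomes = 0), "n_genomes")
  bad_plant <- list(list(family = "RSEP", neighbors = c("a", "b"),
                         gaps = c(10L)))
  expect_error(cohort_config(neighborhood_plants = bad_plant),
               "one gap per neighbor")
  expect_s3_class(cohort_config(), "cohort_config")
})

test_that("a fixed seed reproduces the cohort byte for byte", {
  d1 <- tempfile("c1"); d2 <- tempfile("c2")
  dir.create(d1); dir.create(d2)
  cc <- cohort_config(n_genomes = 5, seed = 99)
  generate_cohort(cc, d1)
  generate_cohort(cc, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  # a different seed changes realizations
  generate_cohort(cohort_config(n_genomes = 5, seed = 100), d2)
  sums1 <- tools::md5sum(file.path(d1, f1))
  sums2 <- tools::md5sum(file.path(d2, list.files(d2, recursive = TRUE)))
  expect_false(identical(unname(sums1), unname(sums2)))
})

test_that("tandem_rate zero plants exactly one PDZ hit per protein", {
  co <- tiny_cohort(n_genomes = 5, seed = 12, tandem_rate = 0)
  expect_true(all(co$truth$proteins$n_pdz_hits == 1L))
})

test_that("planted decoys above threshold never reach architectures", {
  co <- tiny_cohort(n_genomes = 8, seed = 13, decoy_above_rate = 4)
  dec <- co$truth$decoys
  expect_gt(nrow(dec), 0L)
  work <- tempfile("w"); run_stages(co$dir, work, "ingest")
  doms <- read.delim(file.path(work, "domains.tsv"))
  dom_key <- paste(doms$protein_id, doms$domain_id, doms$start)
  dropped <- dec[!dec$kept_scan, ]
  expect_false(any(paste(dropped$protein_id, dropped$domain_id,
                         dropped$start) %in% dom_key))
  # planted family hits all survive: every planted protein has an
  # architecture containing a PDZ identifier
  arch <- read.delim(file.path(work, "architectures.tsv"))
  expect_setequal(arch$protein_id, co$truth$proteins$protein_id)
  expect_true(all(arch$has_pdz))
})

test_that("planted neighborhoods obey the gap and strand rules", {
  anchor <- make_genes(1000, 2200, "+", gene_names = "rseP")
  layout <- plant_neighborhood(anchor, c("frr", "rpsB"), c(20L, 60L))
  expect_equal(nrow(layout), 3L)
  cl <- find_neighborhood(layout, 1L, max_gap = 50L)
  expect_equal(nrow(cl$members), 2L)   # the 60-gap gene is beyond the rule
  expect_equal(cl$members$gene_name, c("rseP", "frr"))
  cl300 <- find_neighborhood(layout, 1L, max_gap = 300L)
  expect_equal(nrow(cl300$members), 3L)

  # a minus-strand interloper breaks the chain even within the gap rule
  broken <- layout
  broken$strand[2] <- "-"
  cl_b <- find_neighborhood(broken, 1L, max_gap = 300L)
  expect_equal(nrow(cl_b$members), 1L)

  expect_error(plant_neighborhood(anchor, c("a", "b"), c(-5L, 10L)), ">= 0")
})

test_that("count model hits its configured expectations across seeds", {
  cfg <- cohort_config()
  md <- data.frame(kingdom = "EUBACTERIA", oxygen = "AEROBIC",
                   habitat = "MULTIPLE", genome_size_mb = 5,
                   stringsAsFactors = FALSE)
  md <- md[rep(1, 400), ]
  means <- vapply(1:20, function(s) {
    set.seed(s)
    mean(draw_pdz_counts(md, cfg))
  }, numeric(1))
  mu <- unname(cfg$oxygen_means["AEROBIC"])   # multipliers are all 1 here
  se <- stats::sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - mu), 3 * se + 1e-9)
  # negative binomial overdispersion: variance exceeds the mean
  set.seed(1)
  draws <- draw_pdz_counts(md, cfg)
  expect_gt(stats::var(draws), mean(draws))
})

test_that("planted family frequencies drive the generated cohort", {
  co <- tiny_cohort(n_genomes = 25, seed = 14)
  tr <- co$truth$proteins
  expect_gt(nrow(tr), 60)
  frac_uncl <- mean(tr$family == "UNCLASSIFIED")
  # planted at 7%; binomial slack at this cohort size
  expect_lt(abs(frac_uncl - 0.07), 3 * sqrt(0.07 * 0.93 / nrow(tr)) + 0.01)
  cls <- tr$family[tr$family != "UNCLASSIFIED"]
  frac_prot <- mean(cls %in% protease_families())
  expect_lt(abs(frac_prot - 0.88), 3 * sqrt(0.88 * 0.12 / length(cls)) + 0.01)
})
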