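# Threshold filtering, overlap resolution, cross-database merge,
# architecture construction.

test_that("threshold filtering honors both cutoffs inclusively, per mode", {
  h <- make_hit(seq_evalue = 0.005, dom_evalue = 0.02)
  expect_equal(nrow(filter_hits(h, threshold_policy("SEARCH"))), 1L)
  expect_equal(nrow(filter_hits(h, threshold_policy("SCAN"))), 0L)
  # thresholds are inclusive
  boundary <- make_hit(seq_evalue = 0.01, dom_evalue = 0.03)
  expect_equal(nrow(filter_hits(boundary, threshold_policy("SEARCH"))), 1L)
  # seq threshold alone can reject
  seq_hi <- make_hit(seq_evalue = 0.02, dom_evalue = 1e-10)
  expect_equal(nrow(filter_hits(seq_hi, threshold_policy("SEARCH"))), 0L)
  expect_error(threshold_policy("SEARCH", seq_evalue_max = 0), "> 0")
})

test_that("filtering is idempotent and monotone in the thresholds", {
  set.seed(5)
  hits <- do.call(rbind, lapply(1:60, function(i) {
    make_hit(protein_id = "p", domain_id = sample(LETTERS, 1),
             seq_evalue = 10^runif(1, -6, 0), dom_evalue = 10^runif(1, -6, 0),
             start = i * 10, end = i * 10 + 50)
  }))
  tight <- threshold_policy("SCAN")
  kept <- filter_hits(hits, tight)
  expect_identical(filter_hits(kept, tight), kept)
  for (loose in list(threshold_policy("SEARCH"),
                     threshold_policy("SCAN", 0.05, 0.05))) {
    kept_loose <- filter_hits(hits, loose)
    expect_true(all(paste(kept$start, kept$dom_evalue) %in%
                      paste(kept_loose$start, kept_loose$dom_evalue)))
  }
})

test_that("overlap resolution keeps the max-score compatible subset", {
  one <- make_hit()
  expect_identical(resolve_overlaps(one), one)

  # A(1-100, s=50) vs B(50-150, s=40): overlap 51 > 20% of 100 -> only A
  ab <- make_hits(
    make_hit(domain_id = "A", start = 1, end = 100, bit_score = 50),
    make_hit(domain_id = "B", start = 50, end = 150, bit_score = 40))
  expect_equal(resolve_overlaps(ab)$domain_id, "A")

  # A(1-100, s=50), B(95-200, s=40): overlap 6 <= 20% of shorter -> both
  ab2 <- make_hits(
    make_hit(domain_id = "A", start = 1, end = 100, bit_score = 50),
    make_hit(domain_id = "B", start = 95, end = 200, bit_score = 40))
  expect_equal(resolve_overlaps(ab2)$domain_id, c("A", "B"))

  # one strong hit must not block two disjoint weaker hits that together
  # outscore it
  trio <- make_hits(
    make_hit(domain_id = "LONG", start = 1, end = 100, bit_score = 100),
    make_hit(domain_id = "L1", start = 1, end = 50, bit_score = 55),
    make_hit(domain_id = "L2", start = 51, end = 100, bit_score = 55))
  expect_setequal(resolve_overlaps(trio)$domain_id, c("L1", "L2"))
})

test_that("overlap resolution matches exhaustive search on random instances", {
  set.seed(17)
  for (i in 1:120) {
    hits <- random_hit_instance(sample(2:8, 1))
    kept <- resolve_overlaps(hits)
    expect_equal(sum(kept$bit_score), brute_force_resolve(hits),
                 tolerance = 1e-12)
  }
})

test_that("overlap resolution is deterministic under input permutation", {
  set.seed(23)
  hits <- random_hit_instance(7)
  ref <- resolve_overlaps(hits)
  for (i in 1:5) {
    perm <- hits[sample(nrow(hits)), , drop = FALSE]
    expect_equal(resolve_overlaps(perm)$start, ref$start)
    expect_equal(resolve_overlaps(perm)$domain_id, ref$domain_id)
  }
})

test_that("cross-database merge absorbs, appends, and unions correctly", {
  pfam <- make_hit(domain_id = "PDZ", start = 10, end = 90)
  sf <- make_hit(domain_id = "50156", source = "SUPERFAMILY",
                 start = 12, end = 88, bit_score = NA)
  m <- merge_cross_db(pfam, sf)
  expect_equal(nrow(m), 1L)          # absorbed as corroboration
  expect_equal(m$domain_id, "PDZ")   # Pfam record kept
  expect_true(m$corroborated)

  m2 <- merge_cross_db(pfam[0, ], make_hit(domain_id = "50156",
                                           source = "SUPERFAMILY",
                                           start = 5, end = 80,
                                           bit_score = NA))
  expect_equal(nrow(m2), 1L)         # Superfamily-only PDZ survives
  expect_equal(m2$source, "SUPERFAMILY")

  disjoint <- merge_cross_db(
    make_hit(domain_id = "Trypsin", start = 100, end = 300),
    make_hit(domain_id = "50156", source = "SUPERFAMILY", start = 10,
             end = 80, bit_score = NA))
  expect_equal(nrow(disjoint), 2L)
  expect_false(any(disjoint$corroborated))
})

test_that("architecture construction: order, tandem count, flavor", {
  hits <- make_hits(
    make_hit(domain_id = "PDZ", start = 10, end = 90),
    make_hit(domain_id = "Trypsin", start = 120, end = 340),
    make_hit(domain_id = "PDZ_2", start = 400, end = 480))
  a <- build_architecture("p1", hits)
  expect_equal(architecture_string(a), "PDZ-Trypsin-PDZ_2")
  expect_equal(a$tandem_pdz_count, 2L)
  expect_true(a$has_pdz)
  expect_equal(a$pdz_flavor, "MIXED")

  canon <- build_architecture("p2", make_hit(domain_id = "PF00595",
                                             start = 5, end = 85))
  expect_equal(canon$pdz_flavor, "CANONICAL")
  noncanon <- build_architecture("p3", make_hit(domain_id = "PDZ_2"))
  expect_equal(noncanon$pdz_flavor, "NONCANONICAL")

  none <- build_architecture("p4", make_hit()[0, ])
  expect_false(none$has_pdz)
  expect_equal(none$pdz_flavor, "NONE")
  expect_equal(none$tandem_pdz_count, 0L)
})

test_that("Q-linker-split domains merge into one logical domain", {
  split_arch <- make_arch(c("PDZ", "Trypsin", "Trypsin"),
                          starts = c(10, 120, 300), lens = c(85, 120, 100))
  ld <- logical_domains(split_arch)   # gap 300-239-1 = 60 - 1? gap is 60
  # gap between segments: 300 - (120+120-1) - 1 = 60 -> not merged at < 60
  expect_equal(nrow(ld), 3L)
  close_arch <- make_arch(c("PDZ", "Trypsin", "Trypsin"),
                          starts = c(10, 120, 290), lens = c(85, 120, 100))
  ld2 <- logical_domains(close_arch)  # gap 50 < 60 -> merged
  expect_equal(nrow(ld2), 2L)
  expect_equal(ld2$domain_id, c("PDZ", "Trypsin"))
  expect_equal(ld2$end[2], 389L)
})

test_that("tandem counts summed over a proteome equal kept PDZ hits", {
  co <- tiny_cohort(n_genomes = 6, seed = 31)
  gdirs <- list.dirs(file.path(co$dir, "genomes"), recursive = FALSE)
  total_tandem <- 0L; total_pdz_hits <- 0L
  for (gdir in gdirs) {
    tid <- basename(gdir)
    pfam <- read_domtblout(file.path(gdir, paste0(tid, ".domtblout")))
    sf <- read_superfamily_table(file.path(gdir, paste0(tid, ".supfam.tsv")))
    archs <- build_architectures(pfam, sf)
    total_tandem <- total_tandem +
      sum(vapply(archs, `[[`, integer(1), "tandem_pdz_count"))
    total_pdz_hits <- total_pdz_hits + sum(vapply(archs, function(a) {
      sum(a$domains$domain_id %in% pdz_domain_ids())
    }, integer(1)))
  }
  expect_gt(total_tandem, 0L)
  expect_identical(total_tandem, total_pdz_hits)
  expect_identical(total_tandem, sum(co$truth$proteins$n_pdz_hits))
})
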