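# Family signatures, motif matching, classification rules, summaries.

test_that("there are twelve signatures in the documented precedence order", {
  sigs <- default_signatures()
  expect_length(sigs, 12L)
  expect_equal(vapply(sigs, `[[`, character(1), "family_id"),
               c("HTRA", "CTP", "RSEP", "APN", "LON", "SPOIVB", "AP", "ZEP",
                 "GSPC", "FESO", "HAEM", "COMP"))
  comp <- sigs[[12]]
  expect_length(comp$required, 2L)  # both kinase domains required
})

test_that("motif matching: positions, region windows, validation", {
  expect_equal(match_motif("AAHELGHAA", motif_pattern("HExGH", "HExGH")), 3L)
  expect_equal(match_motif("CAAACAACAA", motif_pattern("CxxxCxxC", "CxxxCxxC")), 1L)
  expect_equal(match_motif("AAAA", motif_pattern("m", "HExGH")), integer())
  # all occurrences, 1-based
  expect_equal(match_motif("HEAGHXHEAGH", motif_pattern("HExGH", "HExGH")),
               c(1L, 7L))
  # region restriction: same motif accepted in the N half, rejected in C half
  seqn <- paste0("AAHELGHAA", strrep("Q", 20))
  expect_length(match_motif(seqn, motif_pattern("m", "HExGH",
                                                "N_TERMINAL_HALF")), 1L)
  expect_length(match_motif(seqn, motif_pattern("m", "HExGH",
                                                "C_TERMINAL_HALF")), 0L)
  expect_error(motif_pattern("bad", "HE?GH"), "invalid character")
  expect_error(motif_pattern("short", "HE"), "length")
})

test_that("classification follows architecture signatures", {
  expect_equal(classify_protein(make_arch(c("PDZ", "Peptidase_S41",
                                            "DUF3340")))$family_id, "CTP")
  expect_equal(classify_protein(make_arch(c("PDZ", "Trypsin")))$family_id,
               "HTRA")
  expect_equal(classify_protein(make_arch(c("PDZ", "HisKA_3",
                                            "HATPase_c")))$family_id, "COMP")
  # one kinase domain alone is not ComP
  expect_equal(classify_protein(make_arch(c("PDZ", "HisKA_3")))$family_id,
               "UNCLASSIFIED")
  expect_equal(classify_protein(make_arch(c("PDZ", "NovelDomainX")))$family_id,
               "UNCLASSIFIED")
  # Pfam accession synonyms resolve to the signature vocabulary
  expect_equal(classify_protein(make_arch(c("PDZ", "PF00089")))$family_id,
               "HTRA")
  no_pdz <- build_architecture("p0", make_hit(domain_id = "Trypsin"))
  expect_error(classify_protein(no_pdz), "PDZ-positive")
})

test_that("motif corroboration is mandatory with a sequence, waived without", {
  feso <- make_arch(c("PDZ", "Radical_SAM"))
  with_motif <- paste0(strrep("A", 150), "CAAACAAC", strrep("A", 150))
  expect_equal(classify_protein(feso, sequence = with_motif)$family_id, "FESO")
  expect_equal(classify_protein(feso, sequence = strrep("A", 300))$family_id,
               "UNCLASSIFIED")
  unchecked <- classify_protein(feso)
  expect_equal(unchecked$family_id, "FESO")
  expect_equal(unchecked$confidence_note, "motif unchecked")

  # FeSO requires the PDZ N-terminal to the radical SAM domain
  swapped <- make_arch(c("Radical_SAM", "PDZ"))
  expect_equal(classify_protein(swapped)$family_id, "UNCLASSIFIED")

  rsep <- make_arch(c("PDZ", "Peptidase_M50"))
  L <- 400L
  seq_ok <- strrep("A", L)
  seq_ok <- paste0("AA", "HELGH", substr(seq_ok, 8, L - 40),
                   "NAAPAAALDG", strrep("A", 30))
  expect_equal(classify_protein(rsep, sequence = seq_ok)$family_id, "RSEP")
  # one motif missing: not RseP
  seq_half <- paste0("AA", "HELGH", strrep("A", L - 7))
  expect_equal(classify_protein(rsep, sequence = seq_half)$family_id,
               "UNCLASSIFIED")
})

test_that("co-occurring signatures resolve to the earlier precedence family", {
  sigs <- default_signatures()
  ids <- vapply(sigs, `[[`, character(1), "family_id")
  req_domains <- function(s) vapply(s$required, `[`, character(1), 1)
  for (i in seq_along(sigs)) {
    for (j in seq_along(sigs)) {
      if (i >= j) next
      doms <- c("PDZ", req_domains(sigs[[i]]), req_domains(sigs[[j]]))
      got <- classify_protein(make_arch(doms))$family_id
      expect_equal(got, ids[i],
                   label = sprintf("pair %s+%s -> %s", ids[i], ids[j], got))
    }
  }
})

test_that("classification is invariant under input order", {
  archs <- list(make_arch(c("PDZ", "Trypsin"), protein_id = "a"),
                make_arch(c("PDZ", "Lon_C"), protein_id = "b"),
                make_arch(c("PDZ", "Peptidase_M28"), protein_id = "c"))
  ref <- classify_proteins(archs)
  for (perm in list(c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))) {
    expect_identical(classify_proteins(archs[perm]), ref)
  }
})

test_that("family summaries count members and organisms per group", {
  md <- data.frame(taxon_id = c("t1", "t2", "t3"), organism = "o",
                   kingdom = c("EUBACTERIA", "EUBACTERIA", "ARCHAEA"),
                   phylum = c("Firmicutes", "Firmicutes", "Euryarchaeota"),
                   gram = NA, habitat = NA, oxygen = NA, genome_size_mb = 3,
                   stringsAsFactors = FALSE)
  asg <- data.frame(protein_id = sprintf("p%d", 1:4),
                    family_id = c("CTP", "CTP", "CTP", "HTRA"),
                    taxon_id = c("t1", "t1", "t2", "t3"),
                    stringsAsFactors = FALSE)
  s <- summarize_families(asg, md, by = "phylum")
  ctp <- s[s$family_id == "CTP", ]
  expect_equal(ctp$members, 3L)      # 3 proteins ...
  expect_equal(ctp$organisms, 2L)    # ... in 2 genomes of the phylum
  expect_equal(format_family_matrix(s)["CTP", "Firmicutes"], "3/2")
  expect_equal(format_family_matrix(s)["HTRA", "Firmicutes"], "")

  # kingdom totals equal the sum over constituent phyla
  sk <- summarize_families(asg, md, by = "kingdom")
  expect_equal(sk$members[sk$family_id == "CTP" & sk$group == "EUBACTERIA"],
               sum(s$members[s$family_id == "CTP"]))

  # bucket mapping folds rare phyla together
  sb <- summarize_families(asg, md, by = "phylum",
                           bucket_map = c(Euryarchaeota = "Other Archaea"))
  expect_true("Other Archaea" %in% sb$group)

  orphan <- asg; orphan$taxon_id[1] <- "t99"
  expect_error(summarize_families(orphan, md), "t99")
})

test_that("protease fraction over classified proteins", {
  asg <- data.frame(
    protein_id = sprintf("p%d", 1:11),
    family_id = c(rep("HTRA", 5), "CTP", "RSEP", "ZEP", "GSPC", "COMP",
                  "UNCLASSIFIED"), stringsAsFactors = FALSE)
  expect_equal(protease_fraction(asg), 0.8)
  all_htra <- data.frame(protein_id = "p", family_id = "HTRA")
  expect_equal(protease_fraction(all_htra), 1.0)
  none <- data.frame(protein_id = "p", family_id = "UNCLASSIFIED")
  expect_error(protease_fraction(none), "no classified")
})
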