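# Fixture builders and independent oracles shared across the suite.

make_hit <- function(protein_id = "p1", domain_id = "PDZ", source = "PFAM",
                     seq_evalue = 1e-10, dom_evalue = 1e-10,
                     start = 1L, end = 90L, bit_score = 100) {
  data.frame(protein_id = protein_id, domain_id = domain_id, source = source,
             seq_evalue = seq_evalue, dom_evalue = dom_evalue,
             start = as.integer(start), end = as.integer(end),
             bit_score = bit_score, stringsAsFactors = FALSE)
}

make_hits <- function(...) do.call(rbind, list(...))

make_genes <- function(starts, ends, strands, replicon = "chr",
                       gene_names = NULL, locus = NULL) {
  n <- length(starts)
  data.frame(replicon_id = replicon, start = as.integer(starts),
             end = as.integer(ends), strand = strands,
             locus_tag = if (is.null(locus)) sprintf("g%02d", seq_len(n)) else locus,
             gene_name = if (is.null(gene_names)) rep("", n) else gene_names,
             product = rep("", n), protein_id = sprintf("p%02d", seq_len(n)),
             stringsAsFactors = FALSE)
}

make_arch <- function(domain_ids, starts = NULL, protein_id = "p1",
                      lens = 100L) {
  n <- length(domain_ids)
  lens <- rep_len(as.integer(lens), n)
  if (is.null(starts)) starts <- cumsum(c(10L, utils::head(lens, -1) + 20L))
  hits <- data.frame(protein_id = protein_id, domain_id = domain_ids,
                     source = "PFAM", seq_evalue = 1e-10, dom_evalue = 1e-10,
                     start = as.integer(starts),
                     end = as.integer(starts + lens - 1L),
                     bit_score = 100, stringsAsFactors = FALSE)
  build_architecture(protein_id, hits)
}

# independent oracle: exhaustive maximum-total-bit-score subset under the
# pairwise overlap constraint (all 2^n subsets)
brute_force_resolve <- function(hits, overlap_tol = 0.2) {
  n <- nrow(hits)
  score <- ifelse(is.na(hits$bit_score), 0, hits$bit_score)
  feasible <- function(idx) {
    if (length(idx) < 2) return(TRUE)
    for (a in seq_along(idx)[-1]) for (b in seq_len(a - 1)) {
      i <- idx[a]; j <- idx[b]
      ov <- max(0L, min(hits$end[i], hits$end[j]) -
                  max(hits$start[i], hits$start[j]) + 1L)
      shorter <- min(hits$end[i] - hits$start[i] + 1L,
                     hits$end[j] - hits$start[j] + 1L)
      if (ov > overlap_tol * shorter) return(FALSE)
    }
    TRUE
  }
  best <- -Inf
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (feasible(idx)) best <- max(best, sum(score[idx]))
  }
  best
}

random_hit_instance <- function(n_hits, protein_id = "p") {
  starts <- sample(1:400, n_hits, replace = TRUE)
  lens <- sample(30:200, n_hits, replace = TRUE)
  data.frame(protein_id = protein_id,
             domain_id = sample(LETTERS, n_hits, replace = TRUE),
             source = "PFAM", seq_evalue = 1e-10, dom_evalue = 1e-10,
             start = starts, end = starts + lens - 1L,
             bit_score = round(runif(n_hits, 10, 200), 1),
             stringsAsFactors = FALSE)
}

# independent oracle: gene j belongs to the anchor's cluster iff every
# consecutive pair between the anchor and j (sorted order) is codirectional
# with intergenic distance <= max_gap
brute_force_neighborhood <- function(genes, anchor_idx, max_gap) {
  g <- genes[order(genes$start, genes$end), , drop = FALSE]
  i <- which(g$start == genes$start[anchor_idx] &
               g$end == genes$end[anchor_idx] &
               g$locus_tag == genes$locus_tag[anchor_idx])[1]
  ok_pair <- function(a, b) {
    g$strand[a] == g$strand[b] && g$strand[a] == g$strand[i] &&
      max(0L, g$start[b] - g$end[a] - 1L) <= max_gap
  }
  members <- i
  for (j in seq_len(nrow(g))) {
    if (j == i) next
    rng <- if (j < i) j:(i - 1) else i:(j - 1)
    if (all(vapply(rng, function(a) ok_pair(a, a + 1L), logical(1)))) {
      members <- c(members, j)
    }
  }
  sort(g$start[members])
}

random_gene_layout <- function(n_genes, replicon = "chr") {
  pos <- 100L
  starts <- ends <- integer(n_genes)
  for (i in seq_len(n_genes)) {
    starts[i] <- pos
    ends[i] <- pos + sample(200:900, 1)
    # mix gaps around the 50-nt rule, including exact 50 and 51
    pos <- ends[i] + 1L + sample(c(0:60, 50L, 51L, 200L), 1)
  }
  make_genes(starts, ends, sample(c("+", "-"), n_genes, replace = TRUE),
             replicon = replicon)
}

tiny_cohort <- function(n_genomes = 8, seed = 11, dir = tempfile("cohort"),
                        ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cc <- cohort_config(n_genomes = n_genomes, seed = seed, ...)
  truth <- generate_cohort(cc, dir)
  list(dir = dir, truth = truth, config = cc)
}

run_stages <- function(cohort_dir, work_dir,
                       stages = c("ingest", "classify", "context", "stats",
                                  "report")) {
  for (s in stages) {
    suppressWarnings(run_pipeline(s, list(cohort_dir = cohort_dir,
                                          work_dir = work_dir)))
  }
  invisible(work_dir)
}
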