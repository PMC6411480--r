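# Stage orchestration: simulate -> ingest -> classify -> context -> stats ->
# report, communicating through on-disk TSV artifacts so every stage is
# inspectable, diffable, and a pure function of (inputs, config, seed).

read_tsv_artifact <- function(path, stage) {
  if (!file.exists(path)) {
    stop("missing artifact ", basename(path), "; run the '", stage,
         "' stage first")
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

write_tsv_artifact <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

genome_dirs <- function(cohort_dir) {
  root <- file.path(cohort_dir, "genomes")
  if (!dir.exists(root)) stop("no genomes/ directory under ", cohort_dir)
  sort(list.dirs(root, recursive = FALSE))
}

#' Ingest a cohort: filter, merge, resolve, build architectures
#'
#' Reads each genome's Pfam domtblout and Superfamily table, applies the
#' threshold policy, merges across databases, resolves overlaps and writes
#' `architectures.tsv` (one row per protein with at least one kept hit) and
#' `domains.tsv` (the kept hits) under `work_dir`.
#'
#' @param cohort_dir Cohort directory (as written by [generate_cohort()]).
#' @param work_dir Output directory for pipeline artifacts.
#' @param policy A [threshold_policy()]; SCAN by default, matching a scan of
#'   each protein against the full domain libraries.
#' @param overlap_tol,absorb_frac See [resolve_overlaps()] and
#'   [merge_cross_db()].
#' @return Invisibly, a list with the two artifact paths and record counts.
#' @export
pdz_ingest <- function(cohort_dir, work_dir,
                       policy = threshold_policy("SCAN"),
                       overlap_tol = 0.2, absorb_frac = 0.5) {
  dir.create(work_dir, recursive = TRUE, showWarnings = FALSE)
  arch_rows <- list(); dom_rows <- list()
  for (gdir in genome_dirs(cohort_dir)) {
    tid <- basename(gdir)
    pfam <- read_domtblout(file.path(gdir, paste0(tid, ".domtblout")))
    supfam <- read_superfamily_table(file.path(gdir, paste0(tid, ".supfam.tsv")))
    archs <- build_architectures(pfam, supfam, policy = policy,
                                 overlap_tol = overlap_tol,
                                 absorb_frac = absorb_frac)
    arch_rows[[tid]] <- summarize_architectures(archs, taxon_id = tid)
    dom_rows[[tid]] <- do.call(rbind, lapply(archs, function(a) {
      if (!nrow(a$domains)) return(NULL)
      cbind(data.frame(protein_id = a$protein_id, taxon_id = tid,
                       stringsAsFactors = FALSE), a$domains)
    }))
  }
  arch <- do.call(rbind, arch_rows); rownames(arch) <- NULL
  doms <- do.call(rbind, dom_rows); rownames(doms) <- NULL
  write_tsv_artifact(arch, file.path(work_dir, "architectures.tsv"))
  write_tsv_artifact(doms, file.path(work_dir, "domains.tsv"))
  invisible(list(architectures = nrow(arch), domains = nrow(doms)))
}

rebuild_architectures <- function(work_dir) {
  doms <- read_tsv_artifact(file.path(work_dir, "domains.tsv"), "ingest")
  doms$corroborated <- as.logical(doms$corroborated)
  by_prot <- split(doms, doms$protein_id)
  archs <- lapply(by_prot, function(d) {
    build_architecture(d$protein_id[1], d[, c(DOMAIN_HIT_COLS, "corroborated")])
  })
  taxon <- vapply(by_prot, function(d) d$taxon_id[1], character(1))
  list(archs = archs, taxon_ids = stats::setNames(taxon, names(by_prot)))
}

#' Classify ingested architectures into families
#'
#' Rebuilds architectures from the ingest artifacts, attaches protein
#' sequences from each genome's FASTA for motif corroboration, and writes
#' `assignments.tsv`.
#'
#' @param cohort_dir Cohort directory (for the `.faa` files).
#' @param work_dir Pipeline artifact directory (needs a prior ingest).
#' @param signatures Signature list (default [default_signatures()]).
#' @return Invisibly, assignment counts by family.
#' @export
pdz_classify <- function(cohort_dir, work_dir,
                         signatures = default_signatures()) {
  rb <- rebuild_architectures(work_dir)
  seqs <- character()
  for (gdir in genome_dirs(cohort_dir)) {
    tid <- basename(gdir)
    fa <- file.path(gdir, paste0(tid, ".faa"))
    if (file.exists(fa)) seqs <- c(seqs, read_fasta(fa))
  }
  asg <- classify_proteins(rb$archs, sequences = seqs,
                           taxon_ids = rb$taxon_ids, signatures = signatures)
  write_tsv_artifact(asg, file.path(work_dir, "assignments.tsv"))
  invisible(table(asg$family_id))
}

#' Extract codirectional neighborhoods around PDZ-coding genes
#'
#' Anchors are the genes whose protein id has a PDZ-positive architecture.
#' Writes `clusters.tsv` (one row per cluster member) and
#' `conservation.tsv` (cross-genome neighbor counts).
#'
#' @param cohort_dir Cohort directory (for the `.ptt` files).
#' @param work_dir Pipeline artifact directory (needs a prior ingest).
#' @param max_gap Maximum intergenic distance (default 50 nt).
#' @param pairwise Measure gaps from the anchor instead of chaining.
#' @param key Conservation key: `"GENE_NAME"` or `"PRODUCT"`.
#' @return Invisibly, the list of `neighborhood_cluster` objects.
#' @export
pdz_context <- function(cohort_dir, work_dir, max_gap = 50L,
                        pairwise = FALSE, key = "GENE_NAME") {
  arch <- read_tsv_artifact(file.path(work_dir, "architectures.tsv"), "ingest")
  pdz_prot <- arch$protein_id[arch$has_pdz]
  clusters <- list(); rows <- list()
  for (gdir in genome_dirs(cohort_dir)) {
    tid <- basename(gdir)
    genes <- read_ptt(file.path(gdir, paste0(tid, ".ptt")), replicon_id = tid)
    anchors <- which(genes$protein_id %in% pdz_prot)
    for (i in anchors) {
      cl <- find_neighborhood(genes, i, max_gap = max_gap, pairwise = pairwise)
      clusters[[length(clusters) + 1L]] <- cl
      rows[[length(rows) + 1L]] <- data.frame(
        taxon_id = tid, anchor_locus = cl$anchor$locus_tag,
        anchor_protein = cl$anchor$protein_id,
        member_locus = cl$members$locus_tag,
        member_gene = cl$members$gene_name,
        member_strand = cl$members$strand,
        is_anchor = seq_len(nrow(cl$members)) == cl$anchor_index,
        stringsAsFactors = FALSE)
    }
  }
  write_tsv_artifact(do.call(rbind, rows), file.path(work_dir, "clusters.tsv"))
  cons <- conserved_neighbors(clusters, key = key)
  write_tsv_artifact(cons, file.path(work_dir, "conservation.tsv"))
  invisible(clusters)
}

#' Per-genome profiles, group comparisons and trends
#'
#' Writes `profiles.tsv`, `comparisons.tsv` (one row per tested group pair
#' across the habitat, oxygen, Gram and kingdom plans), `trends.tsv`
#' (genome-size Spearman trend per kingdom with >= 4 genomes) and
#' `loc_fractions.tsv`.
#'
#' @param cohort_dir Cohort directory (for metadata and localization tables).
#' @param work_dir Pipeline artifact directory (needs a prior ingest).
#' @param measure `"proteins"` or `"domains"`.
#' @param alternative Test direction for group comparisons.
#' @param adjust `"none"` or `"BH"`.
#' @return Invisibly, the profiles data.frame.
#' @export
pdz_stats <- function(cohort_dir, work_dir, measure = "proteins",
                      alternative = "greater", adjust = "none") {
  arch <- read_tsv_artifact(file.path(work_dir, "architectures.tsv"), "ingest")
  metadata <- read_metadata(file.path(cohort_dir, "metadata.tsv"))
  loc <- read_localization(file.path(cohort_dir, "localization.tsv"))
  profiles <- build_profiles(arch, loc, metadata)
  write_tsv_artifact(profiles, file.path(work_dir, "profiles.tsv"))
  comps <- list()
  for (grouping in c("HABITAT", "OXYGEN", "GRAM", "KINGDOM")) {
    cg <- withCallingHandlers(
      compare_groups(profiles, grouping, measure = measure,
                     alternative = alternative, adjust = adjust),
      warning = function(w) invokeRestart("muffleWarning"))
    if (nrow(cg)) comps[[grouping]] <- cbind(grouping = grouping, cg)
  }
  write_tsv_artifact(do.call(rbind, comps),
                     file.path(work_dir, "comparisons.tsv"))
  trends <- list()
  for (k in KINGDOMS) {
    n_k <- sum(!is.na(metadata$kingdom) & metadata$kingdom == k)
    if (n_k >= 4) {
      tr <- tryCatch(size_trend(profiles, k, measure = measure),
                     error = function(e) NULL)
      if (!is.null(tr)) {
        trends[[k]] <- data.frame(kingdom = k, rho = tr$rho, p = tr$p,
                                  n = tr$n, stringsAsFactors = FALSE)
      }
    }
  }
  write_tsv_artifact(do.call(rbind, trends), file.path(work_dir, "trends.tsv"))
  write_tsv_artifact(localization_fractions(profiles, "ALL"),
                     file.path(work_dir, "loc_fractions.tsv"))
  invisible(profiles)
}

#' Final report: family matrix, iTOL bars, summary, machine-readable log
#'
#' Writes `family_matrix.tsv` (members/organisms by phylum and kingdom),
#' `itol_bars.txt`, a plain-text `summary.txt`, and `run_log.json` with the
#' package version, input checksums, per-stage record counts and artifact
#' checksums (no timestamps, so identical inputs give identical logs).
#'
#' @param cohort_dir Cohort directory.
#' @param work_dir Pipeline artifact directory (needs prior ingest, classify
#'   and stats stages).
#' @return Invisibly, the run-log list.
#' @export
pdz_report <- function(cohort_dir, work_dir) {
  asg <- read_tsv_artifact(file.path(work_dir, "assignments.tsv"), "classify")
  profiles <- read_tsv_artifact(file.path(work_dir, "profiles.tsv"), "stats")
  metadata <- read_metadata(file.path(cohort_dir, "metadata.tsv"))
  fam_phy <- summarize_families(asg, metadata, by = "phylum")
  fam_kng <- summarize_families(asg, metadata, by = "kingdom")
  mat <- rbind(
    cbind(level = "phylum", fam_phy),
    cbind(level = "kingdom", fam_kng))
  write_tsv_artifact(mat, file.path(work_dir, "family_matrix.tsv"))
  write_itol_bars(profiles, file.path(work_dir, "itol_bars.txt"))

  n_prot <- nrow(asg)
  n_cls <- sum(asg$family_id != "UNCLASSIFIED")
  lf <- localization_fractions(profiles, "ALL")
  summary_lines <- c(
    sprintf("genomes: %d", nrow(profiles)),
    sprintf("PDZ proteins: %d", n_prot),
    sprintf("PDZ domains (tandem-aware): %d", sum(profiles$n_pdz_domains)),
    sprintf("classified: %d (%.1f%%)", n_cls, 100 * n_cls / max(1, n_prot)),
    sprintf("protease-family fraction of classified: %.1f%%",
            100 * protease_fraction(asg)),
    sprintf("membrane-targeted (TM/SP/TMSP) fraction: %.2f%%",
            100 * (1 - lf$frac_CYT[1])),
    sprintf("cytoplasmic fraction: %.2f%%", 100 * lf$frac_CYT[1]))
  writeLines(summary_lines, file.path(work_dir, "summary.txt"))

  inputs <- sort(c(list.files(cohort_dir, recursive = TRUE, full.names = TRUE)))
  artifacts <- c("architectures.tsv", "domains.tsv", "assignments.tsv",
                 "profiles.tsv", "comparisons.tsv", "trends.tsv",
                 "loc_fractions.tsv", "family_matrix.tsv", "itol_bars.txt",
                 "summary.txt", "clusters.tsv", "conservation.tsv")
  artifacts <- artifacts[file.exists(file.path(work_dir, artifacts))]
  counts <- lapply(stats::setNames(artifacts, artifacts), function(f) {
    length(readLines(file.path(work_dir, f), warn = FALSE)) - 1L
  })
  log <- list(
    package = "pdzsurvey",
    version = as.character(utils::packageVersion("pdzsurvey")),
    input_checksums = as.list(tools::md5sum(inputs)),
    artifact_checksums = as.list(tools::md5sum(file.path(work_dir, artifacts))),
    record_counts = counts)
  names(log$input_checksums) <- sub(paste0("^", gsub("([.\\\\])", "\\\\\\1", cohort_dir), "/?"),
                                    "", names(log$input_checksums))
  names(log$artifact_checksums) <- basename(names(log$artifact_checksums))
  jsonlite::write_json(log, file.path(work_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(log)
}

#' Run pipeline stages
#'
#' Dispatches the named stage (or `"all"`) with a single config list. Stage
#' outputs are pure functions of (inputs, config, seed): re-running a stage
#' with the same inputs is idempotent, and two `"all"` runs with the same
#' config and seed produce byte-identical reports.
#'
#' @param stage One of `"simulate"`, `"ingest"`, `"classify"`, `"context"`,
#'   `"stats"`, `"report"`, `"all"`.
#' @param config List with: `cohort_dir` (input/output cohort directory),
#'   `work_dir` (artifact directory), and optionally `seed`, `cohort`
#'   (a [cohort_config()] for simulate), `mode` (`"SCAN"`/`"SEARCH"`),
#'   `max_gap`, `pairwise`, `measure`, `alternative`, `adjust`.
#' @return Invisibly, the last stage's return value.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "ingest", "classify",
                                   "context", "stats", "report"),
                         config = list()) {
  stage <- match.arg(stage)
  cohort_dir <- config$cohort_dir
  work_dir <- config$work_dir
  if (is.null(cohort_dir)) stop("config$cohort_dir is required")
  if (is.null(work_dir) && stage != "simulate") {
    stop("config$work_dir is required")
  }
  stages <- if (stage == "all") {
    c("simulate", "ingest", "classify", "context", "stats", "report")
  } else stage
  out <- NULL
  for (s in stages) {
    out <- switch(s,
      simulate = {
        cc <- config$cohort
        if (is.null(cc)) cc <- cohort_config(seed = config$seed %||% 1L)
        if (!is.null(config$seed)) cc$seed <- as.integer(config$seed)
        generate_cohort(cc, cohort_dir)
      },
      ingest = pdz_ingest(cohort_dir, work_dir,
                          policy = threshold_policy(config$mode %||% "SCAN")),
      classify = pdz_classify(cohort_dir, work_dir),
      context = pdz_context(cohort_dir, work_dir,
                            max_gap = config$max_gap %||% 50L,
                            pairwise = config$pairwise %||% FALSE),
      stats = pdz_stats(cohort_dir, work_dir,
                        measure = config$measure %||% "proteins",
                        alternative = config$alternative %||% "greater",
                        adjust = config$adjust %||% "none"),
      report = pdz_report(cohort_dir, work_dir))
  }
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
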