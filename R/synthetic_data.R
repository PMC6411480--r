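# Seeded generator of synthetic genome cohorts with planted ground truth.
# Emits exactly the file formats the readers consume (hmmscan-style
# domtblout, Superfamily assignment TSV, NCBI PTT, metadata/localization
# TSV, FASTA) plus a truth manifest.

FAMILY_PARTNER_DOMAINS <- list(
  HTRA = "Trypsin", CTP = "Peptidase_S41", RSEP = "Peptidase_M50",
  APN = "Peptidase_M61", LON = "Lon_C", SPOIVB = "Peptidase_S55",
  AP = "Asp_protease", ZEP = "Peptidase_M28", GSPC = "Pilus_P",
  FESO = "Radical_SAM", HAEM = "Haem_bd_uptake",
  COMP = c("HisKA_3", "HATPase_c"))

DOMAIN_LENGTHS <- c(PDZ = 85, PDZ_2 = 85, Trypsin = 220, Peptidase_S41 = 200,
                    Peptidase_M50 = 210, Peptidase_M61 = 250, Lon_C = 200,
                    Peptidase_S55 = 230, Asp_protease = 180,
                    Peptidase_M28 = 240, Pilus_P = 120, Radical_SAM = 230,
                    Haem_bd_uptake = 150, HisKA_3 = 70, HATPase_c = 110,
                    DUF3340 = 90)

# decoy vocabulary is disjoint from every signature so a decoy can never
# accidentally complete a family
DECOY_DOMAINS <- c("Methyltransf_25", "AAA_21", "HTH_1", "TPR_2", "ABC_tran",
                   "SBP_bac_5", "GGDEF", "Response_reg")
NOVEL_DOMAINS <- c("DUF4923", "DUF2994", "YjbK_like")
DECOY_LEN <- 110L

PHYLA <- list(
  EUBACTERIA = c("Proteobacteria", "Firmicutes", "Actinobacteria",
                 "Cyanobacteria", "Bacteroidetes", "Planctomycetes"),
  ARCHAEA = c("Euryarchaeota", "Crenarchaeota"),
  FUNGI = c("Ascomycota", "Basidiomycota"))

NEIGHBOR_PRODUCTS <- c(
  cdsA = "phosphatidate cytidylyltransferase",
  uppS = "undecaprenyl pyrophosphate synthase",
  dxr = "1-deoxy-D-xylulose 5-phosphate reductoisomerase",
  frr = "ribosome recycling factor",
  rpsB = "30S ribosomal protein S2",
  bamA = "outer membrane protein assembly factor",
  coaD = "phosphopantetheine adenylyltransferase",
  rsmD = "16S rRNA methyltransferase",
  yqgF = "putative resolvase")

#' Configuration for a synthetic genome cohort
#'
#' Defaults emulate the statistical structure the survey assumes: mostly
#' eubacterial genomes; per-genome PDZ gene counts drawn from a negative
#' binomial whose mean depends on oxygen requirement (aerobic 8, anaerobic 3,
#' facultative 5 at the reference size), habitat (terrestrial and aquatic
#' above multiple, host-associated and specialized niches), kingdom
#' (archaea/fungi reduced) and, in eubacteria only, genome size; family
#' labels drawn so that 93% of proteins are classifiable and 88% of
#' classified proteins fall in the eight protease families; a 0.25 chance of
#' a tandem (second) PDZ hit; localization mix giving 11% cytoplasmic among
#' known calls; RseP and lon neighborhoods planted with their conserved
#' neighbor genes, plus one deliberate 60-nt break gene.
#'
#' @param n_genomes Number of genomes.
#' @param kingdom_mix,oxygen_mix,habitat_mix,localization_mix,family_mix
#'   Named probability vectors (each sums to 1).
#' @param genome_size_range Named list of c(min, max) genome sizes in Mb per
#'   kingdom.
#' @param oxygen_means Mean PDZ genes per genome by oxygen class at the
#'   reference size.
#' @param habitat_mult,kingdom_mult Multiplicative effects on the mean.
#' @param size_ref_mb Reference size; eubacterial means scale as size/ref.
#' @param dispersion Negative binomial size parameter (Inf = Poisson).
#' @param tandem_rate Probability a PDZ protein carries a further PDZ hit
#'   (geometric continuation, capped at 4 hits).
#' @param canonical_rate Probability a planted PDZ hit is the canonical Pfam
#'   family rather than PDZ_2.
#' @param sf_corroborate_rate Probability a Pfam PDZ hit gets an overlapping
#'   Superfamily 50156 assignment.
#' @param sf_only_rate Probability a protein's PDZ hits appear only in the
#'   Superfamily table (Pfam miss).
#' @param decoy_above_rate,decoy_below_rate Mean number per genome of planted
#'   decoy hits above and below the inclusion thresholds.
#' @param nan_rate Fraction of proteins without a localization call.
#' @param neighborhood_plants List of plants: each a list with `family`,
#'   `neighbors`, `gaps` (one gap per neighbor), and optional
#'   `break_neighbor`/`break_gap` appending a gene beyond the 50-nt rule.
#' @param seed Integer seed; a fixed seed gives byte-identical outputs.
#' @return A validated `cohort_config` object.
#' @export
cohort_config <- function(n_genomes = 60,
                          kingdom_mix = c(EUBACTERIA = 0.75, ARCHAEA = 0.15,
                                          FUNGI = 0.10),
                          oxygen_mix = c(AEROBIC = 0.5, ANAEROBIC = 0.25,
                                         FACULTATIVE = 0.25),
                          habitat_mix = c(AQUATIC = 0.2, TERRESTRIAL = 0.2,
                                          MULTIPLE = 0.2,
                                          HOST_ASSOCIATED = 0.2,
                                          SPECIALIZED = 0.2),
                          genome_size_range = list(EUBACTERIA = c(2, 9),
                                                   ARCHAEA = c(1.5, 5),
                                                   FUNGI = c(10, 40)),
                          oxygen_means = c(AEROBIC = 8, ANAEROBIC = 3,
                                           FACULTATIVE = 5),
                          habitat_mult = c(TERRESTRIAL = 1.5, AQUATIC = 1.3,
                                           MULTIPLE = 1.0,
                                           HOST_ASSOCIATED = 0.7,
                                           SPECIALIZED = 0.5),
                          kingdom_mult = c(EUBACTERIA = 1, ARCHAEA = 0.4,
                                           FUNGI = 0.4),
                          size_ref_mb = 5,
                          dispersion = 5,
                          family_mix = NULL,
                          tandem_rate = 0.25,
                          canonical_rate = 0.8,
                          sf_corroborate_rate = 0.8,
                          sf_only_rate = 0.05,
                          decoy_above_rate = 2,
                          decoy_below_rate = 1,
                          localization_mix = c(TM = 0.32, SP = 0.40,
                                               TMSP = 0.17, CYT = 0.11),
                          nan_rate = 0.05,
                          neighborhood_plants = NULL,
                          seed = 1L) {
  if (is.null(family_mix)) {
    classified <- 0.93
    within <- c(HTRA = 0.30, CTP = 0.22, RSEP = 0.14, APN = 0.05, LON = 0.06,
                SPOIVB = 0.04, AP = 0.03, ZEP = 0.04, GSPC = 0.04,
                FESO = 0.03, HAEM = 0.03, COMP = 0.02)
    family_mix <- c(within * classified, UNCLASSIFIED = 1 - classified)
  }
  if (is.null(neighborhood_plants)) {
    neighborhood_plants <- list(
      list(family = "RSEP",
           neighbors = c("cdsA", "uppS", "dxr", "frr", "rpsB", "bamA"),
           gaps = c(20L, 5L, 35L, 12L, 48L, 9L),
           break_neighbor = "yqgF", break_gap = 60L),
      list(family = "LON", neighbors = c("coaD", "rsmD"),
           gaps = c(18L, 44L)))
  }
  cfg <- list(n_genomes = as.integer(n_genomes), kingdom_mix = kingdom_mix,
              oxygen_mix = oxygen_mix, habitat_mix = habitat_mix,
              genome_size_range = genome_size_range,
              oxygen_means = oxygen_means, habitat_mult = habitat_mult,
              kingdom_mult = kingdom_mult, size_ref_mb = size_ref_mb,
              dispersion = dispersion, family_mix = family_mix,
              tandem_rate = tandem_rate, canonical_rate = canonical_rate,
              sf_corroborate_rate = sf_corroborate_rate,
              sf_only_rate = sf_only_rate,
              decoy_above_rate = decoy_above_rate,
              decoy_below_rate = decoy_below_rate,
              localization_mix = localization_mix, nan_rate = nan_rate,
              neighborhood_plants = neighborhood_plants,
              seed = as.integer(seed))
  for (mx in c("kingdom_mix", "oxygen_mix", "habitat_mix", "family_mix",
               "localization_mix")) {
    if (abs(sum(cfg[[mx]]) - 1) > 1e-8) stop(mx, " must sum to 1")
    if (any(cfg[[mx]] < 0)) stop(mx, " has negative probabilities")
  }
  for (rt in c("tandem_rate", "canonical_rate", "sf_corroborate_rate",
               "sf_only_rate", "nan_rate")) {
    if (cfg[[rt]] < 0 || cfg[[rt]] > 1) stop(rt, " must be in [0, 1]")
  }
  if (cfg$n_genomes < 1) stop("n_genomes must be >= 1")
  for (pl in cfg$neighborhood_plants) {
    if (length(pl$gaps) != length(pl$neighbors)) {
      stop("neighborhood plant for ", pl$family,
           ": need one gap per neighbor")
    }
    if (any(pl$gaps < 0)) stop("neighborhood gaps must be >= 0")
  }
  structure(cfg, class = "cohort_config")
}

#' Draw per-genome PDZ gene counts from the planted rate model
#'
#' Mean per genome = oxygen mean x habitat multiplier x kingdom multiplier,
#' scaled by genome size relative to the reference in eubacteria only; counts
#' are negative binomial with the configured dispersion (Poisson when
#' dispersion is infinite). Uses the current RNG state.
#'
#' @param metadata Genome metadata data.frame.
#' @param config A [cohort_config()].
#' @return Integer vector of PDZ gene counts, one per metadata row.
#' @export
draw_pdz_counts <- function(metadata, config) {
  mu <- config$oxygen_means[metadata$oxygen] *
    config$habitat_mult[metadata$habitat] *
    config$kingdom_mult[metadata$kingdom]
  mu[is.na(mu)] <- mean(config$oxygen_means)
  scale <- ifelse(metadata$kingdom == "EUBACTERIA",
                  metadata$genome_size_mb / config$size_ref_mb, 1)
  mu <- as.numeric(mu * scale)
  if (is.finite(config$dispersion)) {
    stats::rnbinom(length(mu), mu = mu, size = config$dispersion)
  } else {
    stats::rpois(length(mu), lambda = mu)
  }
}

random_sequence <- function(n) {
  paste(sample(AA_LETTERS, n, replace = TRUE), collapse = "")
}

motif_instance <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  chars[chars == "x"] <- sample(AA_LETTERS, sum(chars == "x"), replace = TRUE)
  paste(chars, collapse = "")
}

splice_motif <- function(sequence, motif, at) {
  at <- max(1L, min(at, nchar(sequence) - nchar(motif) + 1L))
  paste0(substr(sequence, 1, at - 1L), motif,
         substr(sequence, at + nchar(motif), nchar(sequence)))
}

#' Lay out a planted codirectional gene cluster
#'
#' Places `neighbor_names` downstream of the anchor gene on the same strand
#' with exactly the stated intergenic distances (1-based inclusive
#' coordinates; a gap above the neighborhood rule's threshold plants a
#' deliberate chain break).
#'
#' @param anchor One-row gene-record data.frame for the anchor gene.
#' @param neighbor_names Character vector of neighbor gene names.
#' @param gaps Integer vector of intergenic distances, one per neighbor
#'   (anchor to first neighbor, then consecutive).
#' @param gene_len Neighbor gene length in nucleotides (recycled).
#' @param locus_prefix Prefix for generated locus tags.
#' @return Gene-record data.frame: anchor row followed by neighbor rows.
#' @export
plant_neighborhood <- function(anchor, neighbor_names, gaps, gene_len = 900L,
                               locus_prefix = "NB") {
  if (length(gaps) != length(neighbor_names)) {
    stop("need one gap per neighbor")
  }
  if (any(gaps < 0)) stop("gaps must be >= 0 (overlapping placement)")
  gene_len <- rep_len(as.integer(gene_len), length(neighbor_names))
  out <- anchor
  prev_end <- anchor$end
  for (i in seq_along(neighbor_names)) {
    start <- prev_end + gaps[i] + 1L
    end <- start + gene_len[i] - 1L
    prod <- NEIGHBOR_PRODUCTS[neighbor_names[i]]
    out <- rbind(out, data.frame(
      replicon_id = anchor$replicon_id, start = start, end = end,
      strand = anchor$strand,
      locus_tag = sprintf("%s_%s%02d", locus_prefix, neighbor_names[i], i),
      gene_name = neighbor_names[i],
      product = if (is.na(prod)) "conserved neighborhood protein" else unname(prod),
      protein_id = sprintf("%s_%s%02d", locus_prefix, neighbor_names[i], i),
      stringsAsFactors = FALSE))
    prev_end <- end
  }
  rownames(out) <- NULL
  out
}

make_cohort_metadata <- function(config) {
  n <- config$n_genomes
  counts <- round(config$kingdom_mix * n)
  # deterministic composition: adjust the largest class so counts sum to n
  counts[which.max(counts)] <- counts[which.max(counts)] + n - sum(counts)
  kingdom <- rep(names(counts), counts)
  taxon_id <- sprintf("T%03d", seq_len(n))
  phylum <- vapply(kingdom, function(k) sample(PHYLA[[k]], 1), character(1))
  gram <- ifelse(kingdom == "EUBACTERIA",
                 sample(c("NEGATIVE", "POSITIVE"), n, replace = TRUE,
                        prob = c(0.6, 0.4)),
                 NA_character_)
  habitat <- sample(names(config$habitat_mix), n, replace = TRUE,
                    prob = config$habitat_mix)
  oxygen <- sample(names(config$oxygen_mix), n, replace = TRUE,
                   prob = config$oxygen_mix)
  size <- vapply(kingdom, function(k) {
    r <- config$genome_size_range[[k]]
    round(stats::runif(1, r[1], r[2]), 2)
  }, numeric(1))
  data.frame(taxon_id = taxon_id,
             organism = sprintf("Synthetica organismus %03d", seq_len(n)),
             kingdom = kingdom, phylum = phylum, gram = gram,
             habitat = habitat, oxygen = oxygen, genome_size_mb = size,
             stringsAsFactors = FALSE)
}

# instantiate one protein: domain layout, hit rows, sequence, truth row
plant_protein <- function(pid, family, config) {
  n_pdz <- 1L
  while (n_pdz < 4L && stats::runif(1) < config$tandem_rate) n_pdz <- n_pdz + 1L
  pdz_label <- ifelse(stats::runif(n_pdz) < config$canonical_rate, "PDZ", "PDZ_2")
  partners <- if (family == "UNCLASSIFIED") {
    if (stats::runif(1) < 0.3) character() else sample(NOVEL_DOMAINS, 1)
  } else {
    p <- FAMILY_PARTNER_DOMAINS[[family]]
    if (family == "CTP" && stats::runif(1) < 0.5) p <- c(p, "DUF3340")
    p
  }
  dom_ids <- c(pdz_label, partners)
  lens <- ifelse(dom_ids %in% names(DOMAIN_LENGTHS),
                 DOMAIN_LENGTHS[dom_ids], DECOY_LEN)
  pos <- 0L
  starts <- ends <- integer(length(dom_ids))
  for (i in seq_along(dom_ids)) {
    starts[i] <- pos + (if (i == 1) 8L else sample(10:40, 1))
    ends[i] <- starts[i] + as.integer(lens[i]) - 1L
    pos <- ends[i]
  }
  length_aa <- pos + 15L
  seqn <- random_sequence(length_aa)
  if (family == "RSEP") {
    seqn <- splice_motif(seqn, motif_instance("HExGH"),
                         max(3L, round(0.08 * length_aa)))
    seqn <- splice_motif(seqn, motif_instance("NxxPxxxLDG"), length_aa - 30L)
  } else if (family == "FESO") {
    rs <- starts[match("Radical_SAM", dom_ids)]
    seqn <- splice_motif(seqn, motif_instance("CxxxCxxC"), rs + 10L)
  }
  hits <- data.frame(
    protein_id = pid, domain_id = dom_ids, source = "PFAM",
    seq_evalue = 10^-stats::runif(length(dom_ids), 6, 30),
    dom_evalue = 10^-stats::runif(length(dom_ids), 6, 30),
    start = starts, end = ends,
    bit_score = round(stats::runif(length(dom_ids), 80, 400), 1),
    stringsAsFactors = FALSE)
  list(hits = hits, sequence = seqn, length_aa = length_aa,
       n_pdz_hits = n_pdz,
       n_other_domains = length(partners),
       is_pdz_row = dom_ids %in% c("PDZ", "PDZ_2"))
}

format_domtblout <- function(hits, qlen) {
  sprintf(paste0("%-20s -  %6d %-16s -  %6d %9.2g %7.1f 0.0 1 1 %9.2g ",
                 "%9.2g %7.1f 0.0 1 %d %d %d %d %d 0.90 -"),
          hits$domain_id, hits$end - hits$start + 1L, hits$protein_id,
          qlen[hits$protein_id], hits$seq_evalue, hits$bit_score * 1.01,
          hits$dom_evalue, hits$dom_evalue, hits$bit_score,
          hits$end - hits$start + 1L,
          hits$start, hits$end, hits$start, hits$end)
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Writes, under `out_dir`, one directory per genome
#' (`genomes/<taxon>/<taxon>.domtblout`, `.supfam.tsv`, `.ptt`, `.faa`),
#' cohort-level `metadata.tsv` and `localization.tsv`, and a `truth/`
#' directory with the manifest (planted per-protein families and tandem
#' counts, per-genome counts, decoy hits with their E-values, planted
#' cluster memberships). All randomness derives from `config$seed`, so a
#' fixed seed reproduces the files byte for byte.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the truth manifest as a list of data.frames
#'   (`proteins`, `genomes`, `decoys`, `clusters`, plus `config`).
#' @export
generate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  dir.create(file.path(out_dir, "genomes"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)

  metadata <- make_cohort_metadata(config)
  n_pdz <- draw_pdz_counts(metadata, config)

  truth_proteins <- list(); truth_decoys <- list(); truth_clusters <- list()
  loc_rows <- list()

  for (gi in seq_len(nrow(metadata))) {
    tid <- metadata$taxon_id[gi]
    gdir <- file.path(out_dir, "genomes", tid)
    dir.create(gdir, showWarnings = FALSE)
    k <- n_pdz[gi]
    fams <- if (k > 0) {
      sample(names(config$family_mix), k, replace = TRUE,
             prob = config$family_mix)
    } else character()
    pids <- if (k > 0) sprintf("%s_P%03d", tid, seq_len(k)) else character()

    proteins <- lapply(seq_len(k), function(j) {
      plant_protein(pids[j], fams[j], config)
    })
    pfam_hits <- if (k > 0) do.call(rbind, lapply(proteins, `[[`, "hits")) else empty_domain_hits()
    qlen <- if (k > 0) stats::setNames(
      vapply(proteins, `[[`, integer(1), "length_aa"), pids) else integer()

    # Superfamily table: corroboration of Pfam PDZ hits, or replacement of
    # them for Superfamily-only proteins
    sf_rows <- list(); drop_pfam <- logical(nrow(pfam_hits))
    for (j in seq_len(k)) {
      ph <- proteins[[j]]
      sf_only <- stats::runif(1) < config$sf_only_rate
      pdz_rows <- which(pfam_hits$protein_id == pids[j])[ph$is_pdz_row]
      for (r in pdz_rows) {
        emit <- sf_only || stats::runif(1) < config$sf_corroborate_rate
        if (emit) {
          sf_rows[[length(sf_rows) + 1L]] <- data.frame(
            protein_id = pids[j], superfamily_id = "50156",
            region = sprintf("%d-%d", pfam_hits$start[r] + 2L,
                             pfam_hits$end[r] - 2L),
            evalue = sprintf("%.2g", 10^-stats::runif(1, 8, 25)),
            stringsAsFactors = FALSE)
        }
        if (sf_only) drop_pfam[r] <- TRUE
      }
    }
    pfam_hits <- pfam_hits[!drop_pfam, , drop = FALSE]

    # decoy hits above the inclusion thresholds (never in architectures
    # under SCAN; the >0.03 kind never under SEARCH either)
    n_above <- stats::rpois(1, config$decoy_above_rate)
    decoys <- list()
    if (k > 0 && n_above > 0) {
      for (d in seq_len(n_above)) {
        j <- sample.int(k, 1)
        kind <- sample(c("dom_hi", "dom_mid", "seq_hi"), 1)
        seq_e <- if (kind == "seq_hi") stats::runif(1, 0.011, 0.5) else 10^-stats::runif(1, 4, 8)
        dom_e <- switch(kind,
                        dom_hi = stats::runif(1, 0.031, 0.5),
                        dom_mid = stats::runif(1, 0.011, 0.029),
                        seq_hi = 10^-stats::runif(1, 4, 8))
        st <- sample.int(max(1L, qlen[[pids[j]]] - DECOY_LEN), 1)
        decoys[[d]] <- data.frame(
          protein_id = pids[j], domain_id = sample(DECOY_DOMAINS, 1),
          source = "PFAM", seq_evalue = seq_e, dom_evalue = dom_e,
          start = st, end = st + DECOY_LEN - 1L,
          bit_score = round(stats::runif(1, 5, 15), 1),
          stringsAsFactors = FALSE)
      }
    }
    # decoy domains below the thresholds: survive filtering, appended past
    # the planted domains so they never contest them
    n_below <- stats::rpois(1, config$decoy_below_rate)
    below <- list()
    if (k > 0 && n_below > 0) {
      for (d in seq_len(n_below)) {
        j <- sample.int(k, 1)
        st <- qlen[[pids[j]]] - 14L
        qlen[pids[j]] <- st + DECOY_LEN + 14L
        proteins[[j]]$length_aa <- qlen[[pids[j]]]
        proteins[[j]]$sequence <- paste0(
          proteins[[j]]$sequence, random_sequence(DECOY_LEN))
        proteins[[j]]$n_other_domains <- proteins[[j]]$n_other_domains + 1L
        if (fams[j] == "RSEP") {
          # the C-terminal motif must track the extended C terminus
          proteins[[j]]$sequence <- splice_motif(
            proteins[[j]]$sequence, motif_instance("NxxPxxxLDG"),
            nchar(proteins[[j]]$sequence) - 30L)
        }
        below[[d]] <- data.frame(
          protein_id = pids[j], domain_id = sample(DECOY_DOMAINS, 1),
          source = "PFAM", seq_evalue = 10^-stats::runif(1, 5, 12),
          dom_evalue = 10^-stats::runif(1, 5, 12),
          start = st, end = st + DECOY_LEN - 1L,
          bit_score = round(stats::runif(1, 80, 150), 1),
          stringsAsFactors = FALSE)
      }
    }
    all_hits <- rbind(pfam_hits,
                      if (length(below)) do.call(rbind, below),
                      if (length(decoys)) do.call(rbind, decoys))
    if (nrow(all_hits)) {
      all_hits <- all_hits[order(all_hits$protein_id, all_hits$start,
                                 all_hits$domain_id), , drop = FALSE]
    }

    # localization
    loc_cat <- if (k > 0) {
      ifelse(stats::runif(k) < config$nan_rate, "NAN",
             sample(names(config$localization_mix), k, replace = TRUE,
                    prob = config$localization_mix))
    } else character()
    if (k > 0) {
      loc_rows[[tid]] <- data.frame(protein_id = pids, category = loc_cat,
                                    stringsAsFactors = FALSE)
    }

    # genome layout: every PDZ gene is a unit; planted families carry their
    # neighbor cluster; fillers keep units apart (inter-unit gap > 50)
    genes <- empty_gene_records()
    pos <- 500L
    plant_for <- function(fam) {
      for (pl in config$neighborhood_plants) if (pl$family == fam) return(pl)
      NULL
    }
    unit_order <- if (k > 0) sample(k) else integer()
    cl_id <- 0L
    for (j in unit_order) {
      # filler gene before each unit
      flen <- sample(300:1500, 1)
      genes <- rbind(genes, data.frame(
        replicon_id = tid, start = pos, end = pos + flen - 1L,
        strand = sample(c("+", "-"), 1),
        locus_tag = sprintf("%s_G%03d", tid, nrow(genes) + 1L),
        gene_name = "", product = "hypothetical protein",
        protein_id = sprintf("%s_F%03d", tid, nrow(genes) + 1L),
        stringsAsFactors = FALSE))
      pos <- pos + flen - 1L + sample(80:400, 1)
      strand <- sample(c("+", "-"), 1)
      glen <- 3L * qlen[[pids[j]]] + 3L
      anchor <- data.frame(
        replicon_id = tid, start = pos, end = pos + glen - 1L,
        strand = strand, locus_tag = sprintf("%s_L%03d", tid, j),
        gene_name = "", product = sprintf("PDZ domain protein (%s)", fams[j]),
        protein_id = pids[j], stringsAsFactors = FALSE)
      pl <- plant_for(fams[j])
      if (is.null(pl)) {
        genes <- rbind(genes, anchor)
        pos <- anchor$end
      } else {
        cl_id <- cl_id + 1L
        nb <- pl$neighbors; gp <- pl$gaps
        if (!is.null(pl$break_neighbor)) {
          nb <- c(nb, pl$break_neighbor); gp <- c(gp, pl$break_gap)
        }
        cluster <- plant_neighborhood(
          anchor, nb, gp, gene_len = 900L,
          locus_prefix = sprintf("%s_C%02d", tid, cl_id))
        genes <- rbind(genes, cluster)
        pos <- max(cluster$end)
        truth_clusters[[length(truth_clusters) + 1L]] <- data.frame(
          taxon_id = tid, family = fams[j], anchor_locus = anchor$locus_tag,
          anchor_protein = pids[j],
          neighbor = nb, gap = gp, in_range = gp <= 50L,
          stringsAsFactors = FALSE)
      }
      pos <- pos + sample(80:400, 1)
    }
    # trailing filler
    genes <- rbind(genes, data.frame(
      replicon_id = tid, start = pos, end = pos + 600L,
      strand = "+", locus_tag = sprintf("%s_G%03d", tid, nrow(genes) + 1L),
      gene_name = "", product = "hypothetical protein",
      protein_id = sprintf("%s_F%03d", tid, nrow(genes) + 1L),
      stringsAsFactors = FALSE))

    # emit files
    dt_lines <- c("#                    --- full sequence --- -------------- this domain --------------",
                  "# target name  acc tlen query name  acc qlen E-value score bias # of c-Evalue i-Evalue score bias hf ht af at ef et acc description")
    if (nrow(all_hits)) dt_lines <- c(dt_lines, format_domtblout(all_hits, qlen))
    writeLines(dt_lines, file.path(gdir, paste0(tid, ".domtblout")))

    sf_tab <- if (length(sf_rows)) do.call(rbind, sf_rows) else
      data.frame(protein_id = character(), superfamily_id = character(),
                 region = character(), evalue = character())
    utils::write.table(sf_tab, file.path(gdir, paste0(tid, ".supfam.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_ptt(genes, file.path(gdir, paste0(tid, ".ptt")),
              description = sprintf("%s - %s, complete genome",
                                    metadata$organism[gi], tid))
    seqs <- if (k > 0) stats::setNames(
      vapply(proteins, `[[`, character(1), "sequence"), pids) else
      stats::setNames(character(), character())
    write_fasta(seqs, file.path(gdir, paste0(tid, ".faa")))

    if (k > 0) {
      truth_proteins[[tid]] <- data.frame(
        protein_id = pids, taxon_id = tid, family = fams,
        n_pdz_hits = vapply(proteins, `[[`, integer(1), "n_pdz_hits"),
        n_other_domains = vapply(proteins, `[[`, integer(1), "n_other_domains"),
        localization = loc_cat, stringsAsFactors = FALSE)
    }
    if (length(decoys)) {
      dd <- do.call(rbind, decoys)
      dd$taxon_id <- tid
      dd$kept_search <- dd$seq_evalue <= 0.01 & dd$dom_evalue <= 0.03
      dd$kept_scan <- dd$seq_evalue <= 0.01 & dd$dom_evalue <= 0.01
      truth_decoys[[tid]] <- dd
    }
  }

  truth <- list(
    proteins = if (length(truth_proteins)) do.call(rbind, truth_proteins) else
      data.frame(protein_id = character(), taxon_id = character(),
                 family = character(), n_pdz_hits = integer(),
                 n_other_domains = integer(), localization = character()),
    genomes = data.frame(taxon_id = metadata$taxon_id, n_pdz_planted = n_pdz,
                         stringsAsFactors = FALSE),
    decoys = if (length(truth_decoys)) do.call(rbind, truth_decoys) else NULL,
    clusters = if (length(truth_clusters)) do.call(rbind, truth_clusters) else NULL,
    config = config)
  rownames(truth$proteins) <- NULL

  write_metadata(metadata, file.path(out_dir, "metadata.tsv"))
  loc <- if (length(loc_rows)) do.call(rbind, loc_rows) else
    data.frame(protein_id = character(), category = character())
  rownames(loc) <- NULL
  write_localization(loc, file.path(out_dir, "localization.tsv"))
  utils::write.table(truth$proteins, file.path(out_dir, "truth", "proteins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$genomes, file.path(out_dir, "truth", "genomes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(truth$decoys)) {
    utils::write.table(truth$decoys, file.path(out_dir, "truth", "decoys.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(truth$clusters)) {
    utils::write.table(truth$clusters, file.path(out_dir, "truth", "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(truth)
}
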