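# Rule-based assignment of PDZ-positive architectures to the twelve
# architecture-defined families, with motif corroboration.

FAMILY_IDS <- c("HTRA", "CTP", "RSEP", "APN", "LON", "SPOIVB", "AP", "ZEP",
                "GSPC", "FESO", "HAEM", "COMP")

#' The eight protease families
#' @return Character vector of family ids whose defining partner domain is a
#'   protease domain.
#' @export
protease_families <- function() {
  c("HTRA", "CTP", "RSEP", "APN", "LON", "SPOIVB", "AP", "ZEP")
}

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct a motif pattern
#'
#' Patterns are strings over the one-letter amino-acid alphabet plus `x`
#' (any residue), e.g. `"HExGH"` or `"CxxxCxxC"`. The region restricts where
#' along the sequence a match may start.
#'
#' @param name Motif name.
#' @param pattern Pattern string (length >= 3).
#' @param region `"ANY"`, `"N_TERMINAL_HALF"` or `"C_TERMINAL_HALF"`.
#' @return A `motif_pattern` object.
#' @export
motif_pattern <- function(name, pattern,
                          region = c("ANY", "N_TERMINAL_HALF", "C_TERMINAL_HALF")) {
  region <- match.arg(region)
  if (nchar(pattern) < 3) stop("motif pattern must have length >= 3")
  chars <- strsplit(pattern, "")[[1]]
  bad <- !(chars %in% AA_LETTERS | chars == "x")
  if (any(bad)) {
    stop("motif pattern contains invalid character(s): ",
         paste(unique(chars[bad]), collapse = ", "))
  }
  structure(list(name = name, pattern = pattern, region = region),
            class = "motif_pattern")
}

#' Find all matches of a motif pattern in a protein sequence
#'
#' A position matches when every non-`x` pattern letter equals the sequence
#' letter. The region constraint restricts the allowed match start: within
#' the first half of the sequence for `N_TERMINAL_HALF` (start <=
#' ceiling(L/2)) and within the second half for `C_TERMINAL_HALF` (match end
#' > floor(L/2)).
#'
#' @param sequence Protein sequence (one-letter codes).
#' @param pattern A [motif_pattern()] (or a bare pattern string, taken as
#'   region `"ANY"`).
#' @return Integer vector of 1-based match start positions.
#' @export
match_motif <- function(sequence, pattern) {
  if (is.character(pattern)) pattern <- motif_pattern(pattern, pattern)
  stopifnot(inherits(pattern, "motif_pattern"))
  seq_chars <- strsplit(toupper(sequence), "")[[1]]
  pat_chars <- strsplit(pattern$pattern, "")[[1]]
  L <- length(seq_chars); m <- length(pat_chars)
  if (m > L) return(integer())
  fixed <- which(pat_chars != "x")
  starts <- seq_len(L - m + 1L)
  hit <- vapply(starts, function(s) {
    all(seq_chars[s + fixed - 1L] == pat_chars[fixed])
  }, logical(1))
  pos <- starts[hit]
  if (pattern$region == "N_TERMINAL_HALF") {
    pos <- pos[pos <= ceiling(L / 2)]
  } else if (pattern$region == "C_TERMINAL_HALF") {
    pos <- pos[pos + m - 1L > floor(L / 2)]
  }
  pos
}

#' Domain-id synonyms
#'
#' Maps Pfam accessions and drifting release names onto the canonical ids the
#' family signatures use. Extend or replace to track a different Pfam
#' release.
#'
#' @return Named character vector: names are synonyms, values canonical ids.
#' @export
domain_synonyms <- function() {
  c(PF00089 = "Trypsin", Trypsin_2 = "Trypsin", Peptidase_S1 = "Trypsin",
    PF03572 = "Peptidase_S41", PF02163 = "Peptidase_M50",
    PF05299 = "Peptidase_M61", PF05362 = "Lon_C",
    PF05579 = "Peptidase_S55", PF00026 = "Asp_protease",
    Asp_protease_2 = "Asp_protease", PF04389 = "Peptidase_M28",
    PF11356 = "Pilus_P", T2SSC = "Pilus_P",
    PF04055 = "Radical_SAM", ChaN = "Haem_bd_uptake",
    PF05433 = "Haem_bd_uptake", PF07730 = "HisKA_3", PF02518 = "HATPase_c")
}

canonical_domain_ids <- function(ids, synonyms = domain_synonyms()) {
  hit <- match(ids, names(synonyms))
  ifelse(is.na(hit), ids, unname(synonyms[hit]))
}

#' Default family signatures
#'
#' The twelve architecture-defined families, in precedence order: the eight
#' protease families HtrA, Ctp (carboxy-terminal protease), RseP (regulator
#' of sigma-E protease), APN (aminopeptidase N), Lon protease, SpoIVB, AP
#' (aspartate protease) and ZEP (Zn-dependent exopeptidase), then the four
#' non-protease families GspC, Fe-S oxidoreductase, Haem-binding uptake and
#' ComP sensor histidine kinase. Every signature requires a PDZ domain plus
#' the listed partner domain(s); RseP additionally carries the HExGH and
#' NxxPxxxLDG motifs, and the Fe-S oxidoreductase the CxxxCxxC iron-sulfur
#' motif with the PDZ N-terminal to the radical SAM domain.
#'
#' @return List of `family_signature` records in precedence order.
#' @export
default_signatures <- function() {
  sig <- function(family_id, required, optional = character(),
                  motifs = list(), motif_mandatory = FALSE,
                  pdz_before = NULL) {
    structure(list(family_id = family_id, required = required,
                   optional = optional, motifs = motifs,
                   motif_mandatory = motif_mandatory,
                   pdz_before = pdz_before),
              class = "family_signature")
  }
  list(
    sig("HTRA", list("Trypsin")),
    sig("CTP", list("Peptidase_S41"),
        optional = c("DUF3340", "PG_binding_1", "Tricorn", "Tricorn_C1", "PD40")),
    sig("RSEP", list("Peptidase_M50"),
        motifs = list(motif_pattern("HExGH", "HExGH", "N_TERMINAL_HALF"),
                      motif_pattern("NxxPxxxLDG", "NxxPxxxLDG", "C_TERMINAL_HALF")),
        motif_mandatory = TRUE),
    sig("APN", list("Peptidase_M61")),
    sig("LON", list("Lon_C")),
    sig("SPOIVB", list("Peptidase_S55")),
    sig("AP", list("Asp_protease")),
    sig("ZEP", list("Peptidase_M28")),
    sig("GSPC", list("Pilus_P")),
    sig("FESO", list("Radical_SAM"),
        motifs = list(motif_pattern("CxxxCxxC", "CxxxCxxC", "ANY")),
        motif_mandatory = TRUE, pdz_before = "Radical_SAM"),
    sig("HAEM", list("Haem_bd_uptake")),
    sig("COMP", list("HisKA_3", "HATPase_c"))
  )
}

signature_satisfied <- function(sign, dom_ids, doms, pdz_ids, sequence) {
  # every required group must be met by at least one of its alternatives
  for (grp in sign$required) {
    if (!any(grp %in% dom_ids)) return(list(ok = FALSE))
  }
  if (!is.null(sign$pdz_before)) {
    pdz_start <- suppressWarnings(min(doms$start[doms$domain_id %in% pdz_ids]))
    other_start <- suppressWarnings(min(doms$start[doms$domain_id %in% sign$pdz_before]))
    if (!is.finite(pdz_start) || !is.finite(other_start) ||
        pdz_start >= other_start) {
      return(list(ok = FALSE))
    }
  }
  matched_motifs <- character()
  note <- ""
  if (length(sign$motifs)) {
    if (is.null(sequence) || is.na(sequence) || !nzchar(sequence)) {
      note <- "motif unchecked"
    } else {
      for (mp in sign$motifs) {
        if (length(match_motif(sequence, mp))) {
          matched_motifs <- c(matched_motifs, mp$name)
        } else if (sign$motif_mandatory) {
          return(list(ok = FALSE))
        }
      }
    }
  }
  list(ok = TRUE, matched_motifs = matched_motifs, note = note)
}

#' Classify one PDZ-positive protein into a family
#'
#' Signatures are evaluated in the fixed precedence order of
#' [default_signatures()]; the first satisfied signature wins. Motif checks
#' run only when a sequence is provided and are then mandatory for RseP and
#' the Fe-S oxidoreductase; without a sequence, domain evidence alone
#' suffices and the assignment is annotated "motif unchecked". A protein
#' matching no signature is UNCLASSIFIED.
#'
#' Matching uses logical domains: consecutive same-id segments separated by
#' fewer than `qlinker_gap` residues (e.g. a protease domain interrupted by a
#' Q-linker) count as one domain.
#'
#' @param arch A `protein_architecture` with `has_pdz = TRUE`.
#' @param sequence Optional protein sequence for motif corroboration.
#' @param signatures Signature list (default [default_signatures()]).
#' @param synonyms Domain-id synonym map (default [domain_synonyms()]).
#' @param pdz_ids Identifiers counted as PDZ.
#' @param qlinker_gap Residue gap below which split same-id segments merge.
#' @return A one-row data.frame: `protein_id`, `family_id` (or
#'   `"UNCLASSIFIED"`), `matched_domains`, `matched_motifs`,
#'   `confidence_note`.
#' @export
classify_protein <- function(arch, sequence = NULL,
                             signatures = default_signatures(),
                             synonyms = domain_synonyms(),
                             pdz_ids = pdz_domain_ids(), qlinker_gap = 60L) {
  stopifnot(inherits(arch, "protein_architecture"))
  if (!arch$has_pdz) {
    stop("classify_protein requires a PDZ-positive architecture (protein ",
         arch$protein_id, ")")
  }
  doms <- logical_domains(arch, max_gap = qlinker_gap)
  doms$domain_id <- canonical_domain_ids(doms$domain_id, synonyms)
  dom_ids <- unique(doms$domain_id)
  for (sign in signatures) {
    res <- signature_satisfied(sign, dom_ids, doms, pdz_ids, sequence)
    if (res$ok) {
      matched <- unlist(sign$required)[unlist(sign$required) %in% dom_ids]
      return(data.frame(
        protein_id = arch$protein_id, family_id = sign$family_id,
        matched_domains = paste(matched, collapse = ","),
        matched_motifs = paste(res$matched_motifs, collapse = ","),
        confidence_note = res$note, stringsAsFactors = FALSE))
    }
  }
  data.frame(protein_id = arch$protein_id, family_id = "UNCLASSIFIED",
             matched_domains = "", matched_motifs = "",
             confidence_note = "no signature satisfied; possibly divergent",
             stringsAsFactors = FALSE)
}

#' Classify a set of architectures
#'
#' @param archs Named list of `protein_architecture` objects (PDZ-negative
#'   entries are skipped).
#' @param sequences Optional named character vector of protein sequences.
#' @param taxon_ids Optional named character vector mapping protein id to
#'   genome (taxon) id; attached as a `taxon_id` column when given.
#' @param ... Passed to [classify_protein()].
#' @return Data.frame of family assignments, one row per PDZ-positive
#'   protein, in protein-id order (classification is order-invariant).
#' @export
classify_proteins <- function(archs, sequences = NULL, taxon_ids = NULL, ...) {
  archs <- archs[order(vapply(archs, `[[`, character(1), "protein_id"))]
  rows <- lapply(archs, function(a) {
    if (!a$has_pdz) return(NULL)
    seq <- if (!is.null(sequences)) unname(sequences[a$protein_id]) else NULL
    classify_protein(a, sequence = seq, ...)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(protein_id = character(), family_id = character(),
                      matched_domains = character(), matched_motifs = character(),
                      confidence_note = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  if (!is.null(taxon_ids)) out$taxon_id <- unname(taxon_ids[out$protein_id])
  out
}

#' Family-by-taxon summary matrix
#'
#' For each family and taxonomic group (phylum or kingdom), counts members
#' (proteins) and organisms (genomes with at least one member), the
#' "members/organisms" convention of phyletic summary tables.
#'
#' @param assignments Assignment data.frame with a `taxon_id` column.
#' @param metadata Genome metadata (see [read_metadata()]).
#' @param by `"phylum"` or `"kingdom"`.
#' @param bucket_map Optional named character vector mapping phylum to a
#'   display bucket (e.g. rare phyla to "Other bacteria"); applied only for
#'   `by = "phylum"`.
#' @param include_unclassified Keep the UNCLASSIFIED row (default TRUE).
#' @return Long-format data.frame: `family_id`, `group`, `members`,
#'   `organisms`.
#' @export
summarize_families <- function(assignments, metadata,
                               by = c("phylum", "kingdom"),
                               bucket_map = NULL,
                               include_unclassified = TRUE) {
  by <- match.arg(by)
  if (!"taxon_id" %in% names(assignments)) {
    stop("assignments need a taxon_id column")
  }
  orphan <- setdiff(unique(assignments$taxon_id), metadata$taxon_id)
  if (length(orphan)) {
    stop("assignments reference genomes absent from metadata: ",
         paste(orphan, collapse = ", "))
  }
  grp <- metadata[[by]][match(assignments$taxon_id, metadata$taxon_id)]
  if (by == "phylum" && !is.null(bucket_map)) {
    mapped <- bucket_map[grp]
    grp <- ifelse(is.na(mapped), grp, unname(mapped))
  }
  fams <- if (include_unclassified) c(FAMILY_IDS, "UNCLASSIFIED") else FAMILY_IDS
  keep <- assignments$family_id %in% fams
  a <- assignments[keep, , drop = FALSE]; grp <- grp[keep]
  if (!nrow(a)) {
    return(data.frame(family_id = character(), group = character(),
                      members = integer(), organisms = integer(),
                      stringsAsFactors = FALSE))
  }
  agg <- aggregate(list(members = a$protein_id),
                   by = list(family_id = a$family_id, group = grp), length)
  org <- aggregate(list(organisms = a$taxon_id),
                   by = list(family_id = a$family_id, group = grp),
                   function(x) length(unique(x)))
  out <- merge(agg, org, by = c("family_id", "group"))
  out$family_id <- factor(out$family_id, levels = fams)
  out <- out[order(out$family_id, out$group), , drop = FALSE]
  out$family_id <- as.character(out$family_id)
  rownames(out) <- NULL
  stopifnot(all(out$organisms <= out$members))
  out
}

#' Format a family summary as a members/organisms matrix
#'
#' @param summary Long-format summary from [summarize_families()].
#' @return Character matrix (families x groups) with `"members/organisms"`
#'   cells and empty strings where a family is absent.
#' @export
format_family_matrix <- function(summary) {
  fams <- unique(summary$family_id)
  groups <- sort(unique(summary$group))
  m <- matrix("", nrow = length(fams), ncol = length(groups),
              dimnames = list(fams, groups))
  for (i in seq_len(nrow(summary))) {
    m[summary$family_id[i], summary$group[i]] <-
      sprintf("%d/%d", summary$members[i], summary$organisms[i])
  }
  m
}

#' Fraction of classified proteins in protease families
#'
#' @param assignments Assignment data.frame.
#' @return Fraction of non-UNCLASSIFIED proteins whose family is one of the
#'   eight protease families.
#' @export
protease_fraction <- function(assignments) {
  cls <- assignments$family_id[assignments$family_id != "UNCLASSIFIED"]
  if (!length(cls)) stop("no classified proteins")
  mean(cls %in% protease_families())
}
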