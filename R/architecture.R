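# From raw domain hits to per-protein ordered, non-overlapping architectures.

#' Default PDZ domain identifiers
#'
#' Pfam families PDZ (PF00595, the metazoan canonical form), PDZ_2 (PF13180,
#' the noncanonical form found in plants and eubacteria), PDZ_1 (PF12812),
#' and the Superfamily PDZ accession 50156.
#'
#' @return Character vector of identifiers counted as PDZ.
#' @export
pdz_domain_ids <- function() {
  c("PDZ", "PDZ_1", "PDZ_2", "PF00595", "PF13180", "PF12812", "50156")
}

canonical_pdz_ids <- function() c("PDZ", "PF00595")

#' E-value inclusion threshold policy
#'
#' Two thresholds gate a hit: the full-sequence E-value must be at most
#' `seq_evalue_max` and the per-domain E-value at most `dom_evalue_max`
#' (both inclusive). Defaults: SEARCH mode (hmmsearch of the PDZ models
#' against each proteome) uses 0.01 and 0.03; SCAN mode (hmmscan of each
#' PDZ-positive protein against the full domain libraries) uses 0.01 and
#' 0.01.
#'
#' @param mode `"SEARCH"` or `"SCAN"`.
#' @param seq_evalue_max,dom_evalue_max Optional overrides (> 0).
#' @return A `threshold_policy` object.
#' @export
threshold_policy <- function(mode = c("SEARCH", "SCAN"),
                             seq_evalue_max = NULL, dom_evalue_max = NULL) {
  mode <- match.arg(mode)
  defaults <- list(SEARCH = c(0.01, 0.03), SCAN = c(0.01, 0.01))[[mode]]
  pol <- list(mode = mode,
              seq_evalue_max = if (is.null(seq_evalue_max)) defaults[1] else seq_evalue_max,
              dom_evalue_max = if (is.null(dom_evalue_max)) defaults[2] else dom_evalue_max)
  if (pol$seq_evalue_max <= 0 || pol$dom_evalue_max <= 0) {
    stop("threshold E-values must be > 0")
  }
  structure(pol, class = "threshold_policy")
}

#' @export
print.threshold_policy <- function(x, ...) {
  cat(sprintf("Threshold policy [%s]: seq E-value <= %g, domain E-value <= %g\n",
              x$mode, x$seq_evalue_max, x$dom_evalue_max))
  invisible(x)
}

#' Filter domain hits by an E-value threshold policy
#'
#' Keeps a hit iff `seq_evalue <= seq_evalue_max` and
#' `dom_evalue <= dom_evalue_max` (inclusive). Order is preserved; the
#' operation is idempotent and monotone in the thresholds.
#'
#' @param hits Domain-hit data.frame.
#' @param policy A [threshold_policy()].
#' @return The kept rows of `hits`.
#' @export
filter_hits <- function(hits, policy) {
  stopifnot(inherits(policy, "threshold_policy"))
  assert_domain_hits(hits)
  if (!nrow(hits)) return(hits)
  keep <- hits$seq_evalue <= policy$seq_evalue_max &
    hits$dom_evalue <= policy$dom_evalue_max
  hits[keep, , drop = FALSE]
}

hit_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
}

pair_compatible <- function(s1, e1, s2, e2, overlap_tol) {
  ov <- hit_overlap(s1, e1, s2, e2)
  shorter <- pmin(e1 - s1 + 1L, e2 - s2 + 1L)
  ov <= overlap_tol * shorter
}

#' Resolve overlapping hits on one protein
#'
#' Selects, among all subsets of hits in which every pair overlaps by at most
#' `overlap_tol` of the shorter hit's length, the subset with maximum total
#' bit score (exact branch-and-bound search; `NA` scores count as zero and
#' rank last). Ties are broken deterministically in favor of hits with higher
#' bit score, then smaller start, then lexicographic domain id. Beyond
#' `max_exact` hits the same ordering is used greedily. The result is sorted
#' by start.
#'
#' @param hits Domain-hit data.frame, all rows for one protein.
#' @param overlap_tol Maximum allowed pairwise overlap as a fraction of the
#'   shorter hit (default 0.2: preserves adjacent tandem repeats while
#'   removing duplicate calls).
#' @param max_exact Hit count above which the greedy fallback is used.
#' @return The kept rows, sorted by start.
#' @export
resolve_overlaps <- function(hits, overlap_tol = 0.2, max_exact = 30L) {
  assert_domain_hits(hits)
  n <- nrow(hits)
  if (n <= 1) return(hits)
  if (length(unique(hits$protein_id)) > 1) {
    stop("resolve_overlaps expects hits for a single protein")
  }
  score <- ifelse(is.na(hits$bit_score), 0, hits$bit_score)
  ord <- order(-score, hits$start, hits$domain_id)
  h <- hits[ord, , drop = FALSE]
  w <- score[ord]
  compat <- outer(seq_len(n), seq_len(n), function(i, j) {
    pair_compatible(h$start[i], h$end[i], h$start[j], h$end[j], overlap_tol)
  })
  diag(compat) <- TRUE

  if (n > max_exact) {
    kept <- integer()
    for (i in seq_len(n)) if (all(compat[i, kept])) kept <- c(kept, i)
  } else {
    best <- list(score = -Inf, set = integer())
    suffix <- rev(cumsum(rev(w)))
    search <- function(i, set, tot) {
      if (i > n) {
        if (tot > best$score) best <<- list(score = tot, set = set)
        return(invisible())
      }
      if (tot + suffix[i] <= best$score) return(invisible())
      if (all(compat[i, set])) search(i + 1L, c(set, i), tot + w[i])
      search(i + 1L, set, tot)
    }
    search(1L, integer(), 0)
    kept <- best$set
  }
  out <- h[kept, , drop = FALSE]
  out[order(out$start, out$end, out$domain_id), , drop = FALSE]
}

#' Merge Pfam and Superfamily hits for one protein
#'
#' Pfam is the reference annotation; Superfamily is the cross-check. A
#' Superfamily hit that overlaps some Pfam hit by at least `absorb_frac` of
#' either hit's extent is absorbed as corroboration (the Pfam record is kept
#' and flagged `corroborated`), so a Superfamily PDZ nested in a Pfam PDZ is
#' never double-counted. Superfamily hits with no such overlap are appended
#' as independent domains — this is how PDZ domains detected only by the
#' Superfamily model survive.
#'
#' @param pfam,superfam Threshold-filtered domain-hit data.frames for one
#'   protein.
#' @param absorb_frac Mutual-overlap fraction for absorption (default 0.5).
#' @return Combined hit data.frame with a logical `corroborated` column.
#' @export
merge_cross_db <- function(pfam, superfam, absorb_frac = 0.5) {
  assert_domain_hits(pfam); assert_domain_hits(superfam)
  pfam$corroborated <- logical(nrow(pfam))
  if (!nrow(superfam)) return(pfam)
  superfam$corroborated <- FALSE
  if (!nrow(pfam)) return(superfam)
  keep_sf <- logical(nrow(superfam))
  for (i in seq_len(nrow(superfam))) {
    ov <- hit_overlap(superfam$start[i], superfam$end[i], pfam$start, pfam$end)
    len_sf <- superfam$end[i] - superfam$start[i] + 1L
    len_pf <- pfam$end - pfam$start + 1L
    absorbed <- ov >= absorb_frac * len_sf | ov >= absorb_frac * len_pf
    if (any(absorbed)) {
      pfam$corroborated[absorbed] <- TRUE
    } else {
      keep_sf[i] <- TRUE
    }
  }
  rbind(pfam, superfam[keep_sf, , drop = FALSE])
}

#' Build a protein's domain architecture
#'
#' Takes hits that have already been filtered, merged across databases, and
#' overlap-resolved, and returns the ordered architecture. The tandem PDZ
#' count is the number of kept hits whose identifier is a PDZ identifier
#' (two or more PDZ hits on one protein are tandem repeats). The PDZ flavor
#' is CANONICAL if every PDZ hit is the canonical Pfam family (PDZ/PF00595),
#' NONCANONICAL if none is, MIXED otherwise, and NONE without PDZ.
#'
#' @param protein_id Protein identifier.
#' @param hits Resolved domain-hit data.frame for this protein (possibly
#'   zero rows).
#' @param pdz_ids Identifiers counted as PDZ (default [pdz_domain_ids()]).
#' @return A `protein_architecture` object.
#' @export
build_architecture <- function(protein_id, hits, pdz_ids = pdz_domain_ids()) {
  assert_domain_hits(hits)
  if (nrow(hits)) {
    hits <- hits[order(hits$start, hits$end, hits$domain_id), , drop = FALSE]
  }
  if (!"corroborated" %in% names(hits)) hits$corroborated <- logical(nrow(hits))
  is_pdz <- hits$domain_id %in% pdz_ids
  n_pdz <- sum(is_pdz)
  flavor <- if (n_pdz == 0) {
    "NONE"
  } else {
    canon <- hits$domain_id[is_pdz] %in% canonical_pdz_ids()
    if (all(canon)) "CANONICAL" else if (!any(canon)) "NONCANONICAL" else "MIXED"
  }
  structure(list(
    protein_id = protein_id,
    domains = hits[, c("domain_id", "source", "start", "end", "bit_score",
                       "seq_evalue", "dom_evalue", "corroborated")],
    tandem_pdz_count = n_pdz,
    has_pdz = n_pdz >= 1L,
    pdz_flavor = flavor
  ), class = "protein_architecture")
}

#' @export
print.protein_architecture <- function(x, ...) {
  cat(sprintf("Protein %s: %s\n", x$protein_id, architecture_string(x)))
  cat(sprintf("  tandem PDZ count: %d, flavor: %s\n",
              x$tandem_pdz_count, x$pdz_flavor))
  invisible(x)
}

#' Architecture string of a protein
#' @param arch A `protein_architecture`.
#' @return Domain ids joined with en dashes, or `"(none)"`.
#' @export
architecture_string <- function(arch) {
  if (!nrow(arch$domains)) return("(none)")
  paste(arch$domains$domain_id, collapse = "-")
}

#' Collapse split same-domain segments into logical domains
#'
#' Consecutive segments with the same domain id separated by fewer than
#' `max_gap` residues are treated as one logical domain (for example a
#' trypsin protease domain interrupted by a Q-linker stretch). Used by the
#' classifier; tandem counting keeps the raw hits.
#'
#' @param arch A `protein_architecture`.
#' @param max_gap Residue gap below which same-id segments merge (default 60).
#' @return Data.frame of logical domains (`domain_id`, `start`, `end`).
#' @export
logical_domains <- function(arch, max_gap = 60L) {
  d <- arch$domains
  if (!nrow(d)) return(data.frame(domain_id = character(), start = integer(),
                                  end = integer(), stringsAsFactors = FALSE))
  out <- d[1, c("domain_id", "start", "end")]
  for (i in seq_len(nrow(d))[-1]) {
    j <- nrow(out)
    gap <- d$start[i] - out$end[j] - 1L
    if (d$domain_id[i] == out$domain_id[j] && gap < max_gap) {
      out$end[j] <- max(out$end[j], d$end[i])
    } else {
      out <- rbind(out, d[i, c("domain_id", "start", "end")])
    }
  }
  rownames(out) <- NULL
  out
}

#' Full per-protein ingestion: filter, merge, resolve, build
#'
#' Convenience wrapper applying the standard stage order to one proteome's
#' raw Pfam and Superfamily hit tables.
#'
#' @param pfam,superfam Raw domain-hit data.frames for one proteome.
#' @param policy A [threshold_policy()] applied to both tables.
#' @param overlap_tol,absorb_frac See [resolve_overlaps()] and
#'   [merge_cross_db()].
#' @param pdz_ids Identifiers counted as PDZ.
#' @return Named list of `protein_architecture` objects, one per protein with
#'   at least one kept hit.
#' @export
build_architectures <- function(pfam, superfam = empty_domain_hits(),
                                policy = threshold_policy("SCAN"),
                                overlap_tol = 0.2, absorb_frac = 0.5,
                                pdz_ids = pdz_domain_ids()) {
  pfam <- filter_hits(pfam, policy)
  superfam <- filter_hits(superfam, policy)
  ids <- sort(unique(c(pfam$protein_id, superfam$protein_id)))
  out <- lapply(ids, function(pid) {
    merged <- merge_cross_db(pfam[pfam$protein_id == pid, , drop = FALSE],
                             superfam[superfam$protein_id == pid, , drop = FALSE],
                             absorb_frac = absorb_frac)
    resolved <- resolve_overlaps(merged[, DOMAIN_HIT_COLS], overlap_tol = overlap_tol)
    # realign corroboration flags by hit identity after resolution
    resolved$corroborated <- merged$corroborated[match(
      paste(resolved$domain_id, resolved$start, resolved$end, resolved$source),
      paste(merged$domain_id, merged$start, merged$end, merged$source))]
    build_architecture(pid, resolved, pdz_ids = pdz_ids)
  })
  names(out) <- ids
  out
}

#' Summarize architectures as a per-protein table
#'
#' @param archs Named list of `protein_architecture` objects.
#' @param taxon_id Genome (taxon) id attached to every row.
#' @param pdz_ids Identifiers counted as PDZ.
#' @return Data.frame with one row per protein: architecture string, domain
#'   counts, tandem PDZ count, flavor, and multidomain flag (at least one
#'   non-PDZ domain; proteins with repetitive PDZ alone are not multidomain).
#' @export
summarize_architectures <- function(archs, taxon_id = NA_character_,
                                    pdz_ids = pdz_domain_ids()) {
  if (!length(archs)) {
    return(data.frame(protein_id = character(), taxon_id = character(),
                      architecture = character(), n_domains = integer(),
                      n_other_domains = integer(), tandem_pdz_count = integer(),
                      has_pdz = logical(), pdz_flavor = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(archs, function(a) {
    n_other <- sum(!a$domains$domain_id %in% pdz_ids)
    data.frame(protein_id = a$protein_id, taxon_id = taxon_id,
               architecture = architecture_string(a),
               n_domains = nrow(a$domains), n_other_domains = n_other,
               tandem_pdz_count = a$tandem_pdz_count, has_pdz = a$has_pdz,
               pdz_flavor = a$pdz_flavor, stringsAsFactors = FALSE)
  }))
}
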