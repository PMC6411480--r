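# Codirectional gene neighborhoods around PDZ-coding genes.

#' Intergenic distance between two genes
#'
#' Number of bases strictly between two genes on the same replicon with
#' 1-based inclusive coordinates: `d = start(b) - end(a) - 1`. Requires
#' `a$end < b$start`; callers dealing with overlapping or abutting genes
#' (common in prokaryotes) should clamp with `max(0, ...)` as
#' [find_neighborhood()] does.
#'
#' @param a,b Gene records (one-row data.frames or lists with `replicon_id`,
#'   `start`, `end`), `a` upstream of `b`.
#' @return Integer distance (>= 0).
#' @export
intergenic_distance <- function(a, b) {
  if (a$replicon_id != b$replicon_id) {
    stop("genes are on different replicons: ", a$replicon_id, " vs ",
         b$replicon_id)
  }
  if (!(a$end < b$start)) {
    stop("intergenic_distance requires a.end < b.start")
  }
  as.integer(b$start - a$end - 1L)
}

gene_gap <- function(end_prev, start_next) {
  as.integer(pmax(0L, start_next - end_prev - 1L))
}

#' Extract the codirectional neighborhood around an anchor gene
#'
#' A gene is a neighbor of a PDZ-coding anchor gene if it is codirectional
#' (same strand, same replicon) and within `max_gap` nucleotides. By default
#' the chain extends transitively in both directions (operon-style): the next
#' gene joins while it is same-strand, same-replicon and at most `max_gap`
#' bases from the previous member, and extension stops at the first violation
#' in each direction. With `pairwise = TRUE` the distance is instead measured
#' from the anchor itself and intervening opposite-strand genes still break
#' the chain. Overlapping or abutting genes count as distance 0. Replicons
#' are treated as linear (the origin junction of a circular replicon is not
#' joined).
#'
#' @param genes Gene-record data.frame sorted by start (one replicon's
#'   annotation, e.g. from [read_ptt()]).
#' @param anchor Locus tag of the anchor gene, or its row index in `genes`.
#' @param max_gap Maximum intergenic distance in nucleotides (default 50; use
#'   300 to reproduce the E. coli exception).
#' @param pairwise Measure gaps from the anchor rather than chaining.
#' @return A `neighborhood_cluster`: list with `genome_id`, `anchor_index`
#'   (into `members`), `anchor`, `members` (ordered gene records), `gaps`
#'   (distances between consecutive members), `max_gap`.
#' @export
find_neighborhood <- function(genes, anchor, max_gap = 50L, pairwise = FALSE) {
  if (!nrow(genes)) stop("empty gene table")
  if (is.character(anchor)) {
    idx <- which(genes$locus_tag == anchor)
    if (length(idx) != 1) stop("anchor locus tag not found (or ambiguous): ", anchor)
  } else {
    idx <- as.integer(anchor)
    if (is.na(idx) || idx < 1 || idx > nrow(genes)) stop("anchor index out of range")
  }
  g <- genes[genes$replicon_id == genes$replicon_id[idx], , drop = FALSE]
  ord <- order(g$start, g$end)
  if (is.unsorted(g$start)) g <- g[ord, , drop = FALSE]
  i <- which(g$start == genes$start[idx] & g$end == genes$end[idx] &
               g$locus_tag == genes$locus_tag[idx])[1]
  strand <- g$strand[i]
  lo <- hi <- i
  while (hi < nrow(g) &&
         g$strand[hi + 1L] == strand &&
         (if (pairwise) {
            gene_gap(g$end[i], g$start[hi + 1L]) <= max_gap
          } else {
            gene_gap(g$end[hi], g$start[hi + 1L]) <= max_gap
          })) {
    hi <- hi + 1L
  }
  while (lo > 1L &&
         g$strand[lo - 1L] == strand &&
         (if (pairwise) {
            gene_gap(g$end[lo - 1L], g$start[i]) <= max_gap
          } else {
            gene_gap(g$end[lo - 1L], g$start[lo]) <= max_gap
          })) {
    lo <- lo - 1L
  }
  members <- g[lo:hi, , drop = FALSE]
  rownames(members) <- NULL
  gaps <- if (nrow(members) > 1) {
    gene_gap(members$end[-nrow(members)], members$start[-1])
  } else integer()
  structure(list(genome_id = members$replicon_id[1],
                 anchor_index = i - lo + 1L,
                 anchor = members[i - lo + 1L, , drop = FALSE],
                 members = members, gaps = gaps, max_gap = max_gap,
                 pairwise = pairwise),
            class = "neighborhood_cluster")
}

#' @export
print.neighborhood_cluster <- function(x, ...) {
  lab <- ifelse(nzchar(x$members$gene_name), x$members$gene_name,
                x$members$locus_tag)
  lab[x$anchor_index] <- paste0("[", lab[x$anchor_index], "]")
  cat(sprintf("Neighborhood on %s (%s strand, max gap %d): %s\n",
              x$genome_id, x$members$strand[1], x$max_gap,
              paste(lab, collapse = " - ")))
  invisible(x)
}

neighbor_key <- function(members, key) {
  if (key == "PRODUCT") {
    k <- members$product
  } else {
    # gene name, falling back to locus tag when no name is available
    k <- ifelse(nzchar(members$gene_name), members$gene_name, members$locus_tag)
  }
  ifelse(nzchar(k), k, "unnamed")
}

#' Cross-genome conservation of neighborhood genes
#'
#' Counts, for each non-anchor neighbor key, the number of distinct genomes
#' whose cluster contains it. Keys are gene names with locus-tag fallback (or
#' products); genes with neither are aggregated under `"unnamed"`.
#'
#' @param clusters List of `neighborhood_cluster` objects.
#' @param key `"GENE_NAME"` or `"PRODUCT"`.
#' @return Data.frame (`neighbor`, `genomes`) sorted by descending genome
#'   count, ties broken alphabetically.
#' @export
conserved_neighbors <- function(clusters, key = c("GENE_NAME", "PRODUCT")) {
  key <- match.arg(key)
  if (!length(clusters)) stop("no clusters given")
  per_genome <- lapply(clusters, function(cl) {
    ks <- neighbor_key(cl$members, key)[-cl$anchor_index]
    if (!length(ks)) return(NULL)
    unique(data.frame(genome = cl$genome_id, neighbor = ks,
                      stringsAsFactors = FALSE))
  })
  all <- unique(do.call(rbind, per_genome))
  if (is.null(all) || !nrow(all)) {
    return(data.frame(neighbor = character(), genomes = integer(),
                      stringsAsFactors = FALSE))
  }
  counts <- aggregate(list(genomes = all$genome),
                      by = list(neighbor = all$neighbor),
                      function(x) length(unique(x)))
  counts <- counts[order(-counts$genomes, counts$neighbor), , drop = FALSE]
  rownames(counts) <- NULL
  counts
}
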