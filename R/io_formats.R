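# Readers and writers for the external formats the survey touches.
# All coordinates are 1-based inclusive (HMMER and NCBI PTT both use this
# convention); every reader documents it and every record keeps it.

DOMAIN_HIT_COLS <- c("protein_id", "domain_id", "source", "seq_evalue",
                     "dom_evalue", "start", "end", "bit_score")

KINGDOMS   <- c("EUBACTERIA", "ARCHAEA", "FUNGI")
GRAMS      <- c("POSITIVE", "NEGATIVE")
HABITATS   <- c("AQUATIC", "TERRESTRIAL", "MULTIPLE", "HOST_ASSOCIATED", "SPECIALIZED")
OXYGENS    <- c("AEROBIC", "ANAEROBIC", "FACULTATIVE")
LOC_CATEGORIES <- c("TM", "SP", "TMSP", "CYT", "NAN")

#' Empty domain-hit table
#'
#' @return A zero-row data.frame with the domain-hit columns.
#' @keywords internal
empty_domain_hits <- function() {
  data.frame(protein_id = character(), domain_id = character(),
             source = character(), seq_evalue = numeric(),
             dom_evalue = numeric(), start = integer(), end = integer(),
             bit_score = numeric(), stringsAsFactors = FALSE)
}

assert_domain_hits <- function(hits) {
  stopifnot(is.data.frame(hits), all(DOMAIN_HIT_COLS %in% names(hits)))
  if (nrow(hits)) {
    bad <- hits$start < 1L | hits$start > hits$end
    if (any(bad)) {
      stop("invalid hit coordinates (need 1 <= start <= end) for: ",
           paste(hits$protein_id[bad], collapse = ", "))
    }
    if (any(hits$seq_evalue < 0 | hits$dom_evalue < 0, na.rm = TRUE)) {
      stop("negative E-values in hit table")
    }
  }
  invisible(hits)
}

#' Read an HMMER3 per-domain hit table (domtblout)
#'
#' Parses the whitespace-separated `--domtblout` format written by HMMER3.
#' Lines starting with `#` are comments. Domain extent is taken from the
#' envelope coordinates (columns 20-21), HMMER's stated region for the
#' domain's location; coordinates are 1-based inclusive residue positions.
#' The full-sequence E-value (column 7) is stored as `seq_evalue` and the
#' per-domain independent E-value (column 13) as `dom_evalue`.
#'
#' @param path Path to a domtblout file.
#' @param program Which program wrote the table: `"hmmscan"` (target = domain
#'   model, query = protein; the default, matching a scan of each protein
#'   against the full Pfam library) or `"hmmsearch"` (target = protein,
#'   query = domain model).
#' @return A data.frame of domain hits with `source = "PFAM"`, one row per
#'   non-comment line.
#' @export
read_domtblout <- function(path, program = c("hmmscan", "hmmsearch")) {
  program <- match.arg(program)
  if (!file.exists(path)) stop("cannot read domtblout file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) return(empty_domain_hits())
  rows <- lapply(idx, function(i) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) < 22) {
      stop("malformed domtblout row at line ", i, " of ", basename(path),
           ": expected >= 22 fields, got ", length(f))
    }
    num <- suppressWarnings(as.numeric(f[c(7, 13, 14, 20, 21)]))
    if (anyNA(num)) {
      stop("non-numeric E-value/score/coordinate at line ", i, " of ",
           basename(path))
    }
    if (program == "hmmscan") {
      dom <- f[1]; prot <- f[4]
    } else {
      dom <- f[4]; prot <- f[1]
    }
    data.frame(protein_id = prot, domain_id = dom, source = "PFAM",
               seq_evalue = num[1], dom_evalue = num[2],
               start = as.integer(num[4]), end = as.integer(num[5]),
               bit_score = num[3], stringsAsFactors = FALSE)
  })
  assert_domain_hits(do.call(rbind, rows))
}

#' Read a Superfamily-style domain assignment table
#'
#' Tab-separated with a header naming `protein_id`, `superfamily_id`,
#' `region` (`"start-end"`, 1-based inclusive) and `evalue`. Superfamily
#' assignments carry a single E-value; it is stored in both `seq_evalue` and
#' `dom_evalue` so one threshold policy applies uniformly across sources.
#' No bit score is available; `bit_score` is `NA` and such hits rank last
#' during overlap resolution.
#'
#' @param path Path to the TSV file.
#' @return A data.frame of domain hits with `source = "SUPERFAMILY"`.
#' @export
read_superfamily_table <- function(path) {
  if (!file.exists(path)) stop("cannot read superfamily table: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("protein_id", "superfamily_id", "region", "evalue")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("superfamily table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!nrow(tab)) return(empty_domain_hits())
  ok <- grepl("^[0-9]+-[0-9]+$", tab$region)
  if (any(!ok)) {
    stop("malformed region (expected \"start-end\") at data line(s) ",
         paste(which(!ok), collapse = ", "), " of ", basename(path))
  }
  parts <- do.call(rbind, strsplit(tab$region, "-", fixed = TRUE))
  start <- as.integer(parts[, 1]); end <- as.integer(parts[, 2])
  if (any(start > end)) {
    stop("region start > end at data line(s) ",
         paste(which(start > end), collapse = ", "), " of ", basename(path))
  }
  ev <- suppressWarnings(as.numeric(tab$evalue))
  if (anyNA(ev)) {
    stop("non-numeric E-value at data line(s) ",
         paste(which(is.na(ev)), collapse = ", "), " of ", basename(path))
  }
  assert_domain_hits(data.frame(
    protein_id = tab$protein_id, domain_id = tab$superfamily_id,
    source = "SUPERFAMILY", seq_evalue = ev, dom_evalue = ev,
    start = start, end = end, bit_score = NA_real_,
    stringsAsFactors = FALSE))
}

PTT_HEADER <- c("Location", "Strand", "Length", "PID", "Gene", "Synonym",
                "Code", "COG", "Product")

#' Read an NCBI PTT gene annotation table
#'
#' NCBI PTT dialect: two header lines (description, column names; a third
#' `Location...` line from files that also carry a protein-count line is
#' tolerated), then tab-separated rows whose first column is `start..end`
#' (1-based inclusive) and second is the strand. A location with start > end
#' never encodes strand (strand has its own column) and is rejected as
#' malformed. Records are returned sorted by start.
#'
#' @param path Path to the PTT file.
#' @param replicon_id Replicon identifier to attach to every record; defaults
#'   to the file name without its `.ptt` extension.
#' @return A data.frame of gene records (`replicon_id`, `start`, `end`,
#'   `strand`, `locus_tag`, `gene_name`, `product`, `protein_id`).
#' @export
read_ptt <- function(path, replicon_id = NULL) {
  if (!file.exists(path)) stop("cannot read PTT file: ", path)
  if (is.null(replicon_id)) replicon_id <- sub("\\.ptt$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stop("PTT file has fewer than 2 header lines: ", path)
  body_at <- 3L
  if (length(lines) >= 3 && grepl("^Location", lines[3])) body_at <- 4L
  if (length(lines) < body_at) return(empty_gene_records(replicon_id))
  data_lines <- lines[body_at:length(lines)]
  data_idx <- seq(body_at, length(lines))
  keep <- nzchar(trimws(data_lines))
  data_lines <- data_lines[keep]; data_idx <- data_idx[keep]
  if (!length(data_lines)) return(empty_gene_records(replicon_id))
  rows <- lapply(seq_along(data_lines), function(k) {
    f <- strsplit(data_lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) {
      stop("malformed PTT row at line ", data_idx[k], " of ", basename(path),
           ": expected 9 tab-separated fields")
    }
    if (!grepl("^[0-9]+\\.\\.[0-9]+$", f[1])) {
      stop("malformed PTT location \"", f[1], "\" (expected start..end) at line ",
           data_idx[k], " of ", basename(path))
    }
    se <- as.integer(strsplit(f[1], "..", fixed = TRUE)[[1]])
    if (se[1] > se[2]) {
      stop("PTT location start > end at line ", data_idx[k], " of ",
           basename(path))
    }
    if (!f[2] %in% c("+", "-")) {
      stop("invalid strand \"", f[2], "\" at line ", data_idx[k], " of ",
           basename(path))
    }
    blank <- function(x) if (x %in% c("-", "")) "" else x
    data.frame(replicon_id = replicon_id, start = se[1], end = se[2],
               strand = f[2], locus_tag = blank(f[6]),
               gene_name = blank(f[5]), product = blank(f[9]),
               protein_id = blank(f[4]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), , drop = FALSE]
}

empty_gene_records <- function(replicon_id = character()) {
  data.frame(replicon_id = character(), start = integer(), end = integer(),
             strand = character(), locus_tag = character(),
             gene_name = character(), product = character(),
             protein_id = character(), stringsAsFactors = FALSE)
}

#' Write gene records as an NCBI PTT table
#'
#' Emits the two-header-line dialect that [read_ptt()] consumes, so a
#' write/read round trip reproduces the records field-for-field.
#'
#' @param genes Gene-record data.frame (see [read_ptt()]).
#' @param path Output path.
#' @param description Free-text first header line.
#' @return `path`, invisibly.
#' @export
write_ptt <- function(genes, path, description = "synthetic replicon") {
  dash <- function(x) ifelse(nzchar(x), x, "-")
  rows <- sprintf("%d..%d\t%s\t%d\t%s\t%s\t%s\t-\t-\t%s",
                  genes$start, genes$end, genes$strand,
                  pmax((genes$end - genes$start + 1L - 3L) %/% 3L, 1L),
                  dash(genes$protein_id), dash(genes$gene_name),
                  dash(genes$locus_tag), dash(genes$product))
  writeLines(c(description, paste(PTT_HEADER, collapse = "\t"), rows), path)
  invisible(path)
}

parse_enum <- function(x, levels, field, na_with_warning = TRUE) {
  up <- toupper(trimws(x))
  up[up %in% c("", "NA", "N/A", "NAN", "-", "UNKNOWN")] <- NA_character_
  bad <- !is.na(up) & !up %in% levels
  if (any(bad)) {
    if (na_with_warning) {
      warning("unknown ", field, " value(s) mapped to NA: ",
              paste(unique(x[bad]), collapse = ", "), call. = FALSE)
      up[bad] <- NA_character_
    } else {
      stop("invalid ", field, " value(s): ", paste(unique(x[bad]), collapse = ", "))
    }
  }
  up
}

#' Read a genome phenotype metadata table
#'
#' Tab-separated with a header naming `taxon_id`, `organism`, `kingdom`,
#' `phylum`, `gram`, `habitat`, `oxygen`, `genome_size_mb` (the fields of the
#' legacy NCBI microbial genome project tables). Enumerated fields are parsed
#' case-insensitively; unknown gram/habitat/oxygen strings map to `NA` with a
#' warning, while an unknown kingdom is an error.
#'
#' @param path Path to the TSV file.
#' @return A data.frame of genome metadata.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("cannot read metadata table: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("taxon_id", "organism", "kingdom", "phylum", "gram", "habitat",
            "oxygen", "genome_size_mb")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("metadata table missing column(s): ",
                         paste(miss, collapse = ", "))
  tab$taxon_id <- as.character(tab$taxon_id)
  tab$kingdom <- parse_enum(tab$kingdom, KINGDOMS, "kingdom",
                            na_with_warning = FALSE)
  if (anyNA(tab$kingdom)) stop("metadata rows with missing kingdom")
  tab$gram    <- parse_enum(tab$gram, GRAMS, "gram")
  tab$habitat <- parse_enum(tab$habitat, HABITATS, "habitat")
  tab$oxygen  <- parse_enum(tab$oxygen, OXYGENS, "oxygen")
  tab$genome_size_mb <- as.numeric(tab$genome_size_mb)
  if (any(!is.na(tab$genome_size_mb) & tab$genome_size_mb <= 0)) {
    stop("genome_size_mb must be > 0 when present")
  }
  tab[need]
}

#' Write a genome metadata table (TSV)
#' @param metadata Metadata data.frame (see [read_metadata()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a per-protein subcellular localization table
#'
#' Tab-separated with header columns `protein_id` and `category`; categories
#' are the Phobius-style calls TM (transmembrane helix), SP (signal peptide),
#' TMSP (both) and CYT (cytoplasmic), plus NaN for proteins without a
#' prediction. Parsing is case-insensitive; an unrecognized category is a
#' format error.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with `protein_id` and `category`.
#' @export
read_localization <- function(path) {
  if (!file.exists(path)) stop("cannot read localization table: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  miss <- setdiff(c("protein_id", "category"), names(tab))
  if (length(miss)) stop("localization table missing column(s): ",
                         paste(miss, collapse = ", "))
  up <- toupper(trimws(tab$category))
  up[up %in% c("", "NA", "N/A")] <- "NAN"
  bad <- !up %in% LOC_CATEGORIES
  if (any(bad)) stop("invalid localization category value(s): ",
                     paste(unique(tab$category[bad]), collapse = ", "))
  data.frame(protein_id = tab$protein_id, category = up,
             stringsAsFactors = FALSE)
}

#' Write a localization table (TSV)
#' @param loc Localization data.frame (`protein_id`, `category`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_localization <- function(loc, path) {
  out <- loc
  out$category[out$category == "NAN"] <- "NaN"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

ITOL_FIELD_COLORS <- c(TM = "#1f78b4", SP = "#33a02c", TMSP = "#ff7f00",
                       CYT = "#e31a1c")

#' Write an iTOL multi-value bar annotation dataset
#'
#' One data line per genome: the taxon id followed by the counts of PDZ
#' proteins in the four predicted localization categories (TM, SP, TMSP,
#' CYT), so bar height is proportional to the number of PDZ
#' domain-containing proteins with a localization call. Before writing, the
#' four counts are checked to sum to the genome's PDZ-protein total with
#' known localization.
#'
#' @param profiles Genome-profile data.frame from [build_profiles()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_itol_bars <- function(profiles, path) {
  if (!nrow(profiles)) stop("no genome profiles to write")
  if (anyDuplicated(profiles$taxon_id)) {
    stop("duplicate taxon_id in profiles: ",
         paste(unique(profiles$taxon_id[duplicated(profiles$taxon_id)]),
               collapse = ", "))
  }
  known <- profiles$loc_TM + profiles$loc_SP + profiles$loc_TMSP + profiles$loc_CYT
  expect <- profiles$n_pdz_proteins - profiles$loc_NAN
  if (any(known != expect)) {
    stop("localization counts do not sum to known-localization protein totals for: ",
         paste(profiles$taxon_id[known != expect], collapse = ", "))
  }
  header <- c("DATASET_MULTIBAR", "SEPARATOR COMMA",
              "DATASET_LABEL,PDZ protein localization",
              "COLOR,#1f78b4",
              paste0("FIELD_COLORS,", paste(ITOL_FIELD_COLORS, collapse = ",")),
              paste0("FIELD_LABELS,", paste(names(ITOL_FIELD_COLORS), collapse = ",")),
              "DATA")
  rows <- sprintf("%s,%d,%d,%d,%d", profiles$taxon_id, profiles$loc_TM,
                  profiles$loc_SP, profiles$loc_TMSP, profiles$loc_CYT)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a FASTA file of protein sequences
#'
#' Minimal FASTA reader for the motif-matching step: returns a named
#' character vector of sequences keyed by the first whitespace-delimited
#' token of each header.
#'
#' @param path Path to the FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) return(setNames(character(), character()))
  if (!hdr[1]) stop("FASTA file does not start with a header line: ", path)
  id <- sub("^>([^ \t]+).*$", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  setNames(as.character(seqs[as.character(seq_along(id))]), id)
}

#' Write protein sequences as FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}
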