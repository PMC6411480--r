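# Per-genome count profiles and nonparametric group comparisons.

#' Build per-genome PDZ count profiles
#'
#' One profile per metadata row (genomes without PDZ proteins get zero
#' counts): number of PDZ proteins, number of PDZ domains (sum of tandem
#' counts), number of multidomain PDZ proteins (at least one non-PDZ domain;
#' proteins with repetitive PDZ alone are not multidomain), and localization
#' tallies. Proteins absent from the localization table count as NAN.
#'
#' @param architectures Per-protein architecture summary
#'   ([summarize_architectures()] output, with `taxon_id`), PDZ-positive rows.
#' @param localizations Localization data.frame (`protein_id`, `category`).
#' @param metadata Genome metadata (see [read_metadata()]).
#' @param assignments Optional assignment data.frame; used only to check
#'   protein-to-genome consistency.
#' @return Data.frame: metadata columns plus `n_pdz_proteins`,
#'   `n_pdz_domains`, `n_multidomain`, `loc_TM`, `loc_SP`, `loc_TMSP`,
#'   `loc_CYT`, `loc_NAN`.
#' @export
build_profiles <- function(architectures, localizations, metadata,
                           assignments = NULL) {
  arch <- architectures[architectures$has_pdz, , drop = FALSE]
  orphan <- setdiff(unique(arch$taxon_id), metadata$taxon_id)
  if (length(orphan)) {
    stop("architectures reference genomes absent from metadata: ",
         paste(orphan, collapse = ", "))
  }
  if (!is.null(assignments)) {
    bad <- setdiff(assignments$protein_id, arch$protein_id)
    if (length(bad)) {
      stop("assignments reference proteins without architectures: ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  cat_of <- function(pid) {
    k <- localizations$category[match(pid, localizations$protein_id)]
    ifelse(is.na(k), "NAN", k)
  }
  arch$loc <- cat_of(arch$protein_id)
  prof <- metadata
  prof$n_pdz_proteins <- 0L; prof$n_pdz_domains <- 0L; prof$n_multidomain <- 0L
  for (cc in LOC_CATEGORIES) prof[[paste0("loc_", cc)]] <- 0L
  if (nrow(arch)) {
    sp <- split(arch, arch$taxon_id)
    for (tid in names(sp)) {
      i <- match(tid, prof$taxon_id)
      a <- sp[[tid]]
      prof$n_pdz_proteins[i] <- nrow(a)
      prof$n_pdz_domains[i] <- sum(a$tandem_pdz_count)
      prof$n_multidomain[i] <- sum(a$n_other_domains >= 1L)
      tab <- table(factor(a$loc, levels = LOC_CATEGORIES))
      for (cc in LOC_CATEGORIES) prof[[paste0("loc_", cc)]][i] <- as.integer(tab[[cc]])
    }
  }
  prof
}

#' Exact rank-sum tail probability by enumeration
#'
#' Brute-force oracle: enumerates all `choose(n1 + n2, n1)` assignments of
#' the pooled (midranked) observations to group 1 and returns the exact tail
#' probability of the observed Mann-Whitney statistic. Ties are handled
#' naturally because the pooled midranks are permuted.
#'
#' @param x,y Numeric samples (group 1 and group 2); `n1 + n2 <= 14`.
#' @param alternative `"greater"` (x tends larger), `"less"`, or
#'   `"two.sided"`.
#' @return Exact p-value.
#' @export
exact_rank_sum_p <- function(x, y,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  if (n > 14) stop("exact enumeration limited to n1 + n2 <= 14")
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(n, n1)
  u_all <- colSums(matrix(r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  eps <- 1e-9
  switch(alternative,
         greater   = mean(u_all >= u_obs - eps),
         less      = mean(u_all <= u_obs + eps),
         two.sided = mean(abs(u_all - mu) >= abs(u_obs - mu) - eps))
}

#' Wilcoxon (Mann-Whitney) rank-sum test
#'
#' Midranks for ties. Uses exact enumeration when `n1 + n2 <= 12` with no
#' ties, otherwise the normal approximation with tie-corrected variance and a
#' 0.5 continuity correction. The survey's significance rule is p < 0.05.
#'
#' @param x,y Numeric samples; the alternative `"greater"` means x tends
#'   larger than y.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @param exact_max Largest pooled size for the exact method (default 12).
#' @return A `rank_sum_test` object: `U` (Mann-Whitney statistic of group 1),
#'   `n1`, `n2`, `z` (tie-corrected normal deviate, `NA` for exact), `p`,
#'   `alternative`, `method` (`"EXACT"` or `"NORMAL"`), `significant`.
#' @export
rank_sum_test <- function(x, y,
                          alternative = c("two.sided", "greater", "less"),
                          exact_max = 12L) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(pooled)
  has_ties <- any(ties > 1)
  if (!has_ties && n1 + n2 <= exact_max) {
    p <- exact_rank_sum_p(x, y, alternative)
    z <- NA_real_
    method <- "EXACT"
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      # all observations identical: no evidence either way
      p <- 1; z <- 0
    } else {
      sigma <- sqrt(sigma2)
      z <- switch(alternative,
                  greater = (U - mu - 0.5) / sigma,
                  less    = (U - mu + 0.5) / sigma,
                  two.sided = (U - mu - sign(U - mu) * 0.5) / sigma)
      p <- switch(alternative,
                  greater   = stats::pnorm(z, lower.tail = FALSE),
                  less      = stats::pnorm(z),
                  two.sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
      p <- min(1, max(0, p))
    }
    method <- "NORMAL"
  }
  structure(list(U = U, n1 = n1, n2 = n2, z = z, p = p,
                 alternative = alternative, method = method,
                 significant = p < 0.05),
            class = "rank_sum_test")
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon rank-sum test (%s, %s): U = %g (n1 = %d, n2 = %d), p = %.4g%s\n",
    x$method, x$alternative, x$U, x$n1, x$n2, x$p,
    if (x$significant) " *" else ""))
  invisible(x)
}

HABITAT_ORDER <- c("SPECIALIZED", "HOST_ASSOCIATED", "MULTIPLE", "AQUATIC",
                   "TERRESTRIAL")

group_plan <- function(grouping) {
  switch(grouping,
         HABITAT = {
           lapply(seq_len(length(HABITAT_ORDER) - 1), function(i) {
             list(lo = HABITAT_ORDER[i], hi = HABITAT_ORDER[i + 1])
           })
         },
         OXYGEN  = list(list(lo = "NON_AEROBIC", hi = "AEROBIC")),
         GRAM    = list(list(lo = "POSITIVE", hi = "NEGATIVE")),
         KINGDOM = list(list(lo = "ARCHAEA", hi = "EUBACTERIA"),
                        list(lo = "FUNGI", hi = "EUBACTERIA")))
}

group_values <- function(profiles, grouping, level, measure_col) {
  field <- switch(grouping, HABITAT = "habitat", OXYGEN = "oxygen",
                  GRAM = "gram", KINGDOM = "kingdom")
  g <- profiles[[field]]
  sel <- if (grouping == "OXYGEN" && level == "NON_AEROBIC") {
    !is.na(g) & g %in% c("ANAEROBIC", "FACULTATIVE")
  } else {
    !is.na(g) & g == level
  }
  profiles[[measure_col]][sel]
}

#' Compare PDZ counts between phenotype groups
#'
#' One-sided Wilcoxon rank-sum tests of per-genome PDZ counts between
#' phenotype groups, with the directional null that the right-hand (higher)
#' group exceeds the left: habitat categories are compared as adjacent
#' ordered pairs (specialized < host-associated < multiple < aquatic <
#' terrestrial), oxygen as aerobic vs non-aerobic (anaerobic + facultative
#' pooled), Gram as negative vs positive, and kingdom as eubacteria vs
#' archaea and eubacteria vs fungi. Genomes with NA in the grouping field are
#' excluded; a group with fewer than 2 genomes is skipped with a warning.
#' Raw p-values are reported by default (no multiple-testing correction);
#' `adjust = "BH"` applies Benjamini-Hochberg.
#'
#' @param profiles Genome-profile data.frame from [build_profiles()].
#' @param grouping `"HABITAT"`, `"OXYGEN"`, `"GRAM"` or `"KINGDOM"`.
#' @param measure `"proteins"` (PDZ protein count) or `"domains"` (PDZ
#'   domain count).
#' @param alternative Test direction; the default `"greater"` tests
#'   hi > lo. `"two.sided"` available by flag.
#' @param all_pairs Compare all level pairs instead of the stated plan
#'   (habitat only).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data.frame: `group_lo`, `group_hi`, `n_lo`, `n_hi`, `U`, `z`,
#'   `p`, `method`, `significant` (one row per comparison).
#' @export
compare_groups <- function(profiles,
                           grouping = c("HABITAT", "OXYGEN", "GRAM", "KINGDOM"),
                           measure = c("proteins", "domains"),
                           alternative = c("greater", "two.sided"),
                           all_pairs = FALSE, adjust = c("none", "BH")) {
  grouping <- match.arg(grouping)
  measure <- match.arg(measure)
  alternative <- match.arg(alternative)
  adjust <- match.arg(adjust)
  measure_col <- if (measure == "proteins") "n_pdz_proteins" else "n_pdz_domains"
  plan <- if (all_pairs && grouping == "HABITAT") {
    pairs <- utils::combn(HABITAT_ORDER, 2)
    lapply(seq_len(ncol(pairs)), function(j) {
      list(lo = pairs[1, j], hi = pairs[2, j])
    })
  } else {
    group_plan(grouping)
  }
  rows <- lapply(plan, function(pr) {
    x_hi <- group_values(profiles, grouping, pr$hi, measure_col)
    x_lo <- group_values(profiles, grouping, pr$lo, measure_col)
    if (length(x_hi) < 2 || length(x_lo) < 2) {
      warning("skipping ", pr$lo, " vs ", pr$hi,
              ": fewer than 2 genomes in a group", call. = FALSE)
      return(NULL)
    }
    t <- rank_sum_test(x_hi, x_lo, alternative = alternative)
    data.frame(group_lo = pr$lo, group_hi = pr$hi,
               n_lo = length(x_lo), n_hi = length(x_hi),
               U = t$U, z = t$z, p = t$p, method = t$method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(group_lo = character(), group_hi = character(),
                      n_lo = integer(), n_hi = integer(), U = numeric(),
                      z = numeric(), p = numeric(), method = character(),
                      significant = logical(), stringsAsFactors = FALSE))
  }
  if (adjust == "BH") out$p <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < 0.05
  rownames(out) <- NULL
  out
}

#' Genome-size trend of PDZ counts within a kingdom
#'
#' Spearman rank correlation between genome size (Mb) and the number of PDZ
#' proteins, with its two-sided p-value.
#'
#' @param profiles Genome-profile data.frame.
#' @param kingdom Kingdom to test (`"EUBACTERIA"`, `"ARCHAEA"`, `"FUNGI"`).
#' @param measure `"proteins"` or `"domains"`.
#' @return List: `rho`, `p`, `n`.
#' @export
size_trend <- function(profiles, kingdom, measure = c("proteins", "domains")) {
  measure <- match.arg(measure)
  col <- if (measure == "proteins") "n_pdz_proteins" else "n_pdz_domains"
  sel <- !is.na(profiles$kingdom) & profiles$kingdom == kingdom &
    !is.na(profiles$genome_size_mb)
  sz <- profiles$genome_size_mb[sel]; ct <- profiles[[col]][sel]
  if (length(sz) < 4) stop("need at least 4 genomes in kingdom ", kingdom)
  if (length(unique(sz)) < 2 || length(unique(ct)) < 2) {
    stop("constant input: size trend undefined for kingdom ", kingdom)
  }
  ct_res <- suppressWarnings(
    stats::cor.test(sz, ct, method = "spearman", exact = FALSE))
  list(rho = unname(ct_res$estimate), p = ct_res$p.value, n = length(sz))
}

#' Localization fractions of PDZ proteins
#'
#' Fractions of TM, SP, TMSP and CYT over proteins with a known localization
#' (NAN excluded), overall or partitioned by kingdom or Gram stain.
#'
#' @param profiles Genome-profile data.frame.
#' @param partition `"ALL"`, `"KINGDOM"` or `"GRAM"`.
#' @return Data.frame: `group`, `n_known`, `frac_TM`, `frac_SP`,
#'   `frac_TMSP`, `frac_CYT` (fractions sum to 1 per row).
#' @export
localization_fractions <- function(profiles,
                                   partition = c("ALL", "KINGDOM", "GRAM")) {
  partition <- match.arg(partition)
  grp <- switch(partition,
                ALL = rep("ALL", nrow(profiles)),
                KINGDOM = profiles$kingdom,
                GRAM = profiles$gram)
  keep <- !is.na(grp)
  rows <- lapply(unique(grp[keep]), function(gv) {
    p <- profiles[keep & grp == gv, , drop = FALSE]
    counts <- c(TM = sum(p$loc_TM), SP = sum(p$loc_SP),
                TMSP = sum(p$loc_TMSP), CYT = sum(p$loc_CYT))
    n_known <- sum(counts)
    if (n_known == 0) stop("no proteins with known localization in group ", gv)
    fr <- counts / n_known
    data.frame(group = gv, n_known = n_known, frac_TM = fr[["TM"]],
               frac_SP = fr[["SP"]], frac_TMSP = fr[["TMSP"]],
               frac_CYT = fr[["CYT"]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
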