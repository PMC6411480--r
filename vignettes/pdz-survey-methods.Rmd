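---
title: "Methods: surveying PDZ domain-containing proteins across microbial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surveying PDZ domain-containing proteins across microbial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdzsurvey)
```

## The problem

PDZ domains are short (~80–100 residue) peptide-binding modules. In
metazoa they scaffold signaling complexes; in bacteria, archaea and fungi
they appear mainly in protein quality-control proteins, where the PDZ
recognizes exposed C-termini of unfolded substrates and hands them to an
attached protease domain (HtrA-, Ctp- and RseP-type proteases). A
comparative survey of these proteins across many genomes rests on a chain
of unglamorous steps — parsing HMM hit tables, deciding which hits to
believe, collapsing overlapping hits into one architecture per protein,
applying family rules, walking gene neighborhoods, and comparing counts
between phenotype groups. Each step has conventions that silently change
results if got wrong. `pdzsurvey` makes each step an explicit, tested
operation, and ships a synthetic-cohort generator so the whole chain can be
checked against planted ground truth.

## Hit ingestion and thresholds

All coordinates are 1-based inclusive residue positions, the convention
shared by HMMER and NCBI PTT tables. Domain extent is taken from the
**envelope** coordinates of the domtblout record — HMMER's own statement of
where the domain lies — rather than the narrower alignment coordinates;
which of the two a survey uses is rarely stated, so the choice is made
explicit here and applied uniformly.

Two E-value thresholds gate every hit, both inclusive:

| mode | full-sequence E ≤ | per-domain E ≤ | used for |
|------|------------------|----------------|----------|
| SEARCH | 0.01 | 0.03 | PDZ-model searches against whole proteomes |
| SCAN   | 0.01 | 0.01 | scans of candidate proteins against the full Pfam/Superfamily libraries |

Filtering is idempotent and monotone: loosening a threshold never removes a
previously kept hit. The Superfamily assignment format carries a single
E-value per hit; it is stored as both the sequence and domain E-value so
one policy applies across sources. Superfamily hits also carry no bit
score; they are given `NA` and rank last during overlap resolution, with
deterministic start/identifier tie-breaks.

## Cross-database merging and overlap resolution

Pfam is the reference classification and Superfamily the consistency
check. A Superfamily hit overlapping a Pfam hit by at least 50% of either
extent is absorbed as corroboration (the Pfam record is kept and flagged);
this stops a Superfamily PDZ nested in a Pfam PDZ from double-counting a
tandem repeat. Superfamily hits without such a partner are appended as
independent domains, which is how PDZ domains found only by the
Superfamily model survive into the analysis.

Overlap resolution selects, among all subsets of a protein's hits in which
every pair overlaps by at most 20% of the shorter hit's length, the subset
with the maximum total bit score (exact branch-and-bound; greedy fallback
above 30 hits, a size real proteins do not reach). The 20% tolerance is a
design choice: small enough to kill duplicate calls on the same region,
large enough to keep genuinely adjacent tandem PDZ repeats. An earlier
greedy-by-score design was considered and rejected: a single high-scoring
long hit can block two shorter disjoint hits whose combined score is
higher, so plain greedy does not reproduce the exhaustive-search optimum it
is tested against; the exact search does, at no practical cost at these
instance sizes. Ties between equal-score optima are broken
deterministically (higher score first, then smaller start, then
lexicographic identifier), so resolution is invariant under input
permutation.

Split domains — e.g. a trypsin protease domain interrupted by a Q-linker
stretch — are left as two segments by the resolver; the classifier treats
consecutive same-identifier segments separated by fewer than 60 residues as
one logical domain.

## Tandem counting and flavors

The tandem PDZ count of a protein is the number of kept hits whose
identifier is a PDZ identifier (Pfam PDZ/PF00595, PDZ_1/PF12812,
PDZ_2/PF13180, Superfamily 50156); two or more such hits are tandem
repeats. Summed over a proteome this equals the total number of kept PDZ
hits — a conservation law the tests enforce, mirroring the relationship
between hit totals and protein totals in any survey of this kind. The
flavor of a protein is CANONICAL if every PDZ hit is the canonical Pfam
family (the metazoan form), NONCANONICAL if none is (e.g. the circularly
permuted PDZ_2 form common in eubacteria), MIXED otherwise.

## The twelve family signatures

Classification is architecture-first: a protein is assigned to the first
signature (fixed precedence order) whose required partner domains all
appear among its logical domains. The precedence order is the order in
which the families are conventionally listed — HtrA, Ctp, RseP, APN, Lon,
SpoIVB, AP, ZEP, GspC, Fe–S oxidoreductase, Haem-binding uptake, ComP —
protease families first; nothing in the underlying biology defines a
tie-break for a protein genuinely carrying two signatures' domains, so the
order is simply fixed and tested (a pairwise enumeration test asserts that
every co-occurring pair resolves to the earlier family). Signature
vocabulary is configurable through a synonyms table because Pfam family
names and clan memberships drift across releases.

Motifs corroborate two families: RseP (HExGH in the N-terminal half,
NxxPxxxLDG in the C-terminal half — the zinc-binding and S2P-like motifs
of intramembrane metalloproteases) and the Fe–S oxidoreductase (CxxxCxxC,
the iron–sulfur cluster motif of radical SAM enzymes, with the PDZ
N-terminal to the radical SAM domain). When a protein sequence is
available these checks are mandatory; without sequences, domain evidence
alone suffices and the assignment is annotated "motif unchecked". This
mirrors the practice of classifying from architectures first and using
motifs as a secondary check. Manual curation steps that a semiautomatic
survey would apply (alignment-based pruning of highly divergent members)
are deliberately not reproduced; such proteins simply remain UNCLASSIFIED
with a note.

Summaries follow the members/organisms convention: a family×group cell
holds the number of member proteins and the number of genomes with at
least one member. Grouping of rare phyla into "Other" buckets is accepted
as an explicit mapping rather than guessed.

## Gene neighborhoods

A gene neighbors a PDZ-coding anchor gene if it is codirectional (same
strand, same replicon) and within 50 nucleotides. Intergenic distance is
d = start(next) − end(prev) − 1 with 1-based inclusive coordinates;
overlapping and abutting genes — common in prokaryotic operons — get d = 0
and therefore count as neighbors. Extension is transitive by default
(operon-style chains, which is what multi-gene conserved clusters look
like); a pairwise-to-anchor mode is available by flag since the
within-50-nt rule could also be read that way. The cutoff is a parameter
(`max_gap`), with 300 reproducing the documented E. coli exception.
Replicons are treated as linear: a cluster spanning the origin of a
circular chromosome would be split, a documented limitation. Cross-genome
conservation is keyed on gene name with locus-tag fallback, and unnamed
genes aggregate under "unnamed".

## Statistics

Group comparisons use the Wilcoxon (Mann–Whitney) rank-sum test,
one-sided by default with the directional hypothesis that the
conventionally higher group (aerobic, Gram-negative, eubacteria, and the
habitat order specialized < host-associated < multiple < aquatic <
terrestrial) exceeds the lower, significant at p < 0.05. Habitat panels
compare adjacent ordered categories; all-pairs mode is available by flag.
Raw p-values are reported (no multiple-testing correction), matching how
such surveys report Wilcoxon results; a Benjamini–Hochberg option exists
but is off by default. Genomes with missing phenotype are excluded per
comparison, never imputed.

The test computes midranks for ties, uses exact enumeration when
n1 + n2 ≤ 12 with no ties, and otherwise a normal approximation with
tie-corrected variance and 0.5 continuity correction (numerically
identical to `stats::wilcox.test(exact = FALSE, correct = TRUE)`, which the
tests use as an independent cross-check). A brute-force enumeration oracle
(`exact_rank_sum_p`, all `choose(n1+n2, n1)` labelings) is exposed for
validation up to n1 + n2 = 14. Two calibration facts the test suite
measures: the type-I rate of the one-sided comparison under a planted null
sits near the nominal 0.05, and the normal approximation deviates from the
exact tail by up to ~0.04 in the n1 + n2 = 8–14 range (worst at two-sided
mid-range p). The deviation is a property of the continuity-corrected
normal approximation itself, not of this implementation.

The genome-size trend is Spearman rank correlation (two-sided p) between
genome size in Mb and PDZ protein count within a kingdom; Spearman is
chosen because the relationship is monotone but not plausibly linear in
counts. Localization fractions (TM, SP, TMSP, CYT) are computed over
proteins with a known category; proteins without a prediction (NaN) are
excluded from fractions but kept in tallies.

## The synthetic cohort generator

The generator emulates the statistical structure the survey assumes, not
real sequence evolution. Per-genome PDZ gene counts are negative binomial
(dispersion 5 by default — counts of this kind are overdispersed with a
heavy right tail; Poisson is the infinite-dispersion special case) with
mean = oxygen level × habitat multiplier × kingdom multiplier, scaled by
genome size in eubacteria only. Defaults: oxygen means 8 (aerobic), 3
(anaerobic), 5 (facultative) at the 5-Mb reference; habitat multipliers
1.5/1.3/1.0/0.7/0.5 for terrestrial/aquatic/multiple/host-associated/
specialized; archaea and fungi reduced to 0.4× with no size dependence.
These plant exactly the group effects and the eubacteria-only size trend
the statistics stage is supposed to detect. A 60-genome cohort at the
default 75/15/10 kingdom mix yields on the order of 300–400 PDZ proteins.

Family labels are drawn so that 93% of proteins are classifiable, with 88%
of the classified in the eight protease families, and relative abundances
highest for HtrA, Ctp and RseP. Each protein's hits instantiate its
family's signature with sub-threshold E-values and non-overlapping
coordinates (PDZ placed N-terminal, which the Fe–S oxidoreductase rule
requires); sequences are random residues with motif instances spliced at
controlled positions (re-spliced when tail extensions move the C-terminal
half). Tandem repeats continue geometrically with probability 0.25 per
additional PDZ hit (mean ≈ 1.33 hits per protein, close to the ~1.27
hits-per-protein ratio such surveys observe). Decoy hits exercise the
filter from both sides: above-threshold decoys (per-domain E > 0.03, or
in (0.01, 0.03], or sequence E > 0.01) must vanish from architectures,
below-threshold decoys from a fixed non-signature vocabulary must survive —
the vocabulary is disjoint from every signature so a decoy can never
complete a family. Localization categories are drawn at TM 0.32, SP 0.40,
TMSP 0.17, CYT 0.11 (11% cytoplasmic among known calls), with 5% NaN.

Planted neighborhoods lay the RseP cluster (cdsA, uppS, dxr, frr, rpsB,
bamA, all gaps ≤ 50 nt) and the lon cluster (coaD, rsmD) codirectionally
next to their anchor genes, plus one deliberate break gene at a 60-nt gap
that the 50-nt rule must exclude. Filler genes are separated by gaps > 50
nt so no accidental chains form. All randomness derives from the config
seed; a fixed seed reproduces every emitted file byte for byte.

What passing tests on such cohorts do **not** show: robustness to HMM
scoring noise (bit scores and E-values are drawn, not computed from
alignments), to annotation errors in real PTT files, to circular-replicon
effects, or to the manual-curation judgment calls of a real survey.
Recovery rates on synthetic data are upper bounds, not estimates, of
real-data performance.

## Problem sizes and numerical choices

The test suite validates the overlap resolver against exhaustive subset
search on 500 random instances of up to 8 hits, the neighborhood extractor
against a brute-force chain oracle on 200 random layouts of up to 50 genes
(gap mixtures straddling 50/51 nt and strand breaks included), rank-sum
calibration on 200 replicates each, planted-effect power and trend
detection on 100 replicates each, and end-to-end recovery on a 60-genome
cohort — sizes at which every oracle is exact and the whole suite runs in
well under a minute. The size-trend replicates hold oxygen and habitat at
one level so the Spearman test measures the planted size factor in
isolation; the oxygen effect has its own planted-effect experiment.
Degenerate inputs are defined, not left to chance: empty groups error,
all-identical samples give p = 1, constant sizes make the trend an error
rather than NA, zero-count genomes appear in profiles with zero tallies.
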