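# pdzsurvey

Comparative-genomics survey machinery for PDZ domain-containing proteins in
microbial (prokaryotic and fungal) genomes.

PDZ domains are ~80–100-residue protein–protein interaction modules that
bind C-terminal peptides. In bacteria they are best known from protein
quality-control proteases (HtrA, tail-specific protease, RseP), where the
PDZ domain recognizes unfolded substrates for the accompanying protease
domain. Surveying them across hundreds of genomes requires a pipeline that
is mostly plumbing — threshold-filtered HMM hit ingestion, overlap
resolution, architecture-based family rules, gene-neighborhood extraction,
nonparametric group comparisons — and that plumbing is exactly where silent
errors live. `pdzsurvey` implements that pipeline as tested, reusable R
code, together with a seeded synthetic-cohort generator that plants known
family architectures, gene clusters and phenotype effects so every stage can
be validated against ground truth.

## What the pipeline computes

* **Ingestion** (`read_domtblout`, `read_superfamily_table`, `filter_hits`):
  HMMER3 per-domain hit tables and Superfamily-style assignment tables are
  filtered by dual E-value inclusion thresholds — full-sequence E ≤ 0.01
  with per-domain E ≤ 0.03 for proteome searches with the PDZ models
  (SEARCH mode), and 0.01/0.01 for scans of candidate proteins against the
  full domain libraries (SCAN mode).
* **Architectures** (`merge_cross_db`, `resolve_overlaps`,
  `build_architecture`): Pfam is the reference annotation and Superfamily
  the cross-check; a Superfamily hit nested in a Pfam hit corroborates it,
  a Superfamily-only PDZ survives as its own domain. Overlapping hits are
  resolved to the maximum-total-bit-score subset in which every pair
  overlaps by at most 20% of the shorter hit. Two or more PDZ hits on one
  protein count as tandem repeats.
* **Families** (`default_signatures`, `classify_protein`): twelve
  architecture-defined families in fixed precedence — the protease
  families HtrA, Ctp, RseP, APN, Lon, SpoIVB, AP, ZEP and the non-protease
  families GspC, Fe–S oxidoreductase, Haem-binding uptake, ComP. RseP is
  corroborated by the HExGH and NxxPxxxLDG motifs (N- and C-terminal
  halves), the Fe–S oxidoreductase by the CxxxCxxC iron–sulfur motif with
  the PDZ N-terminal to the radical SAM domain. Architectures matching no
  signature are UNCLASSIFIED.
* **Genomic context** (`find_neighborhood`, `conserved_neighbors`): a gene
  neighbors a PDZ-coding gene if it is codirectional and within 50
  nucleotides (intergenic distance d = start(next) − end(prev) − 1, chained
  operon-style; `max_gap = 300` reproduces the E. coli exception).
* **Statistics** (`rank_sum_test`, `compare_groups`, `size_trend`):
  one-sided Wilcoxon (Mann–Whitney) rank-sum tests of per-genome PDZ counts
  between habitat, oxygen, Gram and kingdom groups, significant at
  p < 0.05; exact enumeration for small tie-free samples, otherwise the
  normal approximation with tie-corrected variance and continuity
  correction; Spearman correlation for the genome-size trend.

## Worked example

Simulate a 20-genome cohort with planted ground truth, run every stage, and
inspect the report:

```r
library(pdzsurvey)
cohort <- tempfile("cohort"); work <- tempfile("work")
truth <- generate_cohort(cohort_config(n_genomes = 20, seed = 7), cohort)
for (s in c("ingest", "classify", "context", "stats", "report"))
  run_pipeline(s, list(cohort_dir = cohort, work_dir = work))
cat(readLines(file.path(work, "summary.txt")), sep = "\n")
```

```
genomes: 20
PDZ proteins: 100
PDZ domains (tandem-aware): 126
classified: 95 (95.0%)
protease-family fraction of classified: 86.3%
membrane-targeted (TM/SP/TMSP) fraction: 86.60%
cytoplasmic fraction: 13.40%
```

100 PDZ proteins were found and 126 PDZ domains — the excess over the
protein count is tandem repeats. 95% of proteins matched one of the twelve
family signatures (the generator plants 93% classifiable on average), 86%
of the classified ones pair the PDZ with a protease domain, and 87% carry a
transmembrane helix and/or signal peptide. The planted RseP gene cluster is
recovered across genomes:

```r
head(read.delim(file.path(work, "conservation.tsv")), 7)
```

```
  neighbor genomes
1     bamA       8
2     cdsA       8
3      dxr       8
4      frr       8
5     rpsB       8
6     uppS       8
7     coaD       4
```

The six RseP neighbors (cdsA, uppS, dxr, frr, rpsB, bamA) appear in all 8
genomes that carry an RseP protein; the planted break gene beyond the 50-nt
rule does not. A direct group comparison:

```r
rank_sum_test(c(9, 12, 7, 14), c(3, 2, 5, 4), alternative = "greater")
```

```
Wilcoxon rank-sum test (EXACT, greater): U = 16 (n1 = 4, n2 = 4), p = 0.01429 *
```

The first group's counts exceed the second's in all 16 pairings
(U = n1·n2 = 16); exact enumeration gives p = 1/70 ≈ 0.014, significant at
the survey's p < 0.05 rule.

A shell front end with the same stages is installed at
`inst/scripts/domarch.R`
(`Rscript domarch.R simulate --cohort-dir DIR --seed 1`, then `ingest`,
`classify`, `context`, `stats`, `report`).

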