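---
title: "Methods: strand-aware identification of natural antisense transcripts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strand-aware identification of natural antisense transcripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(natscan)
```

## The problem

Natural antisense transcripts (NATs) are RNAs transcribed from the strand
opposite a gene, frequently regulating their sense partner. Calling them
from stranded RNA-seq is confounded by two artifacts that mimic antisense
signal:

1. **Genuinely overlapping opposite-strand genes.** A read that is
   antisense to gene X may simply be a sense read of an annotated gene on
   the other strand.
2. **Strand misassignment.** dUTP-based stranded libraries assign the
   wrong strand to up to ~3% of fragments, so every highly expressed gene
   casts a faint antisense "shadow" of itself.

`natscan` implements the countermeasures as a pipeline: artifact (1) is
removed geometrically, artifact (2) statistically.

## Model and procedure

### Overlap-free zones

For gene $g$ with UTR-inclusive span $S_g$ (the union extent of all its
annotated features), the overlap-free zone is

$$Z_g = S_g \setminus \bigcup_{h \ne g,\; \text{strand}(h) \ne \text{strand}(g)} S_h .$$

Only antisense fragments intersecting $Z_g$ are attributed to antisense
transcription of $g$. Whole opposite-strand gene bodies are subtracted
(not just exons): intronic opposite-strand transcription is real strand
occupancy during transcription, and the annotation does not tell us where
pre-mRNA ends. Same-strand overlaps do **not** shrink the zone — ambiguity
between same-strand genes is resolved at the read level by unique mapping.
By default every annotated biotype blocks; `blocker_biotypes` restricts
this (e.g. to `protein_coding`) for sensitivity analyses.

Two independent implementations exist: a per-gene
`GenomicRanges::setdiff` reference (`compute_overlap_free_zone`) and a
vectorized integer sweep (`zone_core`, behind `overlap_free_zones` and
`overlap_free_zone_table`). The test suite checks both against a per-base
brute-force mask oracle.

### Fragment strand and classification

Under the dUTP ("RF") protocol read 1 aligns antisense to its source
transcript, so the fragment strand is the flip of read 1's alignment
strand and equals read 2's. A fragment is *sense* for $g$ if its strand
matches and it intersects $S_g$; *antisense* if its strand is opposite
and it intersects $Z_g$; *outside_zone* if opposite-strand inside the
span but off the zone; *ambiguous* otherwise. Mates are aggregated by
`qname` (sense/antisense from either mate wins over outside_zone) and a
fragment counts once per feature. Only uniquely mapped fragments are
counted; `NH == 1` is authoritative, with a MAPQ ≥ 30 fallback when the
tag is absent. Fragments are counted, not reads — mates never count
twice.

### Contig QC

De novo antisense contigs pass three gates, in order:

| Gate | Rule | Boundary |
|---|---|---|
| genome self-validation | weighted identity ≥ 99% **and** union query coverage ≥ 95% | inclusive |
| known-lncRNA mapping (annotation only) | coverage > 95% and identity ≥ 99%, per lncRNA subject | coverage strict |
| spurious low-pass | $a/(s+a) > 0.03$, summed unique reads over all samples | strict |

Multi-HSP query coverage is the interval **union** on the query (nested
or overlapping HSPs are not double-counted); identity is the
alignment-length-weighted mean. The two BLAST filters deliberately differ
at the boundary because their published definitions do ("≥95%" vs
">95%"); they are honored literally. The 3% low-pass denominator is the
locus total (cognate-gene sense plus contig antisense), using raw unique
counts summed across samples — a per-sample mode would make a contig's
existence depend on its worst sample.

### Expression summaries

Counts are normalized to counts-per-million with the library size taken
over **both** strata (gene sense + contig antisense counts), keeping the
two on one scale. The detection filter keeps features with ≥ 10 unique
reads in ≥ 3 samples (inclusive). Per gene, the antisense:total ratio is
$a/(s+a)$ over summed normalized counts, and the tissue specificity
score contrasts the two brain regions:

$$\mathrm{TSS} = 100 \times
\frac{\dfrac{Opp_{mPFC}}{Total_{mPFC}} - \dfrac{Opp_{Str}}{Total_{Str}}}
     {\dfrac{Opp_{mPFC}+Opp_{Str}}{Total_{mPFC}+Total_{Str}}}$$

positive for mPFC enrichment, negative for striatum. The published
rendering of this formula is typographically garbled; the form above is
the only reading consistent with the surrounding prose (a difference of
antisense proportions normalized by the pooled antisense proportion) and
with dimensional sanity. It is antisymmetric under tissue exchange and
invariant to common rescaling — both tested. Inputs are normalized counts
summed per tissue; the score is undefined (and flagged) when a tissue
total or the pooled antisense count is zero.

### Developmental slope classification

Per feature and per tissue, normalized counts are regressed on age in
days (7, 14, 56 — numeric coding; the slope sign of a monotone trend is
insensitive to monotone recodings in the two-age case, and the three-age
case is exercised in tests). Significance is the model F-test at
$\alpha = 0.05$ (equal to the slope t-test in simple regression). If the
three-age fit fails, the model is refit on P14+P56 only (`used_fallback`)
— early postnatal samples often break an otherwise clean later trend. The
fallback is applied independently to gene and contig. A pair is
*positive* when both final slopes share a sign, *negative* when they
differ, *flat* at an exactly zero slope (an explicit tie class), *unfit*
when either F-test fails.

**Calibration caveat:** the fallback is a second chance at the same
$\alpha$, so under a true null the fraction of `fit_ok` features is
inflated to ≈ 0.077 rather than 0.05 (measured over 1,000 null
simulations). This is a property of the published procedure, not a bug;
calibration statements and the corresponding acceptance test therefore
apply to the primary three-age F-test (`fallback_ages = NULL`). Values
are not log-transformed, matching the procedure's use of abundance
estimates.

### Conservation

A contig is conserved in the second genome when union coverage **and**
weighted identity both strictly exceed 90%, reusing the QC operators for
consistency. Hits anywhere in the subject genome qualify (the orthologous
locus is not enforced); the gene list of interest enters as plain text,
one symbol per line, already in source-species naming — no orthology
inference is performed.

## The synthetic world

The generator (`sim_config()` defaults) states one world and the tests
live in it:

| Parameter | Default | Why |
|---|---|---|
| genes / overlap fraction | 50 / 0.3 | small genome with a realistic share of opposite-strand overlap |
| design | 2 tissues × ages P7/P14/P56 × 2/5/5 replicates | the profiled study design |
| baseline mean | 100 fragments/gene/sample | desk-scale stand-in for ~162 M reads/sample |
| NB dispersion | 0.1 | typical bulk RNA-seq biological dispersion |
| antisense fraction / ratio | 0.7 of genes; ratios U(0.05, 0.45) | ~70% of examined genes had antisense expression |
| misassignment rate | 0.03 | literature upper bound for dUTP chemistry |
| artifact contigs | 15% of genes at 0.5–1.5% antisense | spurious contigs the low-pass filter must remove |
| negative-pair fraction | 1/6 | antisense mostly positively correlated with sense |
| fold change P7→P56 | 4 | strong but realistic developmental regulation |

Ages act on means log-linearly, so designed slope *signs* are
unambiguous; cognate contig means are $r/(1-r)$ times the gene mean so
the expected antisense:total ratio equals the designed $r$; misassignment
is modeled as a mate-orientation flip (the mechanism dUTP chemistry
confuses), not position shuffling; multi-mappers carry `NH:i:2`.

**What a green test does not establish.** No nucleotides are simulated:
alignment, assembly and BLAST themselves are out of scope (contigs and
hit tables enter as inputs), so the tests validate the decision logic
downstream of those tools, not the tools. Fragments are placed uniformly
within features — no coverage bias, splicing or quality scores. At
desk-scale depth the 3% filter boundary is only a few reads wide, so an
artifact designed near 1.5% can legitimately jitter past it in a tiny
cohort; the wide-margin statement is tested on the default cohort.

## Numerical and engineering choices

- Intervals are 1-based closed `IRanges`/`GRanges` internally (the R
  field convention), making GTF I/O an identity mapping; `pos` on
  alignment records stays 0-based per SAM convention minus one.
- Threshold boundaries follow the published wording exactly: inclusive
  for self-validation and detection, strict for lncRNA coverage, the 3%
  filter and conservation. Boundary cases are pinned in tests
  (30/970 removed, 31/969 kept; 90.0 never conserved; 10-in-3 kept).
- Reports are written with fixed 15-significant-digit formatting and
  sorted keys, so identical seed + config ⇒ byte-identical TSV/JSON
  (tested via md5).
- Degenerate fits (constant values, <2 distinct ages, <3 points) are
  `unfit` with an undefined p-value rather than an error.
- Zero library sizes, negative counts, unknown strands and malformed
  GTF/BLAST rows fail fast with the offending sample/gene/line named.

## Limitations

Splice-aware geometry, isoform quantification, differential-expression
testing (an external table can be ingested for reporting), PCA/clustering
and enrichment analysis are out of scope. The pipeline classifies slope
signs, not nonlinear temporal shapes. Double-counting across alternative
contigs of one gene is possible by design (contigs are alternative
assemblies, not a partition) and never crosses genes.
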