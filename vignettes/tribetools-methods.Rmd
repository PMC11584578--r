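---
title: "Models and methods behind tribetools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tribetools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement

TRIBE (Targets of RBPs Identified By Editing) fuses an RNA-binding protein
to the catalytic domain of ADAR2 (the hyperactive E488Q variant, "ADARcd").
Wherever the RBP binds an mRNA, the tethered deaminase converts nearby
adenosines to inosines, which sequencers read as guanosine. Bound
transcripts therefore acquire A-to-G mismatches against the reference, and
an ADARcd-only construct — the deaminase without the targeting RBP —
provides the background editing level. Read out through droplet single-cell
RNA-seq with cell barcodes and UMIs, the same chemistry yields a per-cell
map of RBP-mRNA binding: the *editome*.

`tribetools` implements the complete computational path from tagged
alignments to cell-state-resolved binding analysis, together with a
ground-truthed synthetic-data generator so that every stage is testable
without any sequencing download.

# Edit-site calling

## UMI-aware pileup

`pileupCounts()` enumerates every genomic position where at least one read
carries a non-reference base. In bulk mode units are reads per sample; in
single-cell mode, reads sharing (cell barcode, gene, UMI) are collapsed to
one molecule whose base at a site is the **majority base** among its PCR
duplicates. A tied vote (e.g. one duplicate G, one A) discards the molecule
at that site rather than guessing — a deliberate conservative tie-break.
Reads below mapping quality 10 (configurable) are excluded, mirroring the
standard alignment-cleanup convention for editing analysis.

Counting molecules instead of reads matters because PCR amplification is
uneven across cells: the per-cell duplication rate acts as a multiplicative
noise term on read counts that UMI collapsing removes. `cvComparison()`
quantifies this as the per-transcript coefficient of variation across
cells, computed on both count types and contrasted with a paired Wilcoxon
test within abundance tiers (quartiles of mean edited-UMI count).

## Strand calibration and masking

Editing happens on the transcript, so only genomic A-to-G on plus-strand
genes and T-to-C on minus-strand genes are candidate edits; every other
substitution class is sequencing error, misalignment, or genetic variation
and is dropped (`calibrateStrand()`). Retained sites are reported uniformly
as A-to-G in transcript space. A site inside annotated genes on *both*
strands cannot be assigned a substitution class and is dropped — the most
conservative resolution of an ambiguity the calling convention leaves open.
Known germline variants (a dbSNP-style VCF) are masked before testing.

## Beta-binomial background and the four-part filter

Editing frequencies in the ADARcd-only control are overdispersed relative
to a binomial: the per-site editing propensity itself varies. The
background model is therefore a beta-binomial,
$k \sim \mathrm{BetaBin}(n, \alpha, \beta)$, parameterized by its mean
$\mu = \alpha/(\alpha+\beta)$ and overdispersion
$\rho = 1/(\alpha+\beta+1)$. `fitBackground()` estimates $\mu$ by pooled
weighted moments and refines $(\mu, \rho)$ by maximum likelihood from a
moment start. Two safeguards:

* when the pooled chi-square dispersion statistic does not exceed its 95%
  null quantile, the control is treated as binomial ($\rho = 0$) — fitting
  an overdispersion the data do not support would only cost power;
* a rate floor (default $10^{-4}$) prevents an all-zero control from
  producing a degenerate zero-rate model.

`testSites()` computes, per site, the one-sided tail probability that the
experimental edited count is at least as large as observed under the
background — one-sided because the fusion adds edits and never removes
them — followed by Benjamini-Hochberg correction. The summation uses the
shorter tail of the distribution for numerical accuracy. With
`pooling = "per_site"`, sites the control covers at more than 10 units use
their own control mean (sharing the global $\rho$); sparsely covered sites
fall back to the pooled model, which is also the default, because most
sites are control-sparse at single-cell depth.

Significant sites must then pass all four gates of `applySiteFilters()`:
FDR < 0.01; editing frequency within 0.05–0.95 (implemented as inclusive
bounds — the convention's wording does not fix the boundary, and no tested
property depends on it); edited units strictly greater than 2; coverage
strictly greater than 10. In bulk mode the last three gates apply per
replicate; in single-cell mode they apply to pseudobulk counts pooled over
cells.

# The editome and its populations

`buildEditome()` aggregates edited UMIs over each gene's significant
*exonic* sites (intronic signal is excluded) into a genes-by-cells matrix,
carried as a `SingleCellExperiment` subclass. Cell QC (`filterCells()`)
keeps cells with ≥ 2 edited transcripts, ≥ 20 edited UMIs, 2,000–100,000
total transcriptome UMIs, and ≤ 10% mitochondrial reads (gene-name prefix
`mt-`, configurable). "Edited transcripts" counts distinct genes with at
least one edited UMI, since matrix rows are genes.

Binding intensity normalizes editing for cell depth:
$b_{gc} = \log(1 + 10^4\, k_{gc} / T_c)$ with $T_c$ the cell's total UMIs —
natural log, the convention of the single-cell toolkits this pipeline's
thresholds come from.

`clusterEditome()` runs the standard community-detection cascade on
binding intensities — top 600 highly variable genes (ranked by variance of
binding intensity), z-scaling capped at ±10, PCA to 8 components, a
shared-nearest-neighbor graph with Jaccard weights over 20 Euclidean
neighbors, Louvain at resolution 0.1 — all defaults configurable and all
seeds fixed and logged. Fusion-negative cells (insufficient ADARcd-fusion
expression) form a low-editing cluster; `selectPositiveCells()` flags as
negative every cluster whose median edited-UMI total falls below a quarter
of the largest cluster median. The source convention says only that the
negative population "does not contain substantial editing" without
quantifying it; the median-ratio rule with fraction 0.25 is this package's
concrete choice, configurable, and sits well clear of both sides in the
intended regime (a roughly 100-fold editing gap).

# Differential binding

`findDbts()` is a one-vs-rest marker analysis on binding intensity: a
two-sided Wilcoxon rank-sum test per gene and group (exact for small
tie-free groups, normal approximation with tie correction otherwise) gated
at raw p < 0.01, and a fold-change gate of 1.2 (log2 threshold 0.263)
computed as
$\mathrm{FC} = (\overline{\mathrm{expm1}(b)}_{\text{in}} + 1) /
(\overline{\mathrm{expm1}(b)}_{\text{out}} + 1)$.
The pseudocount of 1 is the fold-change convention of the marker-analysis
function whose gates are mirrored here; it shrinks fold changes of weakly
edited genes toward 1, which is what makes the 1.2 gate meaningful at
editome depth. No multiple-testing correction is applied to DBT p-values —
a deliberate mirror of the marker-analysis convention, which gates on raw
p. Pairwise group contrasts are available via `comparison = "pairwise"`;
one-vs-rest is the default. A DBT is attributed to the group where binding
is high (the up direction); down-direction records are reported but are
mirrors, not targets.

`classifyDependence()` separates binding changes from abundance changes: a
significant DBT whose gene also shows *higher expression* in the same group
(same test, same gates, on normalized expression) is expression-dependent;
otherwise expression-independent. `relativeBindingIntensity()` expresses
the same contrast as a ratio: each group's editing level relative to the
across-group mean, divided by the relative expression level (plus
$\epsilon = 10^{-9}$ against zero expression).

# Binding dynamics along pseudotime

Pseudotime is consumed, not computed — trajectory inference belongs to
dedicated tools, and the bespoke statistic here is the editome test along
it. `dynamicDbtTest()` fits, per gene, two negative-binomial regressions of
edited counts with a log total-UMI offset (so the modeled quantity is
binding intensity, not depth): a full model with a natural cubic spline of
pseudotime (3 df by default) and an intercept-only null. The
likelihood-ratio statistic is referred to $\chi^2_3$; q-values are BH
across converged genes. Numerical details that matter:

* gene-wise dispersion is ML-estimated with the *dispersion floored at
  $10^{-6}$* (theta capped at $10^6$). Equidispersed genes push theta to
  infinity, where the NB likelihood evaluation loses precision; such fits
  are redone at the cap with a fixed-theta NB family, for both members of
  the pair, so the models stay nested and the LRT stays non-negative
  (it is additionally clamped at 0 against rounding);
* genes with fewer than 5 nonzero cells are skipped; fits that still fail
  are reported `NA` and excluded from the BH correction;
* branch comparisons are realized by subsetting cells to the union of the
  two branch paths before testing.

`smoothProfiles()` evaluates the fitted spline mean on a 100-point grid
spanning the observed pseudotime range at the median cell depth, then
row-standardizes. `groupPatterns()` cuts a hierarchical clustering
(correlation distance, complete linkage) at k groups and orders genes by
group and profile peak; the number of pattern groups is a user choice, as
the grouping of dynamic targets is descriptive, not inferential.

# Motif and peak context

`extractFlanks()` takes ±50 bp windows around edited sites,
reverse-complementing windows on minus-strand genes so all scanning happens
in transcript orientation — consequently motifs are matched in a single
orientation, never against the reverse complement. `motifEnrichment()`
scores a window as a hit if the motif matches anywhere (IUPAC consensus
with configurable mismatches, or a position-weight matrix at a score
threshold) and compares the foreground hit count against the background hit
fraction with a one-sided binomial test, BH-corrected across motifs. The
canonical RBP motifs are shipped as consensus patterns (`GGAGA`; `UGAU`,
i.e. `TGAT` in DNA space) because the discovered weight matrices behind
them are not machine-readably published; users can supply their own
matrices. When no background set is given, a dinucleotide-preserving
shuffle of the foreground (random Eulerian path through the dinucleotide
transition graph, seed logged) serves as the null — the standard choice,
since dinucleotide content dominates spurious motif hits.

`peakFlankProfile()` profiles editing around orthogonal CLIP peaks: each
site gets a signed distance to the nearest peak center (interval midpoint,
or the summit when a seventh BED column provides one), sites beyond ±500 bp
are excluded, and both per-bin and cumulative frequency forms are returned.
`overlapDecomposition()` reports the set algebra between two target lists
(e.g. editing-derived vs CLIP-derived) and the fraction of motif-positive
genes within each partition.

# The synthetic generator

`simulateTruth()` draws a toy genome with non-overlapping two-exon genes,
plants edit sites inside exons (forcing the editable reference base), and
assigns cells to states. Its defaults encode the study conditions the
analysis is designed for:

* three cell states at proportions 0.961 / 0.029 / 0.010 — a dominant
  pluripotent pool, an intermediate population, and a rare
  totipotent-like state;
* log-normal per-cell depth with median 10,000 UMIs, the depth scale of
  current droplet experiments;
* per-cell PCR duplication rate $\lambda_c \sim \Gamma(4, 4)$ with reads
  per UMI $= 1 + \mathrm{Poisson}(\lambda_c)$ — *cell-varying*
  amplification, which is exactly what makes UMI collapsing reduce
  between-cell variability non-trivially;
* edit status drawn once per molecule (editing is a property of the
  transcript, so all duplicates of a UMI agree before sequencing error);
* a configurable fraction of fusion-negative experimental cells whose
  editing is scaled down 100-fold;
* heterozygous germline SNPs and per-base sequencing error
  ($10^{-3}$ by default).

`simulateAlignments()` materializes this as coordinate-sorted tagged SAM
plus matching FASTA/GTF/VCF/BED; `simulateEditomeCounts()` is the fast path
that skips reads and draws the editome directly (multinomial totals over
gene weights, binomial edits at the state's gene-level frequency);
`simulateSiteCounts()` and `simulateDynamicCounts()` produce site-level and
pseudotime-resolved counts for calibration studies. Serialization of the
truth is plain text and lossless.

What the generator does *not* emulate — and hence what passing tests do
not certify about real data: realistic quality-score and error profiles,
spliced or chimeric reads, multi-mapping, ambient RNA, doublets, barcode
collisions, and transcript-level coverage bias (droplet 3'-end chemistry
concentrates edits near the 3' end; the generator places molecules
uniformly within exons). Reads are single-exon by construction, since
junction-spanning reads add no coverage to any tested property.

# Verification scale and design choices under openness

The test suite and the acceptance script run the workflow at sizes chosen
to finish comfortably on one CPU while leaving no statistical check
underpowered: 1,000 sites for calibration and recovery, 500–800 genes and
300–600 cells for the editome analyses (ten seeds for clustering
recovery), 500 genes × 300 cells for the pseudotime test, and 500 + 2,000
windows for motif enrichment. Every stochastic check is pinned to a seed
and every independently re-derivable quantity (aggregation, the four-part
filter, BH, rank-sum p-values, the beta-binomial tail, the spline LRT) is
compared against a brute-force oracle written separately from the
implementation.

Where the underlying conventions were genuinely open, the package commits
to: dropping both-strand-ambiguous sites; dropping consensus ties; the
global background model with optional per-site means; inclusive frequency
bounds; the 0.25 median-ratio negative-population rule; up-direction
attribution of DBTs; pseudocount 1 in the marker fold change; and
algorithmic (hierarchical) pattern grouping with a user-chosen k. Each is
configurable at the function surface.

# Known limitations

The background model assumes a site-independent overdispersion; true
per-site dispersion heterogeneity is absorbed into the pooled $\rho$. The
editome matrix treats a gene's sites as exchangeable — site-level
differential editing within a gene is out of scope. The negative-population
rule presumes the negative subset clusters separately; if fusion expression
varies continuously, the boundary is arbitrary at the configured fraction.
The spline LRT models counts per gene independently and does not share
dispersion across genes. Motif consensus scanning cannot capture the full
information content of a discovered weight matrix.
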