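---
title: "Linking G-quadruplexes to alternative promoter usage: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking G-quadruplexes to alternative promoter usage: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4prom)
```

# The scientific question

G-quadruplexes (G4s) are four-stranded DNA secondary structures formed by
stacked guanine tetrads in G-rich sequence. They are enriched at promoters
and have been implicated in transcriptional regulation. Many genes have
several promoters, and which promoter a cell uses determines the transcript
isoform it produces. `g4prom` implements an analysis chain that asks whether
G4 structures are associated with *which* promoter of a gene is used, by
combining three data types:

1. sequence-predicted G4 propensity (G4Hunter-style scanning of a genome),
2. promoter activity measured by 5′-end tag data (NET-CAGE CTSS counts) in
   two conditions (e.g. two cell lines), plus G4 ChIP-seq peaks and signal
   per condition, and
3. an independent G4-ligand treatment branch in which promoter activity is
   quantified from RNA-seq splice junctions.

Every stage can be exercised on data from the bundled synthetic generator,
which plants known promoter switches and G4 couplings.

# Models and procedures

## G4 scanning (`g4_base_scores`, `g4_extract_hits`, `g4_scan_fasta`)

Each base receives an integer score determined by its maximal homopolymer
run: G runs of length 1, 2, 3, ≥4 score +1, +2, +3, +4 per base; C runs
mirror this with negative sign; A, T, U, N score 0. A window of $W$ bases
(default 25) slides one base at a time and the window mean is compared with
a threshold $\theta$ (default 1.5; the permissive default of the original
scheme is 1.2). Windows with $|\text{mean}| \ge \theta$ and a common sign
are merged when they overlap or abut; each merged region is then trimmed so
it starts and ends on a scored base (G for positive regions, C for
negative), and the score is recomputed as the mean over the trimmed
interval. A negative score marks a C-rich region whose G4 would form on the
complementary strand; such hits are reported in plus-strand coordinates with
strand `-`.

Numerical choices worth stating:

* The threshold comparison is `>=`; the boundary case is deliberate and
  tested.
* Qualifying windows of opposite sign are never merged, even when adjacent.
* Trimming can only raise the magnitude of the mean (only neutral bases are
  removed), so a merged region never falls back below the window criterion.
* Soft-masked (lower-case) sequence scores identically to upper case, since
  reference genomes are soft-masked.

## Tag clusters and annotation (`call_tag_clusters`, filters)

Per-base CTSS counts are TPM-normalized per sample (`count / library size ×
10^6`, with the library size taken before any filtering) and pooled across
samples. On each chromosome and strand, positions with pooled signal join a
single-linkage cluster when adjacent member positions are at most
`merge_dist` (default 20) bases apart. Cluster counts are re-quantified as
member sums — the suite asserts tag conservation — and the cluster peak is
the member with maximal pooled TPM, ties broken toward the cluster's 5′
end so output is deterministic.

Clusters are then filtered in a fixed order, each step idempotent and
logged in the pipeline manifest:

1. **Support**: TPM strictly greater than `min_tpm` (default 1) in at least
   `min_samples` (default 6, half of a 12-sample design) samples. The
   strict inequality is a documented reading of "> 1 TPM"; the flag is
   exposed.
2. **TSS overlap**: at least one annotated same-strand TSS shares a base
   with the cluster; de-novo promoters are out of scope. An optional
   exclusion BED (typically predicted enhancers, produced by external
   tools) removes clusters on any-strand overlap first.
3. **Gene assignment**: clusters are assigned to the same-strand gene whose
   span, extended 1000 bp upstream (`upstream_ext`; the upstream window of
   the cited assignment step is not documented, so the value is exposed and
   logged), overlaps them; ties break toward the gene owning an overlapped
   TSS, then the largest overlap, then lexicographic id. Only
   protein-coding genes with symbols on chr1–22 and chrX are retained.
   Antisense assignment is not permitted.
4. **Composition**: within each gene and sample, a cluster's usage fraction
   is its TPM over the gene's summed TPM; clusters need a fraction strictly
   above 10% in at least 6 samples. Retained fractions are *not*
   re-normalized, so per-gene fractions need not sum to 1 downstream.

## Differential promoter usage (`diff_usage_test`)

Counts are normalized with standard TMM (trimmed mean of M-values, 30%/5%
trims, inverse-asymptotic-variance weights, factors rescaled to geometric
mean 1; verified against the reference implementation in the suite). A
single negative-binomial dispersion $\varphi$ shared across promoters is
estimated by Pearson pseudo-likelihood: with group means fitted by ML at a
given $\varphi$, $\varphi$ solves $X^2(\varphi) = $ residual df. Tagwise
shrinkage is deliberately not applied, matching the ligand branch's stated
practice and keeping the two branches consistent.

For each promoter $p$ of gene $g$, an NB GLM with log link and offsets
$\log(\text{library size} \times \text{TMM factor})$ gives the condition
log2 fold change $\beta_p$ with Wald variance $v_p$. The usage statistic
contrasts each promoter against its gene:

$$\tilde\beta_p = \beta_p - \frac{\sum_{q \in g} \beta_q / v_q}{\sum_{q \in g} 1/v_q},
\qquad
t_p^2 = \frac{\tilde\beta_p^2}{v_p - 1/\sum_{q} 1/v_q}$$

referred to an $F(1, \text{pooled residual df})$ distribution. The
inverse-variance-weighted mean of $\tilde\beta_p$ within a gene is zero by
construction (asserted to $10^{-8}$). Genes with a single expressed
promoter are reported with `p = NA` and excluded from the
Benjamini–Hochberg correction (NAs do not count toward the number of
tests). An alternative promoter (AP) is a promoter with `fdr < 0.05`
(strict) and usage fold change above 2, i.e. $|\tilde\beta_p| > 1$;
a flag switches the fold-change threshold to the promoter-level
$\beta_p$ instead, since the original description does not pin down which
scale the threshold lives on.

This is a re-implementation of the essential relative-usage contrast, not a
numerical clone of any particular package: the acceptance surface is
simulation calibration (type-I error within [0.03, 0.07] at $\alpha=0.05$
on nulls) and power on planted switches, both part of the shipped suite.

## G4 association, enrichment, density, directionality

A promoter is *G4-associated* in a condition when at least one peak shares
a base with the promoter interval or with the 100 bp window immediately
upstream. Upstream is strand-aware (rightward for minus-strand promoters);
this is the biologically coherent reading of "immediately upstream" and a
flag reverts to strand-naive behaviour. With two conditions each promoter
falls in a category — associated in `neither`, `one`, or `both`.

Enrichment of categories among APs over all retained promoters uses
Fisher's exact test on the 2×3 table — exact for totals ≤ 200 and a seeded
Monte-Carlo approximation (B = 10^5) beyond, with per-category ratios
(proportion among APs over proportion among background). The exact branch
is validated in the suite against full enumeration of tables with fixed
margins.

The relative G4 density profile tiles 10 bp windows over each promoter
plus flanks, with promoter bodies rescaled to a common 500 bp by exact
area-averaging and minus-strand regions flipped to read 5′→3′. Window $n$
reports

$$d_n = \frac{\sum_{i=1}^{M} w_i}{10 \times M}$$

where $w_i$ is the number of bases of window $n$ covered by G4s in region
$i$ and $M$ the number of regions — a coverage fraction in $[0,1]$,
M-weighted additive over disjoint region sets. The literal printed form of
this quantity divides by $10 \times N$ ($N$ = number of windows), which is
not a per-window fraction and violates the $[0,1]$ bound whenever
$M > N$; we treat that as a typo, implement the $M$ denominator by
default, and expose `denominator = "N"` to reproduce the literal formula
rather than silently resolving the discrepancy.

Per-promoter mean ChIP-seq signal is the base-weighted average over the
promoter interval (missing bases count 0), and ΔG4 is the
condition-ordered difference of means; AP-versus-non-AP shifts use
one-tailed Wilcoxon rank-sum tests.

Directionality at the gene level: per AP, the G4 effect is *promoting* if
the promoter is associated only in the condition where it is more active,
*repressing* if only in the other, *neutral* if both or neither (the
both-associated-but-biased case is deliberately neutral; the source
analysis does not state a tie-break). Genes are labelled `promotes`,
`represses`, `bidirectional_promotes`, `bidirectional_represses`, or
`mixed` (excluded from counts) by the rules tested in
`test-g4assoc.R`.

## The ligand branch

Promoter activity under G4-ligand treatment is quantified from STAR-style
splice-junction files: a gene's multi-exon transcripts group into promoters
by exact TSS position (first-exon-overlap grouping is a configurable
alternative), a promoter's count is the sum of uniquely mapping reads over
its distinct first introns, single-exon transcripts contribute nothing, and
promoters whose first exon lies inside an internal exon of another
transcript of the same gene are excluded *before* matching so that their
reads are accounted as unmatched — read conservation is exact and tested.
Rows need CPM strictly above 1 in at least one sample; library sizes are
then recomputed. Testing delegates to the usage machinery above, with a
`relaxed` mode (unadjusted p < 0.05, any fold change above 1) mirroring
low-power reanalyses. Distances from AP promoters to the nearest predicted
G4 are 0 on overlap and otherwise the gap in bases (strand ignored), with
a seeded random baseline of equal size drawn uniformly from expressed
non-AP promoters (expression-matched sampling is a documented option).

# The synthetic world

`simulate_world()` emits every input format with known truth: a two-
chromosome genome (base composition 30/20/20/30 for A/C/G/T) with a planted
24-mer G4 motif (score 64/25 = 2.56 at the default window, asserted at
generation time to pass θ = 1.5) upstream of selected promoters; genes
with 1–4 promoters (single-promoter probability 0.877, the observed
genome-wide fraction in the motivating data); NB-distributed CTSS counts
(depth 200 tags/promoter, dispersion 0.05) spread over ±3 bp around each
TSS; planted 4-fold usage switches in half of the multi-promoter genes;
per-condition G4 peaks coupled to the up-regulated side of each switch
with probability ρ, on top of a 15% background peak rate that applies to
every promoter (so ρ = 0 is indistinguishable from background); junction
files drawn from the same usage shares; and 6 replicates per condition.
Where the motivating study pins a value (replicates, depth scale, switch
thresholds, 87.7%) the default is that value; remaining rates (background
peak rate, gene-level DE fraction 0.2, lognormal gene size sd 0.5) are
fixed once at values a CAGE analyst would call unremarkable, and are not
tuned.

Each output kind draws from its own sub-seed derived from the master seed,
so adding samples never perturbs existing ones, and identical
configurations are byte-identical on disk.

What the generator does **not** emulate: promoter shape (broad/sharp),
mappability and GC bias, enhancer contamination, correlated replicates,
overdispersion heterogeneity across promoters, and realistic intron
structure beyond two exons. A green recovery test therefore establishes
that the statistics behave as designed under their stated model — not that
the pipeline is robust to every artefact of real CAGE or ChIP-seq data.

# Known limitations and deliberate deviations

* Exact scale invariance of the usage statistic under rescaling of one
  sample is impossible for any offset-weighted likelihood estimator (the
  sample's weight in the group estimate changes); the suite tests the
  property as approximate (correlation, no systematic shift, stable
  calls).
* Merged G4 regions are trimmed to scored bases and rescored; the
  untrimmed window mean (e.g. 64/25 for the canonical planted motif) is
  what the threshold sees, the trimmed mean (64/22) is what is reported.
* Fisher Monte-Carlo p-values have a 1/(B+1) floor; exact enumeration is
  used wherever the table total allows.
* The genome-wide human scan is supported (`g4_scan_fasta` streams one
  record at a time) but not shipped: reproducing the published hg19
  candidate count requires the external genome and is documented in the
  README as a full-data workflow.
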