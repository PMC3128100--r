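---
title: "Open chromatin analysis and variant prioritization with fairechip"
author: "fairechip maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Open chromatin analysis and variant prioritization with fairechip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fairechip)
```

## The problem

FAIRE (formaldehyde-assisted isolation of regulatory elements) enriches
nucleosome-depleted DNA: open chromatin partitions into the aqueous phase
of a phenol extraction and, hybridized against input on a two-channel
tiling array, shows up as elevated log2 ratios over runs of consecutive
probes.  Mapping these nucleosome-depleted regions (NDRs) in
trait-relevant cell types, then intersecting them with the linkage
disequilibrium (LD) neighbourhood of genome-wide association (GWA) index
SNPs, is a way to prioritize which of the many statistically equivalent
variants at a locus is likely to be the functional, regulatory one.
`fairechip` implements that pipeline end to end for the megakaryocyte /
erythroblast setting — cell types relevant to platelet and red-cell
traits — together with the downstream analyses such a study needs: peak
concordance across cross-linking conditions and cell types, genomic
annotation of peaks, lineage-enrichment testing, eQTL and knockout
differential-expression screens, and an expression-filtered
protein-interaction network around the differentially expressed genes.

Everything runs on plain-text inputs (TSV/BED/GFF3) and on synthetic data
from the package's own generators, so the full pipeline is exercised
without any array download.

## Signal model and scaling

Probe-level input is a log2 ratio of the FAIRE channel over input per
probe.  Between-channel scaling subtracts the *Tukey biweight mean* of all
log2 ratios of a condition (array-wide) from every value.  The biweight
location iteratively reweights observations with the bisquare kernel
$w_i = (1-u_i^2)^2$ for $|u_i|<1$, $u_i = (x_i - m)/(c \cdot \mathrm{MAD})$,
with tuning constant $c = 5$ and the unscaled median absolute deviation;
it is a robust centre that ignores the enriched (peak) tail, so the
background sits at zero after scaling.  When the MAD is zero the median
is returned.  Convergence is declared at $10^{-6}$ on the location, with
a 50-iteration cap.

## Peak calling

NDRs are called with an iterative-threshold sliding-window scan on the
scaled ratios, per chromosome:

* The **hypothetical maximum** of a chromosome is
  $P_{\max} = \text{mean} + 6 \cdot \text{SD}$ of its scaled ratios.
* A descending series of cut-offs is taken at percentages of
  $P_{\max}$: from 90% down to 15% in steps of 0.5, i.e. 151 values.
  The vendor parameter block this mirrors also states "number of steps:
  100", which is arithmetically inconsistent with the series bounds; we
  expose an optional `max_steps` cap (off by default) rather than guess
  which value the original software honoured.
* At each cut-off, a 300 bp window anchored at each probe start
  qualifies when at least 4 probes inside it (by start position) exceed
  the cut-off.  Overlapping qualifying windows merge; inside a merged
  region, a run of more than 2 consecutive below-cut-off probes splits
  it (`gap_probes`; the vendor's "all probes in peak>cut-off=2" is read
  as this tolerated-gap parameter).  A peak spans from its first to its
  last above-cut-off probe and must hold at least `min_probes` of them.
* Because every cut-off in the series admits a superset of the probes
  admitted by the cut-offs above it, the union over the series equals
  the peak set at the most permissive cut-off; each final peak is
  annotated with `score_pct`, the highest percentage at which any part
  of it was detected.  `n_probes` counts above-cut-off probes (at the
  most permissive cut-off) inside the final boundaries — after merging
  the rare overlapping fragments that a long probe's overhang can
  produce between split groups.

The windows are probe-anchored rather than base-anchored: a window
anchored between two probe starts contains the same probe set as the one
anchored at the next probe start, so the results are identical and the
scan is linear-time.  Peak boundaries come from above-cut-off probes,
not window edges, so every emitted interval is probe-supported.

The test suite pins this implementation, at every cut-off, to an
exhaustive oracle that enumerates all windows with a dense
probe-in-window matrix and merges by fixed-point iteration.

## Concordance and comparison

Two cross-linking conditions (8 and 12 min) are merged by keeping only
*concordant* regions: connected components (≥ 1 bp overlap) of the union
of both peak sets that contain at least one peak from each condition.
Cross-cell-type comparison counts shared regions the same way, as
connected components across both cell types, which makes the shared
count a single number valid from either side; per-side percentages are
that count over the side's peak total.  The overlap criterion is ≥ 1 bp
— the most permissive reading, exposed as a configurable minimum in case
stricter reciprocal-overlap definitions are wanted.

## Annotation

Each peak receives exactly one feature class with precedence
`promoter_5utr > utr3 > exonic > intronic > intergenic`.  The promoter
window is 2 kb upstream of the TSS on the gene's strand (unioned with an
annotated 5'-UTR); 2 kb is a package default — the class fractions this
produces are only comparable across peak sets annotated with the same
window.  TSS distance is measured from the peak midpoint, signed
negative upstream, with ties broken by the lexicographically smaller
gene id for determinism.

## Variant prioritization

Index SNPs are expanded to all panel SNPs with $r^2 \ge 0.8$ and MAF
$\ge 0.05$ (no distance limit), always including the index itself at
$r^2 = 1$.  A SNP lies in an NDR when its 0-based position falls in the
half-open peak interval; since every peak containing a given position
overlaps every other such peak, each reported variant gets one harboring
region and a cell-type specificity (`MK_only`, `EB_only`, `shared`).
Motif annotation is purely an intersection with externally supplied,
per-allele motif intervals: a variant is flagged when a motif contains
it and its presence differs between alleles.

Lineage enrichment compares per-gene peak densities (peaks overlapping
the gene ± 2 kb, normalized by gene length in Mb) between cell types
with a Wilcoxon rank-sum test.  For combined $n \le 20$ the null
distribution is enumerated exactly over all $\binom{n}{n_1}$ subset rank
sums — mid-ranks make this a full permutation test under ties — and
above that a normal approximation with tie-corrected variance and
continuity correction takes over.  The reference analysis does not state
its sidedness; the default is two-sided and the alternative is an
argument.

## Expression analyses

The eQTL test is Spearman's rank correlation between allele dosage and
log2 expression with the t-approximation for the nominal P-value; the
cis scan restricts to genes whose TSS lies within ±1 Mb of the SNP.
The knockout screen averages replicates (inputs are assumed
replicate-averaged, normalized log2 values), takes the difference of
group means as the log2 fold change and a one-way ANOVA P-value per
gene.  The ±1.5 fold-change cut-off is applied on the **linear** scale,
$|\log_2 FC| \ge \log_2 1.5 \approx 0.585$: the reference gene lists
include genes at log2 changes of −0.996 and −0.711, which only pass
under the linear reading.  A `fc_scale = "log2"` switch provides the
stricter interpretation.  Over-representation of hit lists in gene sets
uses the hypergeometric upper tail; the row-wise ANOVA is vectorized
in-package and cross-checked in the tests against `stats::oneway.test`
and the two-group $F = t^2$ identity.

## Network construction

Differentially expressed genes are mapped to orthologous "core"
proteins; candidate nodes are the cores plus their first-order
interactors from a pairwise interaction table; non-core interactors not
detected as expressed in megakaryocytes (detection $P > 0.01$) are
dropped (cores are exempt — the reference procedure filters
interactors); and only the largest connected component is rendered,
with ties broken by edge count and then the lexicographically smallest
node set.  One subtlety: the *rendered* node set is not monotone in the
detection threshold, because relaxing the filter can promote a
different component to largest.  Monotonicity does hold for the
expression-filtered candidate set before the component restriction,
which `build_ppi_network()` exposes as `kept_nodes`; the property tests
assert it there.

## The synthetic-data generator

The generators emulate the statistical structure the pipeline assumes,
at the study's stated conditions:

* **Locus panel**: 62 loci of 155 kb (≈ 9.6 Mb total, matching a
  62-locus / 9.59 Mb tiling design), 3 genes per locus with exon/UTR
  structure, 8 genes labelled per lineage (MK, EB, MONO).
* **Probes**: start-to-start spans uniform on 23 ± 10 bp (23 bp mean
  probe span), lengths uniform on 50–75 bp.
* **Signal**: probes inside a planted NDR have mean log2 ratio equal to
  the background plus `enrichment_log2` (default 2, a strong FAIRE
  enrichment); i.i.d. Gaussian noise with SD 0.5; two conditions whose
  enrichment is jittered (SD 0.2) to emulate cross-linking differences.
  Planted NDRs are 500 bp, at least one window width (300 bp) apart so
  distinct elements remain resolvable by the caller, and shared between
  cell types with probability 0.6 (near the published shared fraction).
* **LD**: star-shaped around each index SNP — only index→proxy $r^2$ is
  drawn (U(0.5, 1)), as that is all the proxy-expansion step consumes;
  MAF ~ U(0.05, 0.5).
* **Expression**: 3 knockout vs 3 wild-type samples, planted log2 fold
  changes of ±1.5 with N(0, 0.3) noise on a U(6, 12) log2 baseline;
  per-cell detection P-values small (< 0.005) for expressed genes.
* **Interactome**: Erdős–Rényi-style edges at a configurable density
  over cores and interactors, with a configurable expressed fraction.

What the generator deliberately does **not** model: spatial array
artifacts, probe GC/thermodynamic effects, heavy-tailed or correlated
probe noise (a heavier-tailed option exists for stressing the robust
scaling), coalescent LD among proxies, and library-level normalization
(expression is generated pre-normalized).  Passing tests therefore
demonstrate algorithmic correctness and statistical calibration under
the assumed model, not performance on raw array data.

All generators are pure functions of their parameters and a seed;
per-stage seeds are derived from one global seed, so a whole simulated
experiment is reproducible byte for byte.

## Numerical and design choices

* Internal coordinates are 0-based half-open everywhere; conversion
  happens only at I/O (BED in/out 0-based half-open; GFF3 and SNP
  positions 1-based).  Printed locus lengths in the field mix
  conventions — a 494 bp region quoted exclusively alongside 671/662 bp
  inclusive PCR products — so `interval_length()` supports both and
  infers neither.
* Chromosome names are compared as exact strings; no "chr" stripping.
* A single-cutoff series (`p_start == p_end`) is allowed.
* Degenerate inputs error loudly: zero-SD chromosomes, constant
  genotype or expression vectors, empty universes, empty peak sets in
  a concordance denominator.
* Nominal P-values are reported without multiple-testing correction,
  matching the reference practice; callers can apply `p.adjust`.

## Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` run the simulation checks at
deliberately compact sizes chosen by the package: peak-caller/oracle
equivalence on 500-probe tracks, planted-NDR recovery on 2 loci × 20 kb
per seed (100 and 50 seeds respectively), rank-sum calibration on 2,000
null draws at 8 vs 8, the DE screen on 200 genes × (3 vs 3) per seed,
and the end-to-end demonstration on 6 loci × 30 kb.  These sizes keep
the whole suite in the low minutes while leaving every statistical
assertion well-powered; all of them scale up by argument if a user
wants array-scale runs.

## Limitations

The package reproduces the *procedures* of the reference analysis; its
dataset-level results (peak counts at real loci, concordance
percentages, eQTL P-values, the 642-node network) depend on the
original array, cohort and database inputs, which are consumed as plain
tables when available but are not bundled.  The bundled seven-variant
table ships with synthetic coordinates (only the relational structure —
specificity, r², MAF, distances — is real).  The vendor tool's exact
window semantics are not documented; where two readings exist
(`gap_probes`, `max_steps`) both are parameterized rather than silently
chosen.
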