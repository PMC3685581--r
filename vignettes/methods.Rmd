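---
title: "Methods: divergence, polymorphism and the adaptive fraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: divergence, polymorphism and the adaptive fraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mkalpha)
```

This vignette documents the scientific model behind `mkalpha`, the
conventions and numerical choices baked into its defaults, and the scope
and limits of the bundled data generator. The worked example lives in the
package README; here the emphasis is on *why* each step works the way it
does.

## The question and the study design

Between two closely related species, protein-coding differences accumulate
by two routes: neutral (or effectively neutral) substitutions drifting to
fixation, and adaptive substitutions driven by positive selection. The
McDonald–Kreitman (MK) framework separates them by contrasting divergence
*between* species with polymorphism *within* species at the same loci,
split into non-synonymous (amino-acid changing) and synonymous (silent)
classes:

|                | non-synonymous | synonymous |
|----------------|---------------:|-----------:|
| fixed (divergence)   | $D_n$ | $D_s$ |
| polymorphic    | $P_n$ | $P_s$ |

Under strict neutrality the ratio $D_n/D_s$ equals $P_n/P_s$: both are set
by the same mutational input and the same constraint. An excess of
non-synonymous *fixations* ($D_n/D_s > P_n/P_s$) indicates positive
selection; an excess of non-synonymous *polymorphism* indicates segregating
slightly-deleterious variants.

The pipeline builds this table per orthologous gene pair from (i) assembled
transcriptome contigs of both species and (ii) pooled-sample read pileups
for the within-species polymorphism, then tests each gene and estimates the
transcriptome-wide adaptive substitution fraction.

## Stage conventions and defaults

### ORF prediction

De novo prediction scans all six reading frames and returns the longest
closed reading frame — first in-frame `ATG` through the next stop — of at
least 30 amino acids (`min_aa = 30`). Ties prefer the earlier start, then
the plus strand. The 30-aa floor discards the spurious short ORFs that
random sequence yields in abundance while keeping nearly all real coding
contigs. A homology-anchored mode (`anchor =`) instead extends a given
strand/frame through its stop-free stretch and may stay open at either end;
it exists for contigs whose reading frame is known from a protein hit but
that lack a start or stop within the assembled fragment.

### Codon alignments

Within each ortholog cluster the cross-species contig pair with the highest
global protein alignment score (BLOSUM62, gap opening 10, extension 0.5,
via `Biostrings::pairwiseAlignment`) is selected, and the protein alignment
is back-translated onto the nucleotide sequences so gaps fall only on codon
boundaries. Aligning at the protein level and back-translating — rather
than aligning nucleotides directly — keeps frame-preserving indels from
fragmenting codons.

Two filters follow. First, 15 bp (five codon columns) are trimmed from each
alignment end: assembled transcript ends are enriched for assembly and
alignment artifacts. Second, alignments with uncorrected nucleotide
divergence (p-distance) strictly above 0.1 are discarded; at that distance
between sister species the "ortholog" is more plausibly a paralog or a
misassembly than a 7-fold outlier of the genuine divergence distribution.

### Counting sites and substitutions

Synonymous and non-synonymous *sites* and *substitutions* use the
Nei–Gojobori (1986) unweighted pathway method. Each codon position
contributes fractional synonymous/non-synonymous site counts according to
the effect of the three possible point mutations; mutations that create a
stop are excluded from the denominator by default (`stop_mutants =
"exclude"`), with a `"nonsynonymous"` convention available. Site counts are
averaged over the two sequences. For codon pairs differing at multiple
positions all stop-free substitution orderings are enumerated with equal
weight; the counted $D_n + D_s$ for a pair always equals its number of
differing positions. Per-site divergences can be Jukes–Cantor corrected
($-\tfrac{3}{4}\log(1 - \tfrac{4}{3}p)$), though at ~1.5% divergence the
correction is nearly negligible.

### Pooled SNP calling

Polymorphism comes from pooled sequencing: many individuals sequenced as
one library, so allele frequencies are read-count fractions, not genotypes.
A pileup column is called a SNP only when *all* filters hold:

* depth ≥ 10 reads,
* exactly two alleles observed (three-allele columns are rejected outright),
* the rarer allele seen ≥ 2 times,
* column quality ≥ 20,
* at most 3 low-quality bases in the surrounding window.

The conjunction is deliberate and literal — the test suite checks the
caller against an independent re-application of the five rules. Each SNP in
an ORF is classified silent or non-silent by translating the codon with
each allele (strand-aware), and binned by rarer-allele frequency: low
(< 5%), moderate (5–15%), common (≥ 15%).

The price of pooling is power at low frequency: the rarer allele must be
sampled at least twice, so the detection probability is the binomial upper
tail $1 - F_{\mathrm{Binom}(d, f)}(1)$. At the default minimum depth of 10
a 25% allele is detected with probability
`r round(detection_probability(10, 0.25), 3)` — and a 5% allele with
probability only `r round(detection_probability(10, 0.05), 3)`. Rare
variants are therefore systematically under-sampled, which is one reason
the frequency-class exclusions below matter.

### Per-gene tests and FDR

Each gene's 2×2 table is tested for independence with Pearson's chi-square
without continuity correction (the package also offers Fisher's exact
test, the safer choice at very small counts). Genes with any zero cell are
excluded rather than tested — the odds ratio is undefined there. P-values
are Benjamini–Hochberg adjusted across tested genes, and a gene is flagged
as positively selected only when its adjusted p-value is at most the FDR
level *and* its neutrality ratio $(D_n/D_s)/(P_n/P_s)$ exceeds 1; a
significant table in the other direction signals segregating deleterious
variation, not adaptation.

### The aggregate alpha estimator

The adaptive substitution fraction is estimated from counts summed over
genes:

$$\alpha = 1 - \frac{\sum D_s \,\sum P_n}{\sum D_n \,\sum P_s}.$$

Summing before dividing, rather than averaging per-gene $\alpha$ values,
avoids the instability of per-gene ratios with small or zero counts: most
genes at ~1.5% divergence have single-digit entries. The cost is that the
aggregate estimator weights genes by their counts and is biased when
selection intensity covaries with gene length or diversity; this is the
standard trade-off, and the package makes the choice explicit rather than
hiding it.

Uncertainty comes from a nonparametric bootstrap over *genes* (resampling
genes with replacement, default 1000 replicates, percentile interval) —
genes, not sites, are the approximately independent units.

Slightly-deleterious non-synonymous variants segregate at low frequency but
rarely fix, inflating $P_n$ and biasing $\alpha$ downward. The standard
mitigation is re-estimating $\alpha$ after excluding low (< 5%) or low and
moderate (< 15%) frequency SNPs; `estimate_alpha()` records which exclusion
was applied and the pipeline reports all three. A rising
$\alpha_{none} < \alpha_{low} < \alpha_{low+moderate}$ progression is the
signature of segregating deleterious variation.

### Divergence times

`clock_estimate()` converts mean synonymous divergence into time under a
strict clock, $T = d_S / (2r)$, for a supplied range of per-lineage
synonymous rates; the factor 2 counts both lineages. With $d_S = 0.06$ and
insect synonymous rates of 0.011–0.016 substitutions per site per million
years this gives roughly 1.9–2.7 My. Published splits for comparable data
sometimes quote other intervals from the same inputs; conventions for the
factor of two and for rate units differ across the literature, so the
convention used here is stated explicitly and the function exposes the rate
vector rather than hard-coding one.

## The data generator

`simulate_study()` exists so that every stage can be validated against
known truth. Its model, briefly:

* Genes are independent; lengths are Poisson around `mean_len_codons`
  (default 134 codons ≈ 400 bp, a typical trimmed transcriptome alignment
  length). Sequences are `ATG` + random sense codons + stop.
* Neutral divergence hits internal sites with a per-site probability
  calibrated so the *total* realized divergence matches
  `divergence_target` (default 0.0153) after adaptive substitutions are
  added: adaptive events are drawn per gene as Poisson with mean
  $D_{n,0}\,a/(1-a)$, forced non-synonymous, so the realized adaptive
  fraction among non-synonymous fixations converges to `adaptive_fraction`.
* Polymorphism: each internal site segregates with probability `theta`
  (default 0.006 per bp, a typical insect nuclear diversity); allele
  frequencies are drawn from the folded neutral $1/x$ spectrum discretized
  on a pool of `pool_chromosomes` chromosomes (default 120, i.e. 60
  diploid individuals). An optional `deleterious_theta` adds a forced
  non-synonymous class with a $1/j^2$ low-frequency spectrum truncated at
  15%.
* Pileups: per-site depth is Poisson around `coverage_mean`, reads sample
  the two alleles binomially at the true frequency, and a per-base error
  rate (default 0.0107, a realistic pyrosequencing figure) substitutes
  random bases. Quality columns are simulated so that the caller's quality
  filters have something real to reject.

Everything is seeded; a fixed seed reproduces the study byte for byte.

**What the generator does — and does not — establish.** Passing the
recovery tests shows the estimator chain is *consistent under its own
model*: independent genes, no linkage, free recombination, a static
demography, site-independent mutation, and divergence low enough that
multiple hits are rare. It does not show robustness to demographic change
(bottlenecks mimic the deleterious signature), to linked selection, to
biased codon usage making synonymous sites non-neutral, or to
reference/assembly artifacts — none of which the generator models. The
generator is an instrument for verifying the arithmetic and the sampling
behaviour of the pipeline, not evidence about any real species pair.

## Problem sizes

The defaults target desk-scale validation: hundreds to a few thousand
genes simulate in seconds, a full pipeline run on 300 genes with pileups
takes well under a minute, and 1000-replicate bootstraps over a few
thousand genes are sub-second. Real transcriptome studies (tens of
thousands of contigs) stay within the same design — all per-gene work is
independent and the memory footprint is one gene pair at a time plus flat
result tables.
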