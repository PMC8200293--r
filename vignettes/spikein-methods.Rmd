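---
title: "Methods: spike-in calibrated nascent RNA analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-in calibrated nascent RNA analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nascentr)
```

## The problem

A cell-wide transcriptional shutdown and an experiment in which nothing
changes produce *identical* data under conventional RNA-seq
normalization: rescaling every sample so that the typical gene is
unchanged removes exactly the global component of the signal. Nascent-RNA
(TT-seq) experiments restore the absolute scale by mixing a fixed mass of
metabolically labelled RNA from a second organism into every sample
before purification — here modelled as a 90:10 target:spike-in mass
ratio. Reads are mapped to both genomes; the spike-in genes then serve as
an internal ruler that is, by construction, constant across samples.

`nascentr` implements the quantitative steps downstream of alignment for
such an experiment, and a synthetic-data generator that produces inputs
with known ground truth so that every step can be validated by parameter
recovery.

## Normalization model

Size factors follow the median-of-ratios construction. For a reference
gene set \(R\) (genes with a zero count in any sample are dropped, as the
log-scale geometric mean is undefined for them; gene names ending in
`rRNA` or `RDN` are excluded because high-copy ribosomal loci are
unstable reference points):

\[ g_i = \Big(\prod_{j=1}^m K_{ij}\Big)^{1/m}, \qquad
   s_j = \operatorname{median}_{i \in R} \frac{K_{ij}}{g_i}. \]

Two reference choices give the two analysis modes:

* **internal** — \(R\) = target-organism genes. Any uniform factor
  applied to a sample's target genes is absorbed into \(s_j\), so
  normalized *ratios between samples* are invariant to global shifts:
  this mode asks which genes changed *relative to the rest of the
  transcriptome*.
* **spikein** — \(R\) = spike-in genes only. Because the spike-in mass is
  constant, global shifts in target transcription survive normalization:
  this mode measures *absolute* transcriptional output.

The contrast between the two modes is itself the analysis: a gene set
that disappears under internal normalization but dominates under
spike-in normalization is the signature of a global effect. The companion
summary statistic is the per-sample ratio of total target reads to total
spike-in reads, with condition-level medians across replicates.

Two numerical notes, both consequences of the geometric-mean reference.
With an even reference count the median is the arithmetic mean of the
two central ratios (the conventional sample median; log-scale
implementations interpolate geometrically and differ in the fourth
decimal). And multiplying one sample of \(n\) by \(c\) multiplies every
\(g_i\) by \(c^{1/n}\), so the sample's factor grows by \(c^{1-1/n}\) and
the others shrink by \(c^{1/n}\): equivariance, masking and exposure are
exact statements about *between-sample ratios* of normalized values, and
the test suite asserts them in that form.

## Differential expression

The package deliberately does not re-implement a full NB generalised
linear model with dispersion shrinkage or multi-factor designs. The test
provided is a two-group Wald test on normalized counts:

1. per-gene, per-group means and variances of \(K_{ij}/s_j\);
2. method-of-moments dispersion. A normalized count has variance
   \(\mu/s_j + \alpha\mu^2\), so the Poisson part is weighted by the
   group mean of \(1/s_j\):
   \(\hat\alpha_g = (\widehat{\mathrm{var}} - \bar\mu\,\overline{1/s})/
   \bar\mu^2\), pooled across the two groups by degrees of freedom and
   floored at 0 (the Poisson limit);
3. by default (`dispersion = "shared"`) the per-gene estimates are
   averaged across genes into a single shared dispersion. With three
   replicates per group a per-gene moment estimate has ~4 degrees of
   freedom; plugging it into a normal-reference Wald statistic gives a
   t(4)-like null and a rejection rate near 0.11 at \(\alpha = 0.05\).
   Averaging across genes makes the plug-in variance essentially
   non-random, and the suite's calibration test measures a null rejection
   rate inside [0.03, 0.07] (2,000 genes, 3 vs 3, ten seeds). The
   generative model shares one dispersion across genes, so nothing is
   lost there; on real data with gene-specific dispersions the shared
   estimate is a middle ground, and `dispersion = "per_gene"` is
   available;
4. \(\mathrm{lfc} = \log_2\frac{\bar\mu_1 + p}{\bar\mu_0 + p}\) with
   pseudocount \(p = 1\) (unstated in the original analyses; fixed here
   for reproducibility), delta-method standard error from the NB
   variance, two-sided p from the normal reference. All-zero genes get an
   undefined p-value and are excluded from multiple testing.

Benjamini–Hochberg adjustment is the standard step-up (delegated to
`stats::p.adjust`). Calls require both FDR \(\le\) 0.05 and a linear fold
change beyond the threshold (1.5- or 2-fold); raw pseudocounted fold
changes are used, not shrunken ones. Gene-set overlaps use the one-sided
hypergeometric tail \(P(X \ge k)\) — every overlap hypothesis here is
enrichment — with a default universe of 6,049 genes (the budding-yeast
protein-coding catalogue size conventionally used for such tests; the
pipeline substitutes the simulated gene count).

## Proximity association

Each gene body's distance to its nearest feature interval is the gap
between closest boundaries (0 on any ≥1 bp overlap), strand-agnostic and
intra-chromosomal; gene bodies rather than TSSs anchor the distance, and
feature sets are treated as unstranded. Genes on chromosomes with no
feature are excluded from both partitions symmetrically and their count
reported. The statistic is

\[ r = \frac{\operatorname{median}(d_{\text{sig}})}
            {\operatorname{median}(d_{\text{null}})}, \]

with \(r < 1\) meaning significant genes lie closer to the features. When
either median is zero (most genes of a partition overlap a feature) the
median is replaced by the zero-distance tally; the fallback ratio is
defined as \((z_{\text{null}}/n_{\text{null}})/(z_{\text{sig}}/n_{\text{sig}})\)
so that \(r < 1\) retains its orientation, and `fallback_used` is always
reported so consumers can detect the regime. The orientation of the
original tally fallback is not documented anywhere authoritative; this
choice is the package's own, made once and flagged in the output. No
permutation p-value is attached to \(r\) — null stability is exercised as
a test-suite property (random significant sets of the default synthetic
genome give ratio medians within [0.8, 1.25] over 200 resamples), not as
a user-facing statistic.

## Read counting and repeats

Alignment filtering mirrors the standard nascent-RNA criteria: at most 2
mismatches ("fewer than three"), optionally primary-only and
unique-only. Gene counting assigns a read to every gene it overlaps by
≥1 bp under the library strand rule; the default is reverse-stranded
(read strand opposite the gene strand) with multi-overlap counting, the
behaviour of `featureCounts -O -s 2`.

For repeat families, each read is expanded into one row per *best*
mapping location — all locations tied at the read's minimum mismatch
count ("best possible" is interpreted as that tie set) — with weight
\(1/k\), so each read contributes exactly one unit of mass. Weighted
feature counts sum these weights over ≥1 bp overlaps, strand-agnostic,
with full weight to each of several overlapped features (no minimum
overlap or strand rule is documented for this step; multi-overlap
mirrors the gene-counting choice). Per-million normalization divides by
the filtered read count (each read counted once regardless of \(k\)).

## Metagene matrices

Coverage is per-base read depth, optionally strand-split. The
scale-regions matrix uses 500 bp flanks and a 1,000 bp body at 10 bp
bins (200 columns); minus-strand genes are mirrored so columns always run
upstream → TSS → body → TES → downstream. Body bins average coverage over
*exact fractional* genomic sub-intervals — a gene of length \(L\)
contributes \(L/100\) bp per bin with proportional end weights — rather
than nearest-base resampling: this is deterministic, well-defined for
genes both shorter and longer than the grid, and checkable against a
per-base weighted-mean oracle (the suite asserts agreement to \(10^{-9}\)
on gene lengths 37, 500, 1,000 and 4,999 bp). Positions beyond chromosome
ends contribute zero coverage but still count in the denominator
(missing-data-as-zero). Uniform coverage therefore yields an exactly
constant matrix, up to last-ulp floating-point rounding; the suite
asserts it at \(10^{-12}\). Heat-map rendering and row clustering are out
of scope; the matrix and its column-wise mean/median profile are the
exported artifacts.

## TES base composition

The adenine fraction is computed per offset in \([-100, 100)\) around
each gene's transcription end site, on the sense strand (minus-strand
genes are read on the reverse complement, offsets oriented
downstream-positive); offset 0 is the first base past the gene end.
Positions off a chromosome end are excluded from numerator and
denominator at that offset. Smoothing is a 16 bp sliding mean; an even
window has no centre, so the convention is fixed at offsets \(-8..+7\)
around each position, truncated and renormalized at the edges (no
sequence is fabricated beyond the window). A 16-wide asymmetric window
shifts an affine ramp by half a step; the suite asserts exact affine
reproduction with odd windows and mass preservation for the even
default. This bias matters because adenine templates uracil: 4-TU
labelling enriches fragments near A-rich stretches, producing the
characteristic coverage peak near gene ends.

## The synthetic-data generator

`sim_config()` fixes the study conditions; all generators are pure
functions of (config, seed), each drawing from its own stream seeded at
`seed` plus an operation-specific offset so that adding one stage never
reshuffles another. Defaults and rationale:

| parameter | default | why |
|---|---|---|
| `spike_mass_fraction` | 0.10 | 90:10 target:spike mass mix |
| `global_scale` | control 1, treated 1/2.6 | the headline global repression |
| `n_samples_per_condition` | 3 | triplicate design |
| `de_fraction`, `de_log2fc_location` | 0.1, 2 | a minority of genes with strong effects |
| `nb_dispersion` | 0.05 | typical biological replicate dispersion; 0 gives Poisson |
| `proximity_enrichment`, distance | 0.8, 2 kb | most true-DE genes placed near a binding site |
| gene lengths | log-uniform 500–5,000 bp | spans both sides of the 1,000 bp body grid |
| `families` | Ty1 31, Ty2 13, Ty3 2, Ty4 3, Ty5 1 | the budding-yeast Ty copy-number complement |

Counts are negative binomial with mean
\(\text{base}_i \cdot \text{effect}_{ij} \cdot \text{scale}_j \cdot
\text{depth}_j\): effects apply only to target genes in non-reference
conditions, the global scale applies to target genes only (spike-in mass
is constant), and spike-in baselines are rescaled so their expected share
of reference-condition counts equals `spike_mass_fraction`. Genes are
placed without overlap by rejection sampling (site-linked genes first,
longest first, with a deterministic sweep of site offsets as a fallback
in dense neighbourhoods); spike-in genes live on dedicated chromosomes,
mirroring two-genome mapping. Repeat reads are drawn from families in
proportion to abundance and reported at the homologous offset in every
copy with one shared mismatch count — perfect repeats, so the best-location
tie covers all copies.

What the generator does *not* emulate: sequencing errors and adapter
content, mappability structure, gene-length or GC biases in counting,
gene-specific dispersions, fragment-level (paired) coverage, correlated
gene programmes, or the labelling-bias coverage peak near the TES (the
sequence bias is simulated; its coupling into coverage is not). Passing
recovery tests therefore demonstrates correctness of the *computational*
machinery under the stated generative assumptions, not robustness to
every artefact of real libraries.

## Degenerate inputs and tie-breaks

Zero-coverage runs are omitted from bedGraph output; all-zero
chromosomes produce no records. Genes shorter than one base per body bin
are still processed (fractional weighting). All-zero genes are excluded
from multiple testing rather than assigned p = 1. An undefined
global-transcription ratio (zero spike-in tally) is an error, not an NA.
Reads mapping to several genes are dropped as ambiguous only when
multi-overlap counting is disabled. Empty alignment sets filter to empty
sets, but expanding an empty set is an error (a weight table with no
mass is more likely a pipeline bug than a result).

## Problem sizes

The bundled tests run the generator at 120–2,000 target genes, 3 vs 3
replicates, 10–20 seeds for Monte-Carlo checks, 10,000 reads for
abundance recovery and 200 resamples for proximity null stability; the
full pipeline smoke test uses a 120-gene genome with 20,000 gene-body
reads. These sizes keep the whole suite around a minute while leaving
every statistic in its asymptotic regime of interest.

## Limitations

The NB test is a two-group comparison: batch terms, phase × treatment
interactions and dispersion shrinkage are out of scope, as are
variance-stabilizing transforms, PCA and clustering. BAM/bigWig binary IO
is not provided — the interchange formats are TSV, BED, bedGraph and
FASTA. Fragment-level coverage for paired-end data is not implemented
(the modelled libraries are single-end). The proximity statistic carries
no significance measure by design; resampling utilities in the test
suite show how one could be built if needed.
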