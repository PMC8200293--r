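# nascentr

Quantitative analysis of spike-in calibrated nascent RNA sequencing
(TT-seq) experiments, with a matching synthetic-data generator.

Standard RNA-seq normalization is *relative*: it rescales every sample so
that the typical gene looks unchanged, which silently erases genuinely
global shifts in transcription. TT-seq experiments work around this by
adding a fixed mass of labelled RNA from a second organism (e.g. a 90:10
mix of budding-yeast sample and fission-yeast spike-in) to every sample.
`nascentr` implements the analysis machinery such an experiment needs once
reads have been aligned and counted, for analysts studying global
transcriptional perturbations (heat shock, depletion of chromatin factors
such as condensin, medium shifts):

- **Median-of-ratios size factors** in two modes. For reference genes
  \(i\) with geometric mean \(g_i = (\prod_j K_{ij})^{1/m}\) across
  samples, the factor of sample \(j\) is
  \(s_j = \mathrm{median}_i \, K_{ij} / g_i\). *Internal* mode computes
  this over the target organism's genes (masking global shifts);
  *spike-in* mode uses only the fixed-mass spike-in genes (exposing
  them). Gene names matching configurable suffixes (`rRNA`, `RDN`) are
  excluded from the reference.
- **Global transcription ratio**: per sample, total target reads over
  total spike-in reads; condition-level medians quantify absolute up- or
  down-regulation.
- **Differential expression**: a simplified two-group negative-binomial
  Wald test on normalized counts (method-of-moments dispersion shared
  across genes), Benjamini–Hochberg FDR, and calls at an FDR threshold
  (default 0.05) plus a linear fold-change threshold (1.5- or 2-fold);
  one-sided Fisher/hypergeometric gene-set overlap tests.
- **Proximity association**: per gene, the distance to its nearest
  feature interval (e.g. condensin binding sites); the statistic is
  \(\mathrm{median}(d_{\text{significant}}) /
  \mathrm{median}(d_{\text{null}})\), with a zero-distance tally fallback
  when a median is 0. Values below 1 mean differential genes sit close to
  the feature set.
- **Multi-mapping repeat quantification**: expansion of each read over
  its best mapping locations with weight \(1/k\), and weighted,
  per-million-normalized counts over transposon-family intervals.
- **Metagene profiles**: per-base coverage, bedGraph IO, and
  scale-regions matrices (500 bp flanks, gene bodies rescaled to 1,000 bp,
  10 bp bins; 200 columns) with exact fractional-interval averaging.
- **TES base bias**: sense-strand adenine fraction in a ±100 bp window
  around transcription end sites, smoothed over a sliding 16 bp window —
  the sequence bias that 4-TU labelling imprints on nascent-RNA coverage.
- **Synthetic data**: a two-organism genome/count/alignment/sequence
  generator with recorded ground truth (true fold changes, global scale,
  site-linked genes, repeat-family abundances), so every statistic above
  can be exercised and validated by parameter recovery.

Everything is tibble-in/tibble-out and pipe-friendly; fitted results
carry `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Simulate a 600-gene target genome with a 150-gene spike-in catalogue,
three replicates per condition, a 2.6-fold global repression in the
treated condition, and 10% of genes truly differential, then analyse it:

```r
library(nascentr)
library(dplyr)

cfg <- sim_config(n_target_genes = 600, n_spikein_genes = 150,
                  n_feature_sites = 30, seed = 42,
                  families = c(Ty1 = 4, Ty2 = 2))
g  <- simulate_genome(cfg)
cc <- simulate_counts(g$annotation, g$truth, cfg)

global_transcription_ratio(cc$counts, g$annotation, cc$samples) |>
  transcription_ratio_summary()
#>   condition median_ratio n_samples
#> 1 control           8.65         3
#> 2 treated           4.09         3
```

The target:spike-in read ratio drops from 8.65 to 4.09 — the simulated
global repression is visible because the spike-in mass is constant
(8.65 / 4.09 ≈ 2.1; the quotient recovers the configured 2.6 exactly
when no asymmetric differential genes are simulated on top of it).

```r
sf <- size_factors(cc$counts, g$annotation, mode = "internal")
target_counts <- semi_join(cc$counts,
                           filter(g$annotation, organism == "target"),
                           by = "gene_id")
de <- de_test(target_counts, cc$samples$condition, "treated", "control",
              s = sf, fc_threshold = 1.5)
glance(de)
#>   n_genes n_tested n_up n_down fdr_threshold fc_threshold
#> 1     606      606   31     27          0.05          1.5
```

Internal normalization hides the global shift, so the 58 called genes are
the relatively differential ones (60 were simulated). Are they spatially
linked to the feature sites?

```r
genes  <- filter(g$annotation, organism == "target",
                 biotype == "protein_coding")
called <- intersect(de$gene_id[de$status != "ns"], genes$gene_id)
proximity_association(genes, called, g$feature_sites) |>
  select(median_sig, median_null, ratio, fallback_used)
#>   median_sig median_null  ratio fallback_used
#> 1       1445      41960. 0.0344 FALSE
```

Called genes sit a median 1.4 kb from their nearest site versus 42 kb
for unchanged genes — a proximity association of 0.03 (the generator
placed 80% of true differential genes within 2 kb of a site). `autoplot()`
on the `de` object, on metagene profiles and on TES base-bias profiles
produces the corresponding figures, and `run_pipeline(run_config(...))`
executes every stage end to end into a results directory with a manifest
and log.

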