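test_that("generators are pure functions of the seed", {
  cfg <- quick_config(seed = 11)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)
  c1 <- simulate_counts(g1$annotation, g1$truth, cfg)
  c2 <- simulate_counts(g2$annotation, g2$truth, cfg)
  expect_identical(c1, c2)
  s1 <- simulate_sequences(g1$annotation, TRUE, cfg)
  s2 <- simulate_sequences(g2$annotation, TRUE, cfg)
  expect_identical(as.character(s1), as.character(s2))
})

test_that("full proximity enrichment places every true-DE gene near a site", {
  cfg <- quick_config(seed = 5, proximity_enrichment = 1)
  g <- simulate_genome(cfg)
  de <- g$annotation[g$annotation$gene_id %in% g$truth$true_de$gene_id, ]
  d <- nearest_distance(de, g$feature_sites)
  expect_true(all(d$distance <= cfg$proximity_distance))
})

test_that("no enrichment leaves DE and non-DE genes equally far from sites", {
  # Monte-Carlo over 20 seeds: the ratio of partition medians hovers near 1
  ratios <- vapply(1:20, function(s) {
    cfg <- quick_config(seed = 400 + s, proximity_enrichment = 0)
    g <- simulate_genome(cfg)
    genes <- g$annotation[g$annotation$biotype == "protein_coding" &
                            g$annotation$organism == "target", ]
    proximity_association(genes, g$truth$true_de$gene_id,
                          g$feature_sites)$ratio
  }, numeric(1))
  expect_gt(median(ratios), 0.7)
  expect_lt(median(ratios), 1.4)
})

test_that("overfull genomes are rejected", {
  cfg <- quick_config(seed = 1, chrom_length = 1000)
  expect_error(simulate_genome(cfg), "capacity")
})

test_that("genes never overlap within a chromosome", {
  g <- simulate_genome(quick_config(seed = 9))
  by_chrom <- split(g$annotation, g$annotation$chrom)
  for (tbl in by_chrom) {
    tbl <- tbl[order(tbl$start), ]
    if (nrow(tbl) > 1) {
      expect_true(all(tbl$start[-1] >= tbl$end[-nrow(tbl)]))
    }
  }
})

test_that("null configuration produces no expected difference between conditions", {
  cfg <- quick_config(seed = 21, de_fraction = 0,
                      global_scale = c(control = 1, treated = 1),
                      depth_sdlog = 0, n_samples_per_condition = 10)
  g <- simulate_genome(cfg)
  cc <- simulate_counts(g$annotation, g$truth, cfg)
  m <- as.matrix(cc$counts[-1])
  grp <- cc$samples$condition
  ratio <- sum(m[, grp == "treated"]) / sum(m[, grp == "control"])
  expect_equal(ratio, 1, tolerance = 0.02)
})

test_that("spike-in counts take about a tenth of each library", {
  cfg <- quick_config(seed = 22, global_scale = c(control = 1, treated = 1))
  g <- simulate_genome(cfg)
  cc <- simulate_counts(g$annotation, g$truth, cfg)
  m <- as.matrix(cc$counts[-1])
  spike <- g$annotation$organism[match(cc$counts$gene_id,
                                       g$annotation$gene_id)] == "spikein"
  frac <- colSums(m[spike, ]) / colSums(m)
  expect_true(all(abs(frac - 0.10) < 0.02))
})

test_that("zero dispersion degrades to Poisson draws", {
  cfg <- quick_config(seed = 23, n_target_genes = 1200, nb_dispersion = 0,
                      depth_sdlog = 0, de_fraction = 0,
                      global_scale = c(control = 1, treated = 1),
                      n_samples_per_condition = 12)
  g <- simulate_genome(cfg)
  cc <- simulate_counts(g$annotation, g$truth, cfg)
  m <- as.matrix(cc$counts[-1])
  vm <- apply(m, 1, var) / pmax(rowMeans(m), 1e-9)
  # variance/mean ratio concentrates on 1 across >= 1,000 genes
  expect_equal(mean(vm), 1, tolerance = 0.05)
})

test_that("multi-mapping reads land on every family copy", {
  cfg <- quick_config(seed = 31)
  g <- simulate_genome(cfg)
  fams <- family_intervals(g$annotation)
  aln <- simulate_multimap_reads(fams, c(TyA = 2, TyB = 1), 400, cfg)
  locs_per_read <- table(aln$read_id)
  # TyA has 3 copies, TyB is single-copy
  expect_true(all(locs_per_read %in% c(1, 3)))
  one_primary <- tapply(aln$is_primary, aln$read_id, sum)
  expect_true(all(one_primary == 1))
  expect_error(simulate_multimap_reads(fams, c(TyA = 0, TyB = 0), 10, cfg),
               "zero")
})

test_that("weighted family counts recover a 2:1 abundance ratio", {
  ratios <- vapply(1:5, function(s) {
    cfg <- quick_config(seed = 31 + s)
    g <- simulate_genome(cfg)
    fams <- family_intervals(g$annotation)
    aln <- simulate_multimap_reads(fams, c(TyA = 2, TyB = 1), 10000, cfg)
    ex <- expand_alignments(filter_alignments(aln, max_mismatches = 2))
    wc <- weighted_feature_counts(ex, fams)
    by_fam <- tapply(wc$raw_weighted_count, fams$family, sum)
    unname(by_fam[["TyA"]] / by_fam[["TyB"]])
  }, numeric(1))
  expect_equal(mean(ratios), 2, tolerance = 0.05)
})

test_that("simulated sequences carry adenine bias only when asked", {
  cfg <- quick_config(seed = 41, n_target_genes = 150)
  g <- simulate_genome(cfg)
  genes <- g$annotation[g$annotation$organism == "target", ]
  flat <- base_fraction_window(simulate_sequences(genes, FALSE, cfg,
                                                  attr(g$annotation, "chrom_sizes")),
                               genes, "A", window = 60)
  expect_equal(mean(flat$raw), 0.25, tolerance = 0.03)
  rich <- base_fraction_window(simulate_sequences(genes, TRUE, cfg,
                                                  attr(g$annotation, "chrom_sizes")),
                               genes, "A", window = 60)
  expect_gt(mean(rich$raw[rich$offset >= 0 & rich$offset < 50]),
            mean(rich$raw[rich$offset < 0]) + 0.1)
})
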