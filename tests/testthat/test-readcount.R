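test_that("alignment filtering drops high-mismatch, non-unique and secondary hits", {
  aln <- dplyr::bind_rows(
    aln_row("r1", "chrI", 0, 76, mismatches = 0),
    aln_row("r1", "chrI", 500, 576, mismatches = 3, is_primary = FALSE),
    aln_row("r2", "chrI", 50, 126, mismatches = 1),
    aln_row("r2", "chrI", 700, 776, mismatches = 1, is_primary = FALSE))
  f <- filter_alignments(aln, max_mismatches = 2)
  expect_equal(nrow(f), 3)          # r1's 3-mismatch location removed
  expect_false(any(f$mismatches > 2))

  fu <- filter_alignments(aln, max_mismatches = 2, require_unique = TRUE)
  expect_equal(fu$read_id, "r1")     # r2 still had 2 locations -> dropped

  fp <- filter_alignments(aln, require_primary = TRUE)
  expect_true(all(fp$is_primary))

  empty <- aln[0, ]
  expect_equal(nrow(filter_alignments(empty)), 0)
})

test_that("gene counting honours the reverse-stranded rule", {
  genes <- gene_tbl("g1", "chrI", 100, 1000, strand = "+")
  minus_read <- aln_row("r1", "chrI", 200, 276, strand = "-")
  plus_read <- aln_row("r2", "chrI", 200, 276, strand = "+")
  expect_equal(count_reads_per_gene(minus_read, genes, "reverse")$count, 1L)
  expect_equal(count_reads_per_gene(plus_read, genes, "reverse")$count, 0L)
  expect_equal(count_reads_per_gene(plus_read, genes, "forward")$count, 1L)
  expect_equal(count_reads_per_gene(plus_read, genes, "unstranded")$count, 1L)
})

test_that("multi-overlap counting matches brute-force enumeration on a toy annotation", {
  genes <- gene_tbl(c("a", "b", "c"), "chrI", c(0, 50, 400), c(100, 150, 500),
                    strand = c("+", "+", "-"))
  reads <- dplyr::bind_rows(
    aln_row("r1", "chrI", 60, 90, strand = "-"),   # overlaps a and b
    aln_row("r2", "chrI", 420, 470, strand = "+"), # overlaps c
    aln_row("r3", "chrI", 200, 276, strand = "-")) # overlaps nothing
  got <- count_reads_per_gene(reads, genes, "reverse",
                              allow_multioverlap = TRUE)
  # brute force: every (read, gene) pair, >= 1 bp overlap + opposite strand
  brute <- vapply(seq_len(nrow(genes)), function(j) {
    sum(vapply(seq_len(nrow(reads)), function(i) {
      reads$start[i] < genes$end[j] && reads$end[i] > genes$start[j] &&
        reads$strand[i] != genes$strand[j]
    }, logical(1)))
  }, numeric(1))
  expect_equal(got$count, as.integer(brute))
  expect_equal(sum(got$count), 3L)  # r1 counted twice

  no_multi <- count_reads_per_gene(reads, genes, "reverse",
                                   allow_multioverlap = FALSE)
  expect_equal(no_multi$count, c(0L, 0L, 1L))

  multi_loc <- dplyr::bind_rows(aln_row("r1", "chrI", 0, 76),
                                aln_row("r1", "chrI", 99, 175,
                                        is_primary = FALSE))
  expect_error(count_reads_per_gene(multi_loc, genes), "filter")
})

test_that("expansion divides each read's mass equally over its best locations", {
  aln <- dplyr::bind_rows(
    aln_row("r1", "chrI", 0, 76),
    aln_row("r1", "chrII", 0, 76, is_primary = FALSE),
    aln_row("r1", "chrIII", 0, 76, is_primary = FALSE),
    aln_row("r2", "chrI", 500, 576))
  ex <- expand_alignments(aln)
  expect_equal(ex$weight[ex$read_id == "r1"], rep(1 / 3, 3))
  expect_equal(ex$weight[ex$read_id == "r2"], 1)
  expect_equal(ex$n_locations[ex$read_id == "r1"], rep(3L, 3))

  # only locations tied at the read's minimum mismatch count are kept
  tied <- dplyr::bind_rows(
    aln_row("r1", "chrI", 0, 76, mismatches = 0),
    aln_row("r1", "chrII", 0, 76, mismatches = 1, is_primary = FALSE))
  expect_equal(expand_alignments(tied)$weight, 1)
  expect_equal(nrow(expand_alignments(tied, best_only = FALSE)), 2)

  expect_error(expand_alignments(aln[0, ]), "empty")
})

test_that("expanded weight mass always equals the read count", {
  ks <- c(1, 2, 2, 4, 10)
  aln <- dplyr::bind_rows(lapply(seq_along(ks), function(i) {
    dplyr::bind_rows(lapply(seq_len(ks[i]), function(j) {
      aln_row(paste0("r", i), paste0("chr", j), i * 100, i * 100 + 76,
              is_primary = j == 1)
    }))
  }))
  ex <- expand_alignments(aln)
  expect_equal(sum(ex$weight), 5)
  expect_equal(nrow(ex), sum(ks))
})

test_that("weighted feature counts follow the equal-division rule", {
  feat <- iv("chrI", 1000, 2000, name = "F")
  both_in <- expand_alignments(dplyr::bind_rows(
    aln_row("r1", "chrI", 1100, 1176),
    aln_row("r1", "chrI", 1500, 1576, is_primary = FALSE)))
  expect_equal(weighted_feature_counts(both_in, feat)$raw_weighted_count, 1)

  one_in <- expand_alignments(dplyr::bind_rows(
    aln_row("r1", "chrI", 1100, 1176),
    aln_row("r1", "chrI", 5000, 5076, is_primary = FALSE)))
  expect_equal(weighted_feature_counts(one_in, feat)$raw_weighted_count, 0.5)
  expect_equal(weighted_feature_counts(one_in, feat,
                                       total_mapped_reads = 1500000)$per_million,
               0.5 * 1e6 / 1500000)

  # direct arithmetic: raw 3.0 at 1.5M mapped reads -> 2.0 per million
  three <- expand_alignments(dplyr::bind_rows(lapply(1:3, function(i) {
    aln_row(paste0("r", i), "chrI", 1200, 1276)
  })))
  expect_equal(weighted_feature_counts(three, feat, 1500000)$per_million, 2)

  expect_error(weighted_feature_counts(both_in, feat, 0), "positive")
})

test_that("weighted counting agrees exactly with per-read enumeration", {
  withr::local_seed(77)
  for (rep in 1:5) {
    n_reads <- sample(20:100, 1)
    aln <- dplyr::bind_rows(lapply(seq_len(n_reads), function(i) {
      k <- sample(1:4, 1)
      starts <- sample(0:3000, k)
      dplyr::bind_rows(lapply(seq_len(k), function(j) {
        aln_row(paste0("r", i), sample(c("chrI", "chrII"), 1), starts[j],
                starts[j] + 76, is_primary = j == 1)
      }))
    }))
    feats <- iv(sample(c("chrI", "chrII"), 8, replace = TRUE),
                seq(0, 2800, by = 400), seq(0, 2800, by = 400) + 300,
                name = paste0("f", 1:8))
    ex <- expand_alignments(aln)
    got <- weighted_feature_counts(ex, feats)
    expect_equal(got$raw_weighted_count, oracle_weighted_counts(ex, feats))
    expect_equal(sum(ex$weight), n_reads)
  }
})
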