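ann2 <- function(counts, organism = "target") {
  tibble::tibble(gene_id = counts$gene_id, organism = organism)
}

test_that("size factors reproduce hand-computed median-of-ratios values", {
  sym <- tibble::tibble(gene_id = c("g1", "g2"), A = c(5, 9), B = c(5, 9))
  expect_equal(size_factors(sym, ann2(sym))$size_factor, c(1, 1))

  doubled <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                            A = c(10, 20, 30), B = c(20, 40, 60))
  sf <- size_factors(doubled, ann2(doubled))
  expect_equal(sf$size_factor, c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(attr(sf, "reference_gene_count"), 3L)

  # gene with a zero is excluded; a single surviving reference gene pins s_j
  zero <- tibble::tibble(gene_id = c("g1", "g2"), A = c(0, 10), B = c(5, 10))
  expect_equal(size_factors(zero, ann2(zero))$size_factor, c(1, 1))
  expect_equal(attr(size_factors(zero, ann2(zero)), "reference_gene_count"), 1L)
})

test_that("size factors fail informatively without usable reference genes", {
  allz <- tibble::tibble(gene_id = c("g1", "g2"), A = c(0, 3), B = c(4, 0))
  expect_error(size_factors(allz, ann2(allz)), "zero count")
  rrna <- tibble::tibble(gene_id = c("x_rRNA", "RDN"), A = c(5, 6), B = c(5, 6))
  expect_error(size_factors(rrna, ann2(rrna)), "excluded")
})

test_that("name exclusion removes reference genes but not normalized output", {
  counts <- tibble::tibble(gene_id = c("g1", "g2", "big_rRNA"),
                           A = c(10, 10, 1000), B = c(10, 10, 4000))
  sf <- size_factors(counts, ann2(counts))
  expect_equal(sf$size_factor, c(1, 1))          # the rRNA gene cannot skew
  norm <- normalize_counts(counts, sf)
  expect_equal(nrow(norm), 3)                    # but it is still normalized
})

test_that("spike-in mode uses only spike-in genes as reference", {
  counts <- tibble::tibble(gene_id = c("t1", "t2", "sp1", "sp2"),
                           A = c(100, 200, 10, 20), B = c(50, 100, 10, 20))
  ann <- tibble::tibble(gene_id = counts$gene_id,
                        organism = c("target", "target", "spikein", "spikein"))
  expect_equal(size_factors(counts, ann, mode = "spikein")$size_factor,
               c(1, 1))
  expect_equal(size_factors(counts, ann, mode = "internal")$size_factor,
               c(sqrt(2), 1 / sqrt(2)), tolerance = 1e-12)
})

test_that("size factors agree with the brute-force oracle and DESeq2", {
  withr::local_seed(42)
  for (rep in 1:4) {
    m <- matrix(rpois(50 * 6, lambda = 40), nrow = 50)
    m[sample(50, 9), sample(6, 1)] <- 0  # odd reference count: 41 genes
    counts <- dplyr::bind_cols(
      tibble::tibble(gene_id = paste0("g", 1:50)),
      tibble::as_tibble(as.data.frame(m), .name_repair = ~ paste0("s", 1:6)))
    sf <- size_factors(counts, ann2(counts))
    expect_equal(sf$size_factor, oracle_size_factors(m), tolerance = 1e-12)
    # DESeq2 takes the median on the log-ratio scale; with an odd number of
    # reference genes the two medians coincide and the agreement is exact
    expect_equal(sf$size_factor,
                 unname(DESeq2::estimateSizeFactorsForMatrix(m)),
                 tolerance = 1e-10)
  }
})

test_that("scaling one sample's counts scales its relative size factor exactly", {
  withr::local_seed(3)
  counts <- tibble::tibble(gene_id = paste0("g", 1:20),
                           A = rpois(20, 60) + 1, B = rpois(20, 60) + 1,
                           C = rpois(20, 60) + 1)
  sf <- size_factors(counts, ann2(counts))$size_factor
  scaled <- dplyr::mutate(counts, B = B * 3)
  sf2 <- size_factors(scaled, ann2(scaled))$size_factor
  # the geometric-mean reference absorbs c^(1/n), so equivariance is exact
  # on factor ratios between samples
  expect_equal(sf2[2] / sf2[1], 3 * sf[2] / sf[1], tolerance = 1e-12)
  expect_equal(sf2[2] / sf2[3], 3 * sf[2] / sf[3], tolerance = 1e-12)
  expect_equal(sf2[3] / sf2[1], sf[3] / sf[1], tolerance = 1e-12)
})

test_that("internal normalization masks global shifts while spike-in exposes them", {
  withr::local_seed(7)
  counts <- tibble::tibble(
    gene_id = c(paste0("t", 1:30), paste0("sp", 1:10)),
    A = c(rpois(30, 100) + 1, rpois(10, 50) + 1),
    B = c(rpois(30, 100) + 1, rpois(10, 50) + 1))
  ann <- tibble::tibble(gene_id = counts$gene_id,
                        organism = rep(c("target", "spikein"), c(30, 10)))
  shifted <- counts
  shifted$B[1:30] <- shifted$B[1:30] * 4  # uniform 4x on sample B's targets

  # the geometric-mean reference absorbs 4^(1/n) into every factor, so the
  # masking/exposure contrast is exact on between-sample normalized ratios
  int0 <- normalize_counts(counts, size_factors(counts, ann, "internal"))
  int1 <- normalize_counts(shifted, size_factors(shifted, ann, "internal"))
  expect_equal(int1$B[1:30] / int1$A[1:30], int0$B[1:30] / int0$A[1:30],
               tolerance = 1e-12)

  spk0 <- normalize_counts(counts, size_factors(counts, ann, "spikein"))
  spk1 <- normalize_counts(shifted, size_factors(shifted, ann, "spikein"))
  expect_equal(spk1$B[1:30] / spk1$A[1:30], 4 * spk0$B[1:30] / spk0$A[1:30],
               tolerance = 1e-12)
})

test_that("normalize_counts divides by the factors and checks dimensions", {
  counts <- tibble::tibble(gene_id = "g1", A = 10, B = 10)
  expect_equal(normalize_counts(counts, c(A = 1, B = 1)), counts)
  expect_equal(normalize_counts(counts, c(A = 2, B = 0.5))$A, 5)
  expect_error(normalize_counts(counts, c(A = 1)), "no size factor")
  expect_error(normalize_counts(counts, c(A = -1, B = 1)), "positive")
})

test_that("coverage scaling multiplies by the reciprocal factor", {
  tr <- coverage_track(list(chrI = c(4, 0, 2)))
  expect_equal(scale_coverage(tr, 1)$coverage$chrI, c(4, 0, 2))
  s <- scale_coverage(tr, 2)
  expect_equal(s$coverage$chrI, c(2, 0, 1))
  expect_equal(s$scale, 0.5)
  expect_error(scale_coverage(tr, 0), "positive")
})

test_that("global transcription ratio divides target by spike-in tallies", {
  counts <- tibble::tibble(gene_id = c("t1", "sp1"),
                           A = c(9e6, 1e6), B = c(5, 5))
  ann <- tibble::tibble(gene_id = c("t1", "sp1"),
                        organism = c("target", "spikein"))
  r <- global_transcription_ratio(counts, ann)
  expect_equal(r$ratio, c(9, 1))
  zero <- tibble::tibble(gene_id = c("t1", "sp1"), A = c(10, 0))
  expect_error(global_transcription_ratio(zero, ann), "undefined")
})

test_that("condition summaries report the median replicate ratio", {
  counts <- tibble::tibble(gene_id = c("t1", "sp1"),
                           a1 = c(10, 10), a2 = c(30, 10), a3 = c(20, 10),
                           b1 = c(5, 10), b2 = c(5, 10), b3 = c(50, 10))
  ann <- tibble::tibble(gene_id = c("t1", "sp1"),
                        organism = c("target", "spikein"))
  samples <- tibble::tibble(sample = c("a1", "a2", "a3", "b1", "b2", "b3"),
                            condition = rep(c("ctl", "trt"), each = 3))
  s <- transcription_ratio_summary(
    global_transcription_ratio(counts, ann, samples))
  expect_equal(s$median_ratio[s$condition == "ctl"], 2)
  expect_equal(s$median_ratio[s$condition == "trt"], 0.5)
})
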