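# Brute-force oracles and small fixture builders used across the suite.
# Every oracle deliberately re-derives its quantity from first principles,
# independent of the package's implementation path.

aln_row <- function(read_id, chrom, start, end, strand = "+",
                    mismatches = 0L, is_primary = TRUE) {
  tibble::tibble(read_id = read_id, chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand,
                 mismatches = as.integer(mismatches),
                 is_primary = is_primary)
}

iv <- function(chrom, start, end, name = NA_character_, strand = ".") {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand, name = name)
}

gene_tbl <- function(gene_id, chrom, start, end, strand = "+",
                     organism = "target", biotype = "protein_coding",
                     family = NA_character_) {
  tibble::tibble(gene_id = gene_id, chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand, organism = organism,
                 biotype = biotype, family = family)
}

# All-pairs nearest distance: gap between interval boundaries, 0 on overlap,
# NA when the query's chromosome has no feature.
oracle_nearest <- function(queries, features) {
  vapply(seq_len(nrow(queries)), function(i) {
    f <- features[features$chrom == queries$chrom[i], ]
    if (nrow(f) == 0) return(NA_real_)
    gaps <- vapply(seq_len(nrow(f)), function(j) {
      if (queries$start[i] < f$end[j] && queries$end[i] > f$start[j]) 0
      else if (queries$end[i] <= f$start[j]) f$start[j] - queries$end[i]
      else queries$start[i] - f$end[j]
    }, numeric(1))
    min(gaps)
  }, numeric(1))
}

# Explicit median-of-ratios on a plain matrix: geometric means over genes
# with no zero anywhere, then per-sample median of count / geomean.
oracle_size_factors <- function(m) {
  keep <- apply(m, 1, function(r) all(r > 0))
  m <- m[keep, , drop = FALSE]
  geo <- apply(m, 1, function(r) prod(r)^(1 / length(r)))
  vapply(seq_len(ncol(m)), function(j) median(m[, j] / geo), numeric(1))
}

# Per-read enumeration of (location, feature) overlaps accumulating 1/k.
oracle_weighted_counts <- function(expanded, features) {
  out <- numeric(nrow(features))
  for (i in seq_len(nrow(expanded))) {
    for (j in seq_len(nrow(features))) {
      if (expanded$chrom[i] == features$chrom[j] &&
          expanded$start[i] < features$end[j] &&
          expanded$end[i] > features$start[j]) {
        out[j] <- out[j] + expanded$weight[i]
      }
    }
  }
  out
}

# Fractional-interval averaging of per-base coverage for one gene row of a
# scale-regions matrix, done position by position.
oracle_scale_regions_row <- function(cov, start, end, strand,
                                     body_length = 1000, flank = 500,
                                     bin_size = 10) {
  L <- end - start
  n_flank <- flank / bin_size
  n_body <- body_length / bin_size
  base_mean <- function(a, b) {
    # exact mean over real interval [a, b): each base [i, i+1) contributes
    # its overlap length as weight; positions off the chromosome count as 0
    i <- floor(a):ceiling(b)
    w <- pmax(0, pmin(b, i + 1) - pmax(a, i))
    v <- numeric(length(i))
    ok <- i >= 0 & i < length(cov)
    v[ok] <- cov[i[ok] + 1]
    sum(w * v) / (b - a)
  }
  if (strand == "+") {
    up <- vapply(seq_len(n_flank) - 1, function(k) {
      base_mean(start - flank + k * bin_size, start - flank + (k + 1) * bin_size)
    }, numeric(1))
    body <- vapply(seq_len(n_body) - 1, function(k) {
      base_mean(start + k * L / n_body, start + (k + 1) * L / n_body)
    }, numeric(1))
    down <- vapply(seq_len(n_flank) - 1, function(k) {
      base_mean(end + k * bin_size, end + (k + 1) * bin_size)
    }, numeric(1))
  } else {
    up <- vapply(seq_len(n_flank) - 1, function(k) {
      base_mean(end + flank - (k + 1) * bin_size, end + flank - k * bin_size)
    }, numeric(1))
    body <- vapply(seq_len(n_body) - 1, function(k) {
      base_mean(end - (k + 1) * L / n_body, end - k * L / n_body)
    }, numeric(1))
    down <- vapply(seq_len(n_flank) - 1, function(k) {
      base_mean(start - (k + 1) * bin_size, start - k * bin_size)
    }, numeric(1))
  }
  c(up, body, down)
}

# One-sided hypergeometric enrichment tail from binomial coefficients only.
oracle_hyper_tail <- function(n_a, n_b, k, universe) {
  js <- k:min(n_a, n_b)
  sum(choose(n_a, js) * choose(universe - n_a, n_b - js)) /
    choose(universe, n_b)
}

# A small, quick simulation configuration for integration-style tests.
quick_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_target_genes = 300, n_spikein_genes = 80, n_feature_sites = 20,
         families = c(TyA = 3, TyB = 1), seed = seed),
    list(...))
  do.call(sim_config, args)
}
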