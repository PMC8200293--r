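#' Base fraction around transcription end sites
#'
#' For every offset o in `[-window, window)` relative to the TES, the
#' fraction of genes whose sense-strand base at TES + o equals `base`.
#' Offset 0 is the first base downstream of the gene end; negative offsets
#' lie inside the gene. Minus-strand genes are read on the reverse
#' complement with offsets oriented downstream-positive. Positions off a
#' chromosome end are excluded from both numerator and denominator at that
#' offset.
#'
#' @param genome A [Biostrings::DNAStringSet] (or named character vector of
#'   chromosome sequences).
#' @param annotation Annotation tibble; every gene's chromosome must be
#'   present in `genome`.
#' @param base One of `"A"`, `"C"`, `"G"`, `"T"`.
#' @param window Half-window in bp (default 100).
#' @param smooth_window Width of the sliding mean applied for the
#'   `smoothed` column (default 16).
#' @return Tibble of class `tt_base_profile` with `offset`, `raw`,
#'   `smoothed`, `n_genes`.
#' @export
base_fraction_window <- function(genome, annotation, base = "A",
                                 window = 100, smooth_window = 16) {
  if (!base %in% c("A", "C", "G", "T")) {
    stop_data("`base` must be one of A, C, G, T")
  }
  seqs <- if (inherits(genome, "DNAStringSet")) {
    setNames(as.character(genome), names(genome))
  } else genome
  miss <- setdiff(unique(annotation$chrom), names(seqs))
  if (length(miss) > 0) stop_data("genome lacks chromosome: ", miss[1])
  chrom_len <- setNames(nchar(seqs), names(seqs))
  offsets <- seq(-window, window - 1)
  plus <- annotation$strand == "+"
  tes <- ifelse(plus, annotation$end, annotation$start)  # 0-based boundary
  L <- chrom_len[annotation$chrom]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  raw <- numeric(length(offsets))
  n_used <- integer(length(offsets))
  seq_of_gene <- seqs[annotation$chrom]
  for (k in seq_along(offsets)) {
    o <- offsets[k]
    # 0-based reference position of sense-strand offset o
    pos <- ifelse(plus, tes + o, tes - 1 - o)
    ok <- pos >= 0 & pos < L
    b <- substr(seq_of_gene[ok], pos[ok] + 1, pos[ok] + 1)
    b <- ifelse(plus[ok], b, comp[b])
    n_used[k] <- sum(ok)
    raw[k] <- if (n_used[k] > 0) mean(b == base) else NA_real_
  }
  structure(
    tibble(offset = offsets, raw = raw,
           smoothed = sliding_smooth(raw, min(smooth_window,
                                              length(offsets))),
           n_genes = n_used),
    base = base,
    class = c("tt_base_profile", class(tibble())))
}

#' Centered sliding-window mean
#'
#' Moving average of width `window`. For even widths the window has no
#' center; the convention here places the window at offsets
#' `-window/2 .. window/2 - 1` around each position. At the edges the
#' window is truncated and the mean renormalized over the positions that
#' exist.
#'
#' @param values Numeric vector.
#' @param window Window width (1 to `length(values)`).
#' @return Smoothed vector of the same length.
#' @export
sliding_smooth <- function(values, window = 16) {
  n <- length(values)
  if (window < 1 || window > n) {
    stop_data("`window` must be between 1 and length(values)")
  }
  lo_off <- -floor(window / 2)
  hi_off <- lo_off + window - 1
  vapply(seq_len(n), function(i) {
    idx <- max(1, i + lo_off):min(n, i + hi_off)
    mean(values[idx], na.rm = TRUE)
  }, numeric(1))
}
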