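#' Per-base coverage from unique alignments
#'
#' Builds a per-base depth track from single-location reads, optionally
#' restricted to one read strand (strand-split tracks are the norm for
#' stranded nascent-RNA libraries).
#'
#' @param alignments Alignment tibble (filtered, one location per read).
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param strand `"+"`, `"-"` or `"."` (both).
#' @return A [coverage_track()].
#' @export
coverage_from_alignments <- function(alignments, chrom_sizes, strand = ".") {
  if (!strand %in% c("+", "-", ".")) stop_data("invalid strand selector")
  if (nrow(alignments) > 0) check_alignment_tbl(alignments)
  aln <- if (strand == ".") alignments else
    alignments[alignments$strand == strand, ]
  cov <- lapply(chrom_sizes, function(L) numeric(L))
  for (ch in unique(aln$chrom)) {
    if (!ch %in% names(chrom_sizes)) {
      stop_data("alignment on unknown chromosome: ", ch)
    }
    a <- aln[aln$chrom == ch, ]
    L <- chrom_sizes[[ch]]
    if (any(a$end > L)) stop_data("alignment beyond end of ", ch)
    # diff-accumulate: +1 at start, -1 at end, cumulative sum gives depth
    delta <- numeric(L + 1L)
    tb <- table(a$start + 1L)
    delta[as.integer(names(tb))] <- delta[as.integer(names(tb))] + tb
    te <- table(a$end + 1L)
    delta[as.integer(names(te))] <- delta[as.integer(names(te))] - te
    cov[[ch]] <- cumsum(delta)[seq_len(L)]
  }
  coverage_track(cov, strand = strand, scale = 1)
}

# Mean coverage over a real-valued genomic interval [a, b) with fractional
# end weighting; positions outside [0, L) contribute 0 but still count in
# the denominator (missing data as zero). `cs` is c(0, cumsum(coverage)).
frac_mean <- function(cs, a, b) {
  L <- length(cs) - 1L
  integral_to <- function(x) {
    x <- pmin(pmax(x, 0), L)
    i <- floor(x)
    base <- cs[i + 1L]
    frac <- x - i
    extra <- ifelse(frac > 0, (cs[pmin(i + 2L, L + 1L)] - cs[i + 1L]) * frac, 0)
    base + extra
  }
  (integral_to(b) - integral_to(a)) / (b - a)
}

#' Scale-regions coverage matrix
#'
#' For each gene, mean normalized coverage over a fixed bin grid: an
#' upstream flank, the gene body rescaled to a common length, and a
#' downstream flank (defaults: 500 bp flanks, 1,000 bp body, 10 bp bins =
#' 50 + 100 + 50 = 200 columns). Bins run upstream -> TSS -> body -> TES ->
#' downstream regardless of strand (minus-strand genes are mirrored). Body
#' bins average coverage over exact fractional genomic sub-intervals, so
#' genes shorter or longer than the body grid are handled without
#' resampling artefacts. Positions beyond chromosome ends contribute zero.
#'
#' @param track A [coverage_track()] (typically spike-in scaled).
#' @param annotation Annotation tibble (genes to profile).
#' @param body_length Common body length in bp (default 1000).
#' @param flank Flank length in bp on each side (default 500).
#' @param bin_size Bin width in bp; must divide `flank` and `body_length`.
#' @return A tibble of class `tt_coverage_matrix`: `gene_id` plus one
#'   numeric column per bin (`bin_001`, ...).
#' @export
scale_regions_matrix <- function(track, annotation, body_length = 1000,
                                 flank = 500, bin_size = 10) {
  stopifnot(inherits(track, "coverage_track"))
  if (flank %% bin_size != 0 || body_length %% bin_size != 0) {
    stop_data("bin_size must divide both flank and body_length")
  }
  n_flank <- flank / bin_size
  n_body <- body_length / bin_size
  n_bins <- 2 * n_flank + n_body
  cs_by_chrom <- lapply(track$coverage, function(v) c(0, cumsum(v)))
  rows <- matrix(0, nrow = nrow(annotation), ncol = n_bins)
  for (i in seq_len(nrow(annotation))) {
    ch <- annotation$chrom[i]
    if (!ch %in% names(cs_by_chrom)) {
      stop_data("gene on chromosome absent from track: ", ch)
    }
    cs <- cs_by_chrom[[ch]]
    s <- annotation$start[i]
    e <- annotation$end[i]
    L <- e - s
    if (annotation$strand[i] == "+") {
      up <- s - flank + bin_size * (seq_len(n_flank) - 1)
      body <- s + (L / n_body) * (seq_len(n_body) - 1)
      down <- e + bin_size * (seq_len(n_flank) - 1)
      starts <- c(up, body, down)
      widths <- c(rep(bin_size, n_flank), rep(L / n_body, n_body),
                  rep(bin_size, n_flank))
      rows[i, ] <- frac_mean(cs, starts, starts + widths)
    } else {
      # mirrored: bin 1 is the farthest upstream, i.e. highest coordinate
      up <- e + flank - bin_size * seq_len(n_flank)
      body <- e - (L / n_body) * seq_len(n_body)
      down <- s - bin_size * seq_len(n_flank)
      starts <- c(up, body, down)
      widths <- c(rep(bin_size, n_flank), rep(L / n_body, n_body),
                  rep(bin_size, n_flank))
      rows[i, ] <- frac_mean(cs, starts, starts + widths)
    }
  }
  colnames(rows) <- sprintf("bin_%03d", seq_len(n_bins))
  structure(
    dplyr::bind_cols(tibble(gene_id = annotation$gene_id), as_tibble(rows)),
    n_flank_bins = n_flank, n_body_bins = n_body, bin_size = bin_size,
    class = c("tt_coverage_matrix", class(tibble())))
}

#' Average metagene profile
#'
#' Column-wise mean (and median) of a scale-regions coverage matrix,
#' optionally pooled over replicate matrices of identical shape by
#' averaging them first.
#'
#' @param matrix A `tt_coverage_matrix`, or a list of them (replicates).
#' @return Tibble of class `tt_metagene_profile` with `bin`, `region`
#'   (`upstream` / `body` / `downstream`), `mean`, `median`.
#' @export
metagene_profile <- function(matrix) {
  mats <- if (inherits(matrix, "data.frame")) list(matrix) else matrix
  dims <- vapply(mats, function(m) ncol(m), integer(1))
  if (length(unique(dims)) != 1 ||
      length(unique(vapply(mats, nrow, integer(1)))) != 1) {
    stop_data("replicate matrices differ in shape")
  }
  vals <- lapply(mats, function(m) as.matrix(m[setdiff(names(m), "gene_id")]))
  pooled <- Reduce(`+`, vals) / length(vals)
  n_flank <- attr(mats[[1]], "n_flank_bins") %||% 50
  n_body <- attr(mats[[1]], "n_body_bins") %||% (ncol(pooled) - 2 * n_flank)
  region <- c(rep("upstream", n_flank), rep("body", n_body),
              rep("downstream", n_flank))
  structure(
    tibble(bin = seq_len(ncol(pooled)), region = region,
           mean = unname(colMeans(pooled)),
           median = unname(apply(pooled, 2, median))),
    n_flank_bins = n_flank, n_body_bins = n_body,
    class = c("tt_metagene_profile", class(tibble())))
}
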