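#' Median-of-ratios size factors
#'
#' Computes per-sample size factors by the median-of-ratios method over a
#' chosen reference gene set: `"internal"` uses the target organism's own
#' genes (which masks genuinely global expression shifts), `"spikein"` uses
#' only the fixed-mass spike-in organism's genes (which exposes them). For
#' each reference gene the geometric mean of its counts across samples is
#' taken (genes with a zero in any sample are excluded), and a sample's
#' factor is the median over genes of count / geometric mean. Genes whose
#' names end in one of `exclude_suffixes` (ribosomal RNA loci by default)
#' are removed from the reference before computation; they are still
#' normalized downstream.
#'
#' @param counts Counts tibble (`gene_id` + sample columns).
#' @param annotation Annotation tibble supplying each gene's `organism`.
#' @param mode `"internal"` (target genes) or `"spikein"` (spike-in genes).
#' @param exclude_suffixes Character vector of gene-name suffixes excluded
#'   from the reference set (default `c("rRNA", "RDN")`).
#' @return A tibble with columns `sample`, `size_factor`, of class
#'   `tt_size_factors`, carrying `mode` and `reference_gene_count`
#'   attributes.
#' @examples
#' counts <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
#'                          A = c(10, 20, 30), B = c(20, 40, 60))
#' ann <- tibble::tibble(gene_id = counts$gene_id, organism = "target")
#' size_factors(counts, ann, mode = "internal")
#' @export
size_factors <- function(counts, annotation,
                         mode = c("internal", "spikein"),
                         exclude_suffixes = c("rRNA", "RDN")) {
  mode <- match.arg(mode)
  check_counts_tbl(counts)
  wanted <- if (mode == "internal") "target" else "spikein"
  ref_ids <- annotation$gene_id[annotation$organism == wanted]
  if (length(exclude_suffixes) > 0) {
    excl <- Reduce(`|`, lapply(exclude_suffixes, function(s) {
      endsWith(ref_ids, s)
    }))
    ref_ids <- ref_ids[!excl]
  }
  if (length(ref_ids) == 0) {
    stop_data("no eligible reference gene: all ", wanted,
              " genes were excluded by name")
  }
  m <- counts_matrix(counts)[counts$gene_id %in% ref_ids, , drop = FALSE]
  pos <- rowSums(m == 0) == 0
  if (!any(pos)) {
    stop_data("no eligible reference gene: every ", wanted,
              " reference gene contains a zero count")
  }
  m <- m[pos, , drop = FALSE]
  geo <- exp(rowMeans(log(m)))
  sf <- apply(m / geo, 2, median)
  structure(
    tibble(sample = colnames(m), size_factor = unname(sf)),
    mode = mode, reference_gene_count = nrow(m),
    class = c("tt_size_factors", class(tibble())))
}

sf_vector <- function(s, samples) {
  if (inherits(s, "data.frame")) {
    v <- setNames(s$size_factor, s$sample)
  } else if (!is.null(names(s))) {
    v <- s
  } else {
    stop_data("size factors must be a tt_size_factors table or named vector")
  }
  miss <- setdiff(samples, names(v))
  if (length(miss) > 0) {
    stop_data("no size factor for sample(s): ", paste(miss, collapse = ", "))
  }
  if (any(v <= 0)) stop_data("size factors must be positive")
  v[samples]
}

#' Normalize counts by size factors
#'
#' Divides every sample column by its size factor. The factors are applied
#' to all genes, regardless of which gene subset defined them.
#'
#' @param counts Counts tibble.
#' @param s Size factors ([size_factors()] result or named vector).
#' @return Tibble of normalized (real-valued) counts.
#' @export
normalize_counts <- function(counts, s) {
  check_counts_tbl(counts)
  smp <- sample_cols(counts)
  v <- sf_vector(s, smp)
  out <- counts
  for (j in smp) out[[j]] <- counts[[j]] / v[[j]]
  out
}

#' Scale a coverage track by a size factor
#'
#' Multiplies every per-base value by `1 / s_j`, matching the convention of
#' dividing counts by the size factor, and records the applied factor.
#'
#' @param track A [coverage_track()].
#' @param s_j A positive size factor.
#' @return The scaled [coverage_track()].
#' @export
scale_coverage <- function(track, s_j) {
  stopifnot(inherits(track, "coverage_track"))
  assert_scalar_number(s_j, "s_j")
  if (s_j <= 0) stop_data("size factor must be positive")
  coverage_track(lapply(track$coverage, function(v) v / s_j),
                 strand = track$strand, scale = track$scale / s_j)
}

#' Global transcription ratio (target vs spike-in reads)
#'
#' For each sample, the ratio of total target-organism reads to total
#' spike-in reads. Because the spike-in mass is constant across samples,
#' this ratio tracks absolute transcriptional output, and the quotient of
#' condition medians measures global up- or down-regulation that internal
#' normalization would mask.
#'
#' @param counts Counts tibble (or any per-gene read tally table).
#' @param annotation Annotation tibble supplying `organism` per gene.
#' @param samples Optional samples tibble (`sample`, `condition`) used to
#'   attach condition labels.
#' @return Tibble with `sample`, `target_reads`, `spikein_reads`, `ratio`
#'   (and `condition` if `samples` given).
#' @export
global_transcription_ratio <- function(counts, annotation, samples = NULL) {
  check_counts_tbl(counts)
  org <- setNames(annotation$organism, annotation$gene_id)
  miss <- setdiff(counts$gene_id, names(org))
  if (length(miss) > 0) stop_data("gene not in annotation: ", miss[1])
  m <- counts_matrix(counts)
  is_target <- org[counts$gene_id] == "target"
  out <- tibble(
    sample = colnames(m),
    target_reads = unname(colSums(m[is_target, , drop = FALSE])),
    spikein_reads = unname(colSums(m[!is_target, , drop = FALSE]))
  )
  if (any(out$spikein_reads == 0)) {
    stop_data("spike-in read tally is zero for sample '",
              out$sample[out$spikein_reads == 0][1],
              "'; the ratio is undefined")
  }
  out$ratio <- out$target_reads / out$spikein_reads
  if (!is.null(samples)) {
    out <- dplyr::left_join(out, samples, by = "sample")
  }
  out
}

#' Condition-level summary of global transcription ratios
#'
#' @param ratios Result of [global_transcription_ratio()] with a
#'   `condition` column.
#' @return Tibble with `condition`, `median_ratio`, `n_samples`.
#' @export
transcription_ratio_summary <- function(ratios) {
  if (!"condition" %in% names(ratios)) {
    stop_data("ratios lack a `condition` column; pass `samples` to ",
              "global_transcription_ratio()")
  }
  ratios |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(median_ratio = median(.data$ratio),
                     n_samples = dplyr::n(), .groups = "drop")
}
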