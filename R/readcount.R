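#' Filter candidate alignment locations
#'
#' Applies the standard nascent-RNA alignment filter: drop locations with
#' more than `max_mismatches` mismatches (default 2, i.e. fewer than three),
#' optionally keep only primary locations, and optionally drop reads that
#' still map to more than one location (unique mapping).
#'
#' @param alignments Alignment tibble (one row per location).
#' @param max_mismatches Maximum mismatches retained per location.
#' @param require_unique Drop reads retaining more than one location?
#' @param require_primary Keep only primary locations?
#' @return The filtered alignment tibble (possibly empty).
#' @export
filter_alignments <- function(alignments, max_mismatches = 2,
                              require_unique = FALSE,
                              require_primary = FALSE) {
  assert_scalar_number(max_mismatches, "max_mismatches", lower = 0)
  if (nrow(alignments) == 0) return(alignments)
  check_alignment_tbl(alignments)
  out <- alignments |> dplyr::filter(.data$mismatches <= max_mismatches)
  if (require_primary) out <- dplyr::filter(out, .data$is_primary)
  if (require_unique) {
    out <- out |>
      dplyr::group_by(.data$read_id) |>
      dplyr::filter(dplyr::n() == 1L) |>
      dplyr::ungroup()
  }
  out
}

#' Count uniquely mapped reads per gene
#'
#' Assigns each single-location read to every gene it overlaps by at least
#' 1 bp, subject to the library strand rule. `strandedness = "reverse"`
#' (the default protocol here) requires the read strand to be opposite the
#' gene strand; `"forward"` requires them equal; `"unstranded"` ignores
#' strand. With `allow_multioverlap` a read overlapping g genes increments
#' each of them; without it, reads overlapping more than one gene are
#' discarded as ambiguous.
#'
#' @param alignments Alignment tibble with exactly one location per read
#'   (filter first; multi-location reads are an error).
#' @param annotation Annotation tibble.
#' @param strandedness One of `"unstranded"`, `"forward"`, `"reverse"`.
#' @param allow_multioverlap Count reads into every overlapped gene?
#' @return Tibble with `gene_id` and integer `count`, in annotation order.
#' @export
count_reads_per_gene <- function(alignments, annotation,
                                 strandedness = c("reverse", "forward",
                                                  "unstranded"),
                                 allow_multioverlap = TRUE) {
  strandedness <- match.arg(strandedness)
  if (nrow(alignments) > 0) {
    check_alignment_tbl(alignments)
    if (anyDuplicated(alignments$read_id) > 0) {
      stop_data("multi-location read encountered; run filter_alignments(",
                "require_unique = TRUE) first")
    }
  }
  result <- tibble(gene_id = annotation$gene_id, count = 0L)
  if (nrow(alignments) == 0) return(result)
  hits <- GenomicRanges::findOverlaps(as_granges0(alignments),
                                      as_granges0(annotation),
                                      minoverlap = 1L)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  keep <- switch(strandedness,
    unstranded = rep(TRUE, length(qh)),
    forward = alignments$strand[qh] == annotation$strand[sh],
    reverse = alignments$strand[qh] != annotation$strand[sh]
  )
  qh <- qh[keep]; sh <- sh[keep]
  if (!allow_multioverlap && length(qh) > 0) {
    per_read <- table(qh)
    ambiguous <- as.integer(names(per_read)[per_read > 1])
    drop <- qh %in% ambiguous
    qh <- qh[!drop]; sh <- sh[!drop]
  }
  if (length(sh) > 0) {
    tab <- table(factor(sh, levels = seq_len(nrow(annotation))))
    result$count <- as.integer(tab)
  }
  result
}

#' Expand multi-mapping reads into a weighted alignment table
#'
#' For each read, keeps its best mapping locations (all locations tied at
#' the read's minimum mismatch count) and emits one row per location with
#' weight `1 / n_locations`, so each read contributes exactly one unit of
#' mass in total.
#'
#' @param alignments Alignment tibble (already mismatch-filtered as
#'   desired).
#' @param best_only Keep only locations tied at the read's minimum mismatch
#'   count (default) rather than all surviving locations.
#' @return Tibble with `read_id`, `chrom`, `start`, `end`, `strand`,
#'   `n_locations`, `weight`.
#' @export
expand_alignments <- function(alignments, best_only = TRUE) {
  if (nrow(alignments) == 0) {
    stop_data("cannot expand an empty alignment set")
  }
  check_alignment_tbl(alignments)
  out <- alignments
  if (best_only) {
    out <- out |>
      dplyr::group_by(.data$read_id) |>
      dplyr::filter(.data$mismatches == min(.data$mismatches)) |>
      dplyr::ungroup()
  }
  out |>
    dplyr::group_by(.data$read_id) |>
    dplyr::mutate(n_locations = dplyr::n(), weight = 1 / dplyr::n()) |>
    dplyr::ungroup() |>
    dplyr::select("read_id", "chrom", "start", "end", "strand",
                  "n_locations", "weight")
}

#' Weighted read counts over feature intervals
#'
#' Sums expanded-alignment weights over each feature a location overlaps by
#' at least 1 bp (strand-agnostic; a location overlapping several features
#' contributes its full weight to each). Also reports counts per million
#' mapped reads.
#'
#' @param expanded Expanded alignment table from [expand_alignments()].
#' @param features Interval tibble (e.g. transposon copies); a `name`
#'   column identifies features, else they are numbered.
#' @param total_mapped_reads Library size used for the per-million scaling;
#'   defaults to the number of distinct reads in `expanded`.
#' @return Tibble with `name`, `raw_weighted_count`, `per_million`.
#' @export
weighted_feature_counts <- function(expanded, features,
                                    total_mapped_reads = NULL) {
  check_interval_tbl(features, "feature")
  total_mapped_reads <- total_mapped_reads %||%
    dplyr::n_distinct(expanded$read_id)
  if (is.null(total_mapped_reads) || total_mapped_reads <= 0) {
    stop_data("total_mapped_reads must be positive")
  }
  nm <- features$name %||% as.character(seq_len(nrow(features)))
  result <- tibble(name = nm, raw_weighted_count = 0)
  if (nrow(expanded) > 0) {
    hits <- GenomicRanges::findOverlaps(as_granges0(expanded),
                                        as_granges0(features),
                                        minoverlap = 1L)
    if (length(hits) > 0) {
      acc <- tapply(expanded$weight[S4Vectors::queryHits(hits)],
                    factor(S4Vectors::subjectHits(hits),
                           levels = seq_len(nrow(features))),
                    sum, default = 0)
      result$raw_weighted_count <- as.numeric(acc)
    }
  }
  result$per_million <- result$raw_weighted_count * 1e6 / total_mapped_reads
  result
}
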