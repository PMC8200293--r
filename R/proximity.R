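#' Distance to the nearest feature
#'
#' For each query interval, the gap in bp to the closest feature interval
#' on the same chromosome (0 when they overlap by at least 1 bp);
#' strand-agnostic. Queries on chromosomes carrying no feature have no
#' defined distance: they get `NA` and their count is reported in the
#' `n_excluded` attribute.
#'
#' @param queries Interval tibble (e.g. gene bodies).
#' @param features Non-empty interval tibble (e.g. binding sites).
#' @return `queries` with an added `distance` column; attribute
#'   `n_excluded` counts queries on feature-free chromosomes.
#' @export
nearest_distance <- function(queries, features) {
  if (nrow(features) == 0) stop_data("empty feature set")
  check_interval_tbl(queries, "query")
  check_interval_tbl(features, "feature")
  out <- queries
  out$distance <- NA_real_
  if (nrow(queries) > 0) {
    hits <- GenomicRanges::distanceToNearest(as_granges0(queries),
                                             as_granges0(features),
                                             ignore.strand = TRUE)
    out$distance[S4Vectors::queryHits(hits)] <-
      as.numeric(S4Vectors::mcols(hits)$distance)
  }
  structure(out, n_excluded = sum(is.na(out$distance)))
}

#' Proximity ratio from two distance partitions
#'
#' Core of the proximity-association statistic: the ratio of the median
#' nearest-feature distance of significant genes to that of
#' non-significant genes. A value below 1 means the significant genes sit
#' closer to the feature set. When either median is zero (most genes of a
#' partition overlap a feature), the median is replaced by the
#' zero-distance tally: the fallback ratio is
#' `(zero fraction in null) / (zero fraction in significant)`, which
#' preserves the orientation (< 1 still means significant genes closer),
#' and `fallback_used` is set.
#'
#' @param dist_sig,dist_null Numeric distance vectors for the significant
#'   and null partitions (both non-empty; NAs dropped).
#' @param feature_set_name Label copied into the result.
#' @return One-row tibble: `feature_set`, `median_sig`, `median_null`,
#'   `ratio`, `fallback_used`, `n_sig`, `n_null`, `zero_tally_sig`,
#'   `zero_tally_null`.
#' @export
proximity_ratio <- function(dist_sig, dist_null,
                            feature_set_name = "features") {
  dist_sig <- dist_sig[!is.na(dist_sig)]
  dist_null <- dist_null[!is.na(dist_null)]
  if (length(dist_sig) == 0 || length(dist_null) == 0) {
    stop_data("both distance partitions must be non-empty")
  }
  med_s <- median(dist_sig)
  med_n <- median(dist_null)
  z_s <- sum(dist_sig == 0)
  z_n <- sum(dist_null == 0)
  fallback <- med_s == 0 || med_n == 0
  ratio <- if (fallback) {
    (z_n / length(dist_null)) / (z_s / length(dist_sig))
  } else {
    med_s / med_n
  }
  tibble(feature_set = feature_set_name,
         median_sig = med_s, median_null = med_n, ratio = ratio,
         fallback_used = fallback,
         n_sig = length(dist_sig), n_null = length(dist_null),
         zero_tally_sig = z_s, zero_tally_null = z_n)
}

#' Proximity association between differential genes and a feature set
#'
#' Computes each gene's distance to its nearest feature, bi-partitions the
#' genes into significant and null (all remaining) sets, and forms the
#' ratio of the partition medians (see [proximity_ratio()] for the
#' zero-median fallback). Genes on chromosomes without any feature are
#' excluded from both partitions symmetrically.
#'
#' @param annotation Annotation tibble of all genes considered.
#' @param sig_genes Character vector of significant gene ids (must be a
#'   subset of `annotation$gene_id`).
#' @param features Feature interval tibble.
#' @param feature_set_name Label for the result row.
#' @return One-row tibble as in [proximity_ratio()].
#' @export
proximity_association <- function(annotation, sig_genes, features,
                                  feature_set_name = "features") {
  bad <- setdiff(sig_genes, annotation$gene_id)
  if (length(bad) > 0) {
    stop_data("significant gene not in annotation: ", bad[1])
  }
  d <- nearest_distance(annotation, features)
  d <- d[!is.na(d$distance), ]
  is_sig <- d$gene_id %in% sig_genes
  if (sum(is_sig) == 0 || sum(!is_sig) == 0) {
    stop_data("a partition is empty: ", sum(is_sig), " significant vs ",
              sum(!is_sig), " null genes with defined distances")
  }
  proximity_ratio(d$distance[is_sig], d$distance[!is_sig], feature_set_name)
}

#' Proximity association across several feature sets
#'
#' @param annotation,sig_genes As in [proximity_association()].
#' @param feature_sets Named list of feature interval tibbles.
#' @return Tibble with one [proximity_ratio()] row per feature set.
#' @export
proximity_association_table <- function(annotation, sig_genes, feature_sets) {
  purrr::imap(feature_sets, function(f, nm) {
    proximity_association(annotation, sig_genes, f, feature_set_name = nm)
  }) |> dplyr::bind_rows()
}
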