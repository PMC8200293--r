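#' Per-gene log2 fold changes between two groups
#'
#' `log2((mean treated + pseudocount) / (mean control + pseudocount))` on
#' normalized counts. The pseudocount (default 1) stabilises ratios at low
#' counts and makes the fold change defined for all-zero genes.
#'
#' @param normalized Normalized counts tibble (`gene_id` + sample columns).
#' @param groups Character vector, one entry per sample column, with
#'   exactly two levels.
#' @param treatment,control The group levels compared (treatment over
#'   control).
#' @param pseudocount Positive pseudocount added to both group means.
#' @return Numeric vector of per-gene log2 fold changes, named by gene.
#' @export
log2_fold_changes <- function(normalized, groups, treatment, control,
                              pseudocount = 1) {
  check_counts_tbl(normalized)
  assert_scalar_number(pseudocount, "pseudocount",
                       lower = .Machine$double.xmin)
  m <- counts_matrix(normalized)
  if (length(groups) != ncol(m)) {
    stop_data("`groups` must have one entry per sample column")
  }
  for (g in c(treatment, control)) {
    if (sum(groups == g) == 0) stop_data("group '", g, "' has 0 samples")
  }
  mt <- rowMeans(m[, groups == treatment, drop = FALSE])
  mc <- rowMeans(m[, groups == control, drop = FALSE])
  setNames(log2((mt + pseudocount) / (mc + pseudocount)), rownames(m))
}

#' Simplified two-group negative-binomial test
#'
#' A per-gene Wald test on normalized counts. The NB dispersion is
#' estimated by the method of moments
#' (`alpha = max(0, (var - mean) / mean^2)` on within-group moments pooled
#' across both groups, floored at the Poisson limit). With replicate-level
#' sample sizes the per-gene moment estimate is far too noisy to plug into
#' a Wald statistic, so by default the per-gene estimates are averaged
#' across genes into one shared dispersion
#' (`dispersion = "shared"`); this both stabilises the statistic and keeps
#' the normal reference calibrated. `dispersion = "per_gene"` uses the raw
#' per-gene estimates instead (anti-conservative at small n). The
#' fold-change standard error follows from the NB variance by the delta
#' method and a two-sided p-value is read from the normal reference. Genes
#' with all-zero counts get an undefined p-value and are excluded from
#' multiple testing.
#'
#' This is a deliberate simplification of a full NB generalised linear
#' model with dispersion shrinkage: it keeps the normalization and
#' thresholding logic testable without re-implementing that machinery.
#'
#' @param counts Raw counts tibble.
#' @param s Size factors ([size_factors()] result or named vector).
#' @param groups Character vector, one entry per sample column.
#' @param treatment,control Group levels compared.
#' @param pseudocount Pseudocount used in the fold change.
#' @param dispersion `"shared"` (default) or `"per_gene"`.
#' @return Tibble with `gene_id`, `base_mean`, `log2_fold_change`, `stat`,
#'   `p_value` (NA for all-zero genes).
#' @export
nb_test <- function(counts, s, groups, treatment, control, pseudocount = 1,
                    dispersion = c("shared", "per_gene")) {
  dispersion <- match.arg(dispersion)
  check_counts_tbl(counts)
  m <- counts_matrix(counts)
  if (length(groups) != ncol(m)) {
    stop_data("`groups` must have one entry per sample column")
  }
  for (g in c(treatment, control)) {
    if (sum(groups == g) < 2) {
      stop_data("group '", g, "' has fewer than 2 samples")
    }
  }
  v <- sf_vector(s, colnames(m))
  norm <- sweep(m, 2, v, "/")
  nt <- norm[, groups == treatment, drop = FALSE]
  nc <- norm[, groups == control, drop = FALSE]
  n1 <- ncol(nt); n0 <- ncol(nc)

  mean1 <- rowMeans(nt); mean0 <- rowMeans(nc)
  var1 <- apply(nt, 1, var); var0 <- apply(nc, 1, var)
  # A normalized count K/s has variance mu/s + alpha*mu^2, so the Poisson
  # part of each group's moments carries the group's mean reciprocal factor.
  w1 <- mean(1 / v[groups == treatment])
  w0 <- mean(1 / v[groups == control])
  pool_mean <- (n1 * mean1 + n0 * mean0) / (n1 + n0)
  a1 <- (var1 - mean1 * w1) / pmax(mean1, .Machine$double.eps)^2
  a0 <- (var0 - mean0 * w0) / pmax(mean0, .Machine$double.eps)^2
  alpha <- pmax(0, ((n1 - 1) * a1 + (n0 - 1) * a0) / (n1 + n0 - 2))
  if (dispersion == "shared" && any(pool_mean > 0)) {
    alpha <- rep(mean(alpha[pool_mean > 0]), length(alpha))
  }

  lfc <- log2((mean1 + pseudocount) / (mean0 + pseudocount))
  # Delta method on log2 of pseudocounted group means, NB variance model.
  vm1 <- (mean1 * w1 + alpha * mean1^2) / n1
  vm0 <- (mean0 * w0 + alpha * mean0^2) / n0
  se <- sqrt(vm1 / (mean1 + pseudocount)^2 + vm0 / (mean0 + pseudocount)^2) /
    log(2)
  stat <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * pnorm(-abs(stat))
  all_zero <- rowSums(m) == 0
  p[all_zero] <- NA_real_
  stat[all_zero] <- NA_real_
  tibble(gene_id = rownames(m),
         base_mean = rowMeans(norm),
         log2_fold_change = unname(lfc),
         stat = unname(stat),
         p_value = unname(p))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment controlling the false discovery rate. Undefined
#' p-values (e.g. all-zero genes) stay undefined and do not count toward
#' the number of tests.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Vector of FDR-adjusted values in the input order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop_data("p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Call differential genes at FDR and fold-change thresholds
#'
#' A gene is `up` when its FDR is at most `fdr_threshold` and its linear
#' fold change `2^lfc` is at least `fc_threshold`; `down` symmetrically
#' with `2^lfc <= 1/fc_threshold`; otherwise `ns`. The sets are disjoint by
#' construction.
#'
#' @param de Tibble with `log2_fold_change` and `fdr` columns (e.g. from
#'   [de_test()] or [nb_test()] + [bh_adjust()]).
#' @param fdr_threshold FDR significance threshold (default 0.05).
#' @param fc_threshold Linear fold-change threshold, >= 1 (typically 1.5
#'   or 2).
#' @return `de` with a `status` column (`"up"`, `"down"`, `"ns"`).
#' @export
call_de <- function(de, fdr_threshold = 0.05, fc_threshold = 1.5) {
  assert_scalar_number(fdr_threshold, "fdr_threshold", lower = 0, upper = 1)
  if (!is.numeric(fc_threshold) || fc_threshold < 1) {
    stop_data("`fc_threshold` must be >= 1")
  }
  if (!all(c("log2_fold_change", "fdr") %in% names(de))) {
    stop_data("`de` needs `log2_fold_change` and `fdr` columns")
  }
  sig <- !is.na(de$fdr) & de$fdr <= fdr_threshold
  fc <- 2^de$log2_fold_change
  de$status <- dplyr::case_when(
    sig & fc >= fc_threshold ~ "up",
    sig & fc <= 1 / fc_threshold ~ "down",
    .default = "ns"
  )
  de
}

#' Two-group differential expression pipeline
#'
#' Convenience wrapper chaining [size_factors()] (or user-supplied
#' factors), [nb_test()], [bh_adjust()] and [call_de()].
#'
#' @inheritParams nb_test
#' @inheritParams call_de
#' @param s Size factors; when `NULL` they are computed from `counts` with
#'   [size_factors()] in the given `mode` (requires `annotation`).
#' @param annotation Annotation tibble (needed only when `s` is `NULL`).
#' @param mode Normalization mode when computing size factors.
#' @return A tibble of class `tt_de` with `gene_id`, `base_mean`,
#'   `log2_fold_change`, `stat`, `p_value`, `fdr`, `status`, carrying the
#'   thresholds as attributes.
#' @export
de_test <- function(counts, groups, treatment, control, s = NULL,
                    annotation = NULL, mode = "spikein",
                    fdr_threshold = 0.05, fc_threshold = 1.5,
                    pseudocount = 1) {
  if (is.null(s)) {
    if (is.null(annotation)) {
      stop_data("supply either size factors `s` or an `annotation`")
    }
    s <- size_factors(counts, annotation, mode = mode)
  }
  res <- nb_test(counts, s, groups, treatment, control,
                 pseudocount = pseudocount)
  res$fdr <- bh_adjust(res$p_value)
  res <- call_de(res, fdr_threshold, fc_threshold)
  structure(res, fdr_threshold = fdr_threshold, fc_threshold = fc_threshold,
            class = c("tt_de", class(tibble())))
}

#' @method tidy tt_de
#' @export
tidy.tt_de <- function(x, ...) {
  as_tibble(unclass(x)[c("gene_id", "base_mean", "log2_fold_change",
                         "stat", "p_value", "fdr", "status")])
}

#' @method glance tt_de
#' @export
glance.tt_de <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_tested = sum(!is.na(x$p_value)),
    n_up = sum(x$status == "up"),
    n_down = sum(x$status == "down"),
    fdr_threshold = attr(x, "fdr_threshold"),
    fc_threshold = attr(x, "fc_threshold")
  )
}

#' Fisher's exact test for gene-set overlap
#'
#' One-sided enrichment test: the exact hypergeometric tail probability of
#' observing at least the given overlap between two gene sets drawn from a
#' common universe (default 6,049 genes, the size of the budding-yeast
#' protein-coding catalogue typically used for such tests). The sample odds
#' ratio of the implied 2x2 table is reported, with a 0.5 continuity
#' correction when any cell is empty.
#'
#' @param set_a,set_b Character vectors of gene identifiers (or set sizes
#'   via `n_a`/`n_b`/`n_overlap` directly).
#' @param universe_size Size of the gene universe.
#' @param n_a,n_b,n_overlap Alternative numeric specification of the table.
#' @return One-row tibble: `n_a`, `n_b`, `n_overlap`, `universe_size`,
#'   `odds_ratio`, `p_value`.
#' @examples
#' overlap_fisher(n_a = 5, n_b = 5, n_overlap = 5, universe_size = 10)
#' @export
overlap_fisher <- function(set_a = NULL, set_b = NULL, universe_size = 6049,
                           n_a = NULL, n_b = NULL, n_overlap = NULL) {
  if (!is.null(set_a) || !is.null(set_b)) {
    set_a <- unique(set_a); set_b <- unique(set_b)
    n_a <- length(set_a); n_b <- length(set_b)
    n_overlap <- length(intersect(set_a, set_b))
  }
  if (is.null(n_a) || is.null(n_b) || is.null(n_overlap)) {
    stop_data("supply gene sets or all of n_a, n_b, n_overlap")
  }
  if (n_a > universe_size || n_b > universe_size) {
    stop_data("set size exceeds the universe")
  }
  if (n_overlap > min(n_a, n_b)) {
    stop_data("overlap exceeds the smaller set")
  }
  if (n_a + n_b - n_overlap > universe_size) {
    stop_data("union of the sets exceeds the universe")
  }
  p <- if (n_a == 0 || n_b == 0) 1 else {
    phyper(n_overlap - 1, n_a, universe_size - n_a, n_b, lower.tail = FALSE)
  }
  a <- n_overlap
  b <- n_a - n_overlap
  c_ <- n_b - n_overlap
  d <- universe_size - n_a - n_b + n_overlap
  if (any(c(a, b, c_, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  tibble(n_a = n_a, n_b = n_b, n_overlap = n_overlap,
         universe_size = universe_size,
         odds_ratio = (a * d) / (b * c_), p_value = p)
}
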