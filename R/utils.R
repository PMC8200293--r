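# Internal helpers shared across modules.

# Stop with a data-error message, classed so callers can distinguish
# malformed input from programming errors.
stop_data <- function(...) {
  rlang::abort(paste0(...), class = "nascentr_data_error")
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_data("`", name, "` must be a single non-missing number")
  }
  if (x < lower || x > upper) {
    stop_data("`", name, "` must be in [", lower, ", ", upper, "], got ", x)
  }
  invisible(x)
}

# Convert a tibble of 0-based half-open intervals to a GRanges (1-based,
# closed) for overlap/nearest queries. Strand is dropped unless requested:
# most interval work here is strand-agnostic.
as_granges0 <- function(tbl, keep_strand = FALSE) {
  strand <- if (keep_strand && "strand" %in% names(tbl)) {
    ifelse(tbl$strand %in% c("+", "-"), tbl$strand, "*")
  } else "*"
  GenomicRanges::GRanges(
    seqnames = tbl$chrom,
    ranges = IRanges::IRanges(start = tbl$start + 1L, end = tbl$end),
    strand = strand
  )
}

check_interval_tbl <- function(tbl, what = "interval") {
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0) {
    stop_data(what, " table lacks column(s): ", paste(miss, collapse = ", "))
  }
  bad <- which(!(tbl$start >= 0 & tbl$start < tbl$end))
  if (length(bad) > 0) {
    stop_data(what, " row ", bad[1], " violates 0 <= start < end (start=",
              tbl$start[bad[1]], ", end=", tbl$end[bad[1]], ")")
  }
  if (any(!nzchar(tbl$chrom))) stop_data(what, " has an empty chromosome name")
  invisible(tbl)
}

# Sample columns of a counts tibble (everything except gene_id).
sample_cols <- function(counts) setdiff(names(counts), "gene_id")

check_counts_tbl <- function(counts) {
  if (!"gene_id" %in% names(counts)) {
    stop_data("counts table must have a `gene_id` column")
  }
  smp <- sample_cols(counts)
  if (length(smp) == 0) stop_data("counts table has no sample columns")
  if (nrow(counts) > 0) {
    vals <- as.matrix(counts[smp])
    if (!is.numeric(vals)) stop_data("counts must be numeric")
    if (any(is.na(vals))) stop_data("counts contain missing values")
    if (any(vals < 0)) stop_data("counts contain negative values")
  }
  invisible(counts)
}

counts_matrix <- function(counts) {
  m <- as.matrix(counts[sample_cols(counts)])
  rownames(m) <- counts$gene_id
  m
}
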