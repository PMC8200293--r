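#' Read a BED-like interval file
#'
#' Reads a tab-delimited interval file in the BED convention (0-based,
#' half-open). Three columns are required (`chrom`, `start`, `end`); column 4
#' is taken as the interval name and column 6 as the strand. A missing strand
#' column yields `"."` (feature sets such as protein binding sites are
#' unstranded).
#'
#' @param path Path to a tab-delimited file with >= 3 columns per line.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`, `name`,
#'   one row per input line, in file order.
#' @examples
#' p <- tempfile(fileext = ".bed")
#' writeLines("chrI\t100\t200\tsite1", p)
#' read_intervals(p)
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), name = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  out <- purrr::imap(fields, function(f, i) {
    if (length(f) < 3) stop_data("line ", i, ": fewer than 3 columns")
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) {
      stop_data("line ", i, ": non-integer coordinates ('", f[2], "', '",
                f[3], "')")
    }
    if (start < 0 || start >= end) {
      stop_data("line ", i, ": requires 0 <= start < end, got [", start,
                ", ", end, ")")
    }
    tibble(
      chrom = f[1], start = start, end = end,
      strand = if (length(f) >= 6 && f[6] %in% c("+", "-")) f[6] else ".",
      name = if (length(f) >= 4) f[4] else NA_character_
    )
  })
  dplyr::bind_rows(out)
}

#' Write intervals to a BED file
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and optionally
#'   `name`, `strand` (0-based half-open, as returned by [read_intervals()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  check_interval_tbl(intervals)
  name <- intervals$name %||% rep(".", nrow(intervals))
  name[is.na(name)] <- "."
  strand <- intervals$strand %||% rep(".", nrow(intervals))
  out <- tibble(chrom = intervals$chrom, start = intervals$start,
                end = intervals$end, name = name, score = 0L,
                strand = strand)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Accepts either a GTF file (9 columns; only `gene` feature rows are used,
#' coordinates are 1-based inclusive and converted to the internal 0-based
#' half-open convention) or a headered gene table with columns `gene_id`,
#' `chrom`, `start`, `end`, `strand` and optional `biotype`, `family`
#' (1-based inclusive, converted the same way). Each gene's organism
#' (`"target"` or `"spikein"`) is assigned from its chromosome via
#' `organism_of`.
#'
#' @param path Path to the annotation file.
#' @param organism_of Named character vector mapping chromosome name to
#'   `"target"` or `"spikein"`. Chromosomes absent from the mapping are an
#'   error.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `organism`, `biotype`, `family` (0-based half-open).
#' @export
read_annotation <- function(path, organism_of) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  if (is.null(names(organism_of)) ||
      !all(organism_of %in% c("target", "spikein"))) {
    stop_data("`organism_of` must be a named vector of 'target'/'spikein'")
  }
  first <- readLines(path, n = 1L)
  n_fields <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
  if (n_fields >= 9) {
    ann <- parse_gtf_genes(path)
  } else {
    tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    need <- c("gene_id", "chrom", "start", "end", "strand")
    miss <- setdiff(need, names(tbl))
    if (length(miss) > 0) {
      stop_data("gene table lacks column(s): ", paste(miss, collapse = ", "))
    }
    ann <- tibble(
      gene_id = as.character(tbl$gene_id), chrom = as.character(tbl$chrom),
      start = as.integer(tbl$start) - 1L, end = as.integer(tbl$end),
      strand = as.character(tbl$strand),
      biotype = as.character(tbl$biotype %||%
                               rep("protein_coding", nrow(tbl))),
      family = as.character(tbl$family %||% rep(NA_character_, nrow(tbl)))
    )
  }
  dup <- ann$gene_id[duplicated(ann$gene_id)]
  if (length(dup) > 0) stop_data("duplicate gene_id: ", dup[1])
  if (!all(ann$strand %in% c("+", "-"))) {
    stop_data("gene strand must be '+' or '-'")
  }
  check_interval_tbl(ann, "gene")
  unknown <- setdiff(unique(ann$chrom), names(organism_of))
  if (length(unknown) > 0) {
    stop_data("chromosome not in organism mapping: ", unknown[1])
  }
  ann$organism <- unname(organism_of[ann$chrom])
  ann[, c("gene_id", "chrom", "start", "end", "strand", "organism",
          "biotype", "family")]
}

parse_gtf_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(fields, function(f) length(f) >= 9 && f[3] == "gene",
                 logical(1))
  fields <- fields[keep]
  if (length(fields) == 0) stop_data("no gene records found in GTF")
  attr_value <- function(attrs, key) {
    m <- stringr::str_match(attrs, paste0(key, ' "([^"]+)"'))[, 2]
    m
  }
  purrr::map(fields, function(f) {
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end)) stop_data("non-integer GTF coordinates")
    gid <- attr_value(f[9], "gene_id")
    if (is.na(gid)) stop_data("GTF gene record lacks gene_id attribute")
    bt <- attr_value(f[9], "gene_biotype")
    tibble(gene_id = gid, chrom = f[1], start = start - 1L, end = end,
           strand = f[7],
           biotype = ifelse(is.na(bt), "protein_coding", bt),
           family = NA_character_)
  }) |> dplyr::bind_rows()
}

#' Write a gene annotation table
#'
#' Writes the headered 1-based inclusive gene table read by
#' [read_annotation()]. Round-trips losslessly with it.
#'
#' @param annotation Annotation tibble (0-based half-open internal form).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  out <- tibble(gene_id = annotation$gene_id, chrom = annotation$chrom,
                start = annotation$start + 1L, end = annotation$end,
                strand = annotation$strand, biotype = annotation$biotype,
                family = annotation$family)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read and write gene-level count tables
#'
#' Counts are stored as TSV with a `gene_id` first column and one column per
#' sample. `read_counts(write_counts(x))` is the identity: values and gene /
#' sample order are preserved exactly.
#'
#' @param path Path to a counts TSV.
#' @return `read_counts`: a tibble with `gene_id` plus one numeric column per
#'   sample.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0) stop_data("empty counts file (no header)")
  widths <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (length(unique(widths)) > 1) {
    stop_data("ragged counts file: line ",
              which(widths != widths[1])[1], " has ",
              widths[widths != widths[1]][1], " fields, expected ", widths[1])
  }
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(tbl)[1] != "gene_id") {
    stop_data("first counts column must be 'gene_id'")
  }
  check_counts_tbl(tbl)
  tbl
}

#' @rdname read_counts
#' @param counts Counts tibble (`gene_id` + sample columns, non-negative).
#' @export
write_counts <- function(counts, path) {
  check_counts_tbl(counts)
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Read a tabular alignment file
#'
#' One row per candidate mapping location with columns `read_id`, `chrom`,
#' `start`, `end` (0-based half-open), `strand`, `mismatches`, `is_primary`.
#' Rows sharing a `read_id` are the candidate locations of one multi-mapping
#' read; at most one of them may be primary.
#'
#' @param path Path to the alignment TSV (with header).
#' @return A tibble, one row per mapping location.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  tbl <- suppressWarnings(readr::read_tsv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      read_id = readr::col_character(), chrom = readr::col_character(),
      start = readr::col_integer(), end = readr::col_integer(),
      strand = readr::col_character(), mismatches = readr::col_integer(),
      is_primary = readr::col_logical()
    )
  ))
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    stop_data("alignment parse error at line ", probs$row[1] + 1L, ": expected ",
              probs$expected[1], ", got '", probs$actual[1], "'")
  }
  check_alignment_tbl(tbl)
  tbl
}

check_alignment_tbl <- function(aln) {
  need <- c("read_id", "chrom", "start", "end", "strand", "mismatches",
            "is_primary")
  miss <- setdiff(need, names(aln))
  if (length(miss) > 0) {
    stop_data("alignment table lacks column(s): ", paste(miss, collapse = ", "))
  }
  bad <- which(aln$end <= aln$start)
  if (length(bad) > 0) {
    stop_data("alignment row ", bad[1], ": end <= start")
  }
  if (any(is.na(aln$mismatches)) || any(aln$mismatches < 0)) {
    stop_data("mismatch counts must be non-negative integers")
  }
  if (!all(aln$strand %in% c("+", "-"))) {
    stop_data("alignment strand must be '+' or '-'")
  }
  prim <- aln |> dplyr::filter(.data$is_primary) |> dplyr::count(.data$read_id)
  if (any(prim$n > 1)) {
    stop_data("read '", prim$read_id[prim$n > 1][1],
              "' has more than one primary location")
  }
  invisible(aln)
}

#' @rdname read_alignments
#' @param alignments Alignment tibble.
#' @export
write_alignments <- function(alignments, path) {
  check_alignment_tbl(alignments)
  readr::write_tsv(alignments, path)
  invisible(path)
}

#' Per-base coverage tracks
#'
#' A coverage track stores one non-negative numeric vector per chromosome
#' (element i is the depth over the 0-based base i-1..i), together with the
#' strand it was computed from and any scale factor already applied.
#'
#' @param coverage Named list of non-negative numeric vectors, one per
#'   chromosome; each vector's length is the chromosome length.
#' @param strand One of `"+"`, `"-"`, `"."` (both strands).
#' @param scale Scale factor already applied to the values (1 = raw).
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(coverage, strand = ".", scale = 1) {
  if (!is.list(coverage) || is.null(names(coverage)) ||
      any(!nzchar(names(coverage)))) {
    stop_data("`coverage` must be a named list of per-chromosome vectors")
  }
  if (any(vapply(coverage, function(v) any(v < 0), logical(1)))) {
    stop_data("coverage values must be non-negative")
  }
  if (!strand %in% c("+", "-", ".")) stop_data("invalid strand tag")
  assert_scalar_number(scale, "scale", lower = .Machine$double.xmin)
  structure(list(coverage = coverage, strand = strand, scale = scale),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("<coverage_track> ", length(x$coverage), " chromosome(s), strand '",
      x$strand, "', scale ", format(x$scale), "\n", sep = "")
  invisible(x)
}

#' Write a coverage track as bedGraph
#'
#' Adjacent equal-valued bases are merged into maximal runs; zero-coverage
#' runs are omitted; records are 0-based half-open per the UCSC bedGraph
#' dialect. Values are written with full (round-trip) precision.
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  recs <- purrr::imap(track$coverage, function(v, chrom) {
    if (any(v < 0)) stop_data("negative coverage value on ", chrom)
    r <- rle(v)
    end <- cumsum(r$lengths)
    start <- end - r$lengths
    keep <- r$values != 0
    tibble(chrom = chrom, start = start[keep], end = end[keep],
           value = r$values[keep])
  })
  readr::write_tsv(dplyr::bind_rows(recs), path, col_names = FALSE)
  invisible(path)
}

#' Read a bedGraph file into a coverage track
#'
#' Bases not covered by any record are 0. Chromosome lengths must be
#' supplied since bedGraph carries no sequence dictionary.
#'
#' @param path Path to a bedGraph file.
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param strand,scale Tags recorded on the returned track.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, chrom_sizes, strand = ".", scale = 1) {
  tbl <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                         show_col_types = FALSE, progress = FALSE)
  cov <- lapply(chrom_sizes, function(L) numeric(L))
  for (i in seq_len(nrow(tbl))) {
    chrom <- tbl$chrom[i]
    if (!chrom %in% names(cov)) stop_data("unknown chromosome: ", chrom)
    if (tbl$end[i] > chrom_sizes[[chrom]]) {
      stop_data("record beyond chromosome end on ", chrom)
    }
    cov[[chrom]][(tbl$start[i] + 1L):tbl$end[i]] <- tbl$value[i]
  }
  coverage_track(cov, strand = strand, scale = scale)
}
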