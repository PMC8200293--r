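#' Pipeline run configuration
#'
#' Bundles the simulation configuration, analysis thresholds and output
#' location for [run_pipeline()]. Any externally supplied input paths are
#' checked for existence up front so a bad path fails before any
#' computation.
#'
#' @param out_dir Output directory for the run (created if needed).
#' @param sim A [sim_config()]; the run is deterministic given its seed.
#' @param normalization_mode `"internal"` or `"spikein"` for the
#'   differential-expression stage.
#' @param fdr_threshold,fc_threshold Differential-expression thresholds
#'   (defaults 0.05 and 1.5-fold).
#' @param universe_size Gene universe for the overlap test; `NULL` (the
#'   default) uses the number of simulated target genes. Analyses of the
#'   real budding-yeast catalogue conventionally use 6,049.
#' @param exclude_suffixes Gene-name suffixes excluded from size-factor
#'   reference sets.
#' @param n_gene_reads,n_repeat_reads Read counts for the coverage and
#'   repeat-quantification stages.
#' @param input_counts,input_annotation Optional paths to pre-existing
#'   counts / annotation files used instead of simulation output.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, sim = sim_config(),
                       normalization_mode = c("internal", "spikein"),
                       fdr_threshold = 0.05, fc_threshold = 1.5,
                       universe_size = NULL,
                       exclude_suffixes = c("rRNA", "RDN"),
                       n_gene_reads = 200000, n_repeat_reads = 20000,
                       input_counts = NULL, input_annotation = NULL) {
  normalization_mode <- match.arg(normalization_mode)
  stopifnot(inherits(sim, "sim_config"))
  assert_scalar_number(fdr_threshold, "fdr_threshold", lower = 0, upper = 1)
  if (fc_threshold < 1) stop_data("`fc_threshold` must be >= 1")
  for (p in c(input_counts, input_annotation)) {
    if (!is.null(p) && !file.exists(p)) {
      stop_data("configured input does not exist: ", p)
    }
  }
  structure(as.list(environment()), class = "run_config")
}

#' Run the full synthetic-data analysis pipeline
#'
#' Simulates a two-organism genome, counts, repeat reads, gene-body reads
#' and sequences, then runs every analysis stage: alignment filtering and
#' counting, internal and spike-in size factors, global transcription
#' ratios, differential expression, proximity association, weighted repeat
#' counting, metagene profiling and TES base-composition bias. All inputs
#' and result tables are written as TSV under `config$out_dir` together
#' with a manifest (parameters, input checksums, record counts) and a log.
#' Re-running with the same configuration reproduces byte-identical result
#' tables.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`annotation`,
#'   `counts`, `size_factors`, `ratio_summary`, `de`, `proximity`,
#'   `repeats`, `profile`, `base_bias`, paths).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(file.path(config$out_dir, "inputs"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(config$out_dir, "results"), showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "log.txt")
  log_lines <- character()
  t0 <- Sys.time()
  note <- function(stage, msg) {
    line <- sprintf("[%s] %.1fs %s", stage,
                    as.numeric(difftime(Sys.time(), t0, units = "secs")), msg)
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_data("stage '", name, "' failed: ", conditionMessage(e))
    })
  }
  in_path <- function(f) file.path(config$out_dir, "inputs", f)
  res_path <- function(f) file.path(config$out_dir, "results", f)

  # --- simulate ---------------------------------------------------------
  sim <- config$sim
  g <- stage("simulate", simulate_genome(sim))
  cc <- stage("simulate", simulate_counts(g$annotation, g$truth, sim))
  fams <- family_intervals(g$annotation)
  rep_aln <- stage("simulate", simulate_multimap_reads(
    fams, g$truth$family_abundances, config$n_repeat_reads, sim))
  gene_aln <- stage("simulate", simulate_gene_alignments(
    g$annotation, config$n_gene_reads, sim))
  genome_seq <- stage("simulate", simulate_sequences(
    g$annotation, a_rich_downstream = TRUE, sim))
  write_annotation(g$annotation, in_path("genes.tsv"))
  write_intervals(g$feature_sites, in_path("feature_sites.bed"))
  write_counts(cc$counts, in_path("counts.tsv"))
  readr::write_tsv(cc$samples, in_path("samples.tsv"))
  write_alignments(rep_aln, in_path("repeat_alignments.tsv"))
  write_alignments(gene_aln, in_path("gene_alignments.tsv"))
  Biostrings::writeXStringSet(genome_seq, in_path("genome.fa"))
  note("simulate", sprintf("%d genes, %d sites, %d samples",
                           nrow(g$annotation), nrow(g$feature_sites),
                           nrow(cc$samples)))

  # --- filter / count ---------------------------------------------------
  uniq <- stage("filter", filter_alignments(
    gene_aln, max_mismatches = 2, require_unique = TRUE,
    require_primary = TRUE))
  gene_counts <- stage("count-genes", count_reads_per_gene(
    uniq, g$annotation, strandedness = "reverse", allow_multioverlap = TRUE))
  readr::write_tsv(gene_counts, res_path("gene_read_counts.tsv"))
  note("count-genes", sprintf("%d reads assigned over %d genes",
                              sum(gene_counts$count), nrow(gene_counts)))

  # --- normalize --------------------------------------------------------
  sf_int <- stage("normalize", size_factors(
    cc$counts, g$annotation, mode = "internal",
    exclude_suffixes = config$exclude_suffixes))
  sf_spk <- stage("normalize", size_factors(
    cc$counts, g$annotation, mode = "spikein",
    exclude_suffixes = config$exclude_suffixes))
  readr::write_tsv(
    dplyr::bind_rows(internal = sf_int, spikein = sf_spk, .id = "mode"),
    res_path("size_factors.tsv"))
  gtr <- stage("normalize", global_transcription_ratio(
    cc$counts, g$annotation, cc$samples))
  gtr_summary <- transcription_ratio_summary(gtr)
  readr::write_tsv(gtr, res_path("transcription_ratio.tsv"))
  readr::write_tsv(gtr_summary, res_path("transcription_ratio_summary.tsv"))
  note("normalize", sprintf("median ratio by condition: %s",
                            paste(sprintf("%s=%.2f", gtr_summary$condition,
                                          gtr_summary$median_ratio),
                                  collapse = ", ")))

  # --- differential expression -----------------------------------------
  conditions <- unique(cc$samples$condition)
  de <- stage("de", de_test(
    cc$counts, groups = cc$samples$condition,
    treatment = conditions[2], control = conditions[1],
    s = if (config$normalization_mode == "spikein") sf_spk else sf_int,
    fdr_threshold = config$fdr_threshold,
    fc_threshold = config$fc_threshold))
  readr::write_tsv(tidy(de), res_path("differential_expression.tsv"))
  de_called <- de$gene_id[de$status != "ns"]
  note("de", sprintf("%d up, %d down of %d genes",
                     sum(de$status == "up"), sum(de$status == "down"),
                     nrow(de)))

  # --- overlap with ground truth ---------------------------------------
  target_ids <- g$annotation$gene_id[g$annotation$organism == "target"]
  universe <- config$universe_size %||% length(target_ids)
  ovl <- stage("overlap", overlap_fisher(
    intersect(de_called, target_ids), g$truth$true_de$gene_id,
    universe_size = universe))
  readr::write_tsv(ovl, res_path("overlap_truth.tsv"))

  # --- proximity --------------------------------------------------------
  prox_genes <- g$annotation |>
    dplyr::filter(.data$organism == "target",
                  .data$biotype == "protein_coding")
  prox <- stage("proximity", proximity_association(
    prox_genes, intersect(de_called, prox_genes$gene_id),
    g$feature_sites, feature_set_name = "feature_sites"))
  readr::write_tsv(prox, res_path("proximity.tsv"))
  note("proximity", sprintf("ratio %.3f (fallback: %s)", prox$ratio,
                            prox$fallback_used))

  # --- repeats ----------------------------------------------------------
  rep_filt <- stage("count-repeats", filter_alignments(rep_aln,
                                                       max_mismatches = 2))
  expanded <- stage("count-repeats", expand_alignments(rep_filt))
  rep_counts <- stage("count-repeats", weighted_feature_counts(
    expanded, fams))
  rep_counts$family <- fams$family[match(rep_counts$name, fams$name)]
  fam_counts <- rep_counts |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(raw_weighted_count = sum(.data$raw_weighted_count),
                     per_million = sum(.data$per_million), .groups = "drop")
  readr::write_tsv(rep_counts, res_path("repeat_copy_counts.tsv"))
  readr::write_tsv(fam_counts, res_path("repeat_family_counts.tsv"))
  note("count-repeats", sprintf("%d expanded rows, %.0f weighted reads",
                                nrow(expanded),
                                sum(rep_counts$raw_weighted_count)))

  # --- metagene ---------------------------------------------------------
  sizes <- attr(g$annotation, "chrom_sizes")
  cov <- stage("metagene", coverage_from_alignments(uniq, sizes))
  sf_first <- sf_spk$size_factor[1]
  cov_scaled <- scale_coverage(cov, sf_first)
  write_bedgraph(cov_scaled, res_path("coverage.bedgraph"))
  mat <- stage("metagene", scale_regions_matrix(cov_scaled, prox_genes))
  prof <- metagene_profile(mat)
  readr::write_tsv(mat, res_path("metagene_matrix.tsv"))
  readr::write_tsv(prof, res_path("metagene_profile.tsv"))
  note("metagene", sprintf("%d genes x %d bins", nrow(mat), ncol(mat) - 1))

  # --- TES base bias ----------------------------------------------------
  bias <- stage("tes-bias", base_fraction_window(
    genome_seq, prox_genes, base = "A"))
  readr::write_tsv(bias, res_path("tes_base_bias.tsv"))
  note("tes-bias", sprintf("mean downstream A fraction %.3f",
                           mean(bias$raw[bias$offset >= 0])))

  # --- manifest ---------------------------------------------------------
  input_files <- list.files(file.path(config$out_dir, "inputs"),
                            full.names = TRUE)
  manifest <- list(
    package = "nascentr",
    version = as.character(utils::packageVersion("nascentr")),
    parameters = list(
      sim = unclass(sim),
      normalization_mode = config$normalization_mode,
      fdr_threshold = config$fdr_threshold,
      fc_threshold = config$fc_threshold,
      universe_size = universe,
      exclude_suffixes = config$exclude_suffixes,
      n_gene_reads = config$n_gene_reads,
      n_repeat_reads = config$n_repeat_reads
    ),
    input_checksums = as.list(tools::md5sum(input_files)),
    record_counts = list(
      genes = nrow(g$annotation), feature_sites = nrow(g$feature_sites),
      samples = nrow(cc$samples), expanded_rows = nrow(expanded),
      de_up = sum(de$status == "up"), de_down = sum(de$status == "down")
    )
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, log_path)

  invisible(list(
    annotation = g$annotation, truth = g$truth, counts = cc$counts,
    samples = cc$samples,
    size_factors = list(internal = sf_int, spikein = sf_spk),
    ratio_summary = gtr_summary, de = de, overlap = ovl, proximity = prox,
    repeats = fam_counts, matrix = mat, profile = prof, base_bias = bias,
    out_dir = config$out_dir
  ))
}
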