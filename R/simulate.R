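#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generators. Defaults encode
#' the experimental design the package targets: a two-organism nascent-RNA
#' experiment where each sample carries a fixed-mass spike-in contributing
#' about 10% of the RNA, three replicates per condition, a global
#' transcriptional repression of 2.6-fold in the treated condition, and
#' differential genes preferentially placed near protein binding sites.
#'
#' @param n_target_genes,n_spikein_genes Number of genes in the target and
#'   spike-in organism catalogues.
#' @param n_feature_sites Number of binding-site intervals on the target
#'   genome.
#' @param n_samples_per_condition Replicates per condition.
#' @param global_scale Named positive vector, one entry per condition, of
#'   global transcription-output multipliers. The first condition is the
#'   reference; true differential effects are applied in the remaining
#'   condition(s). Default `c(control = 1, treated = 1/2.6)`.
#' @param de_fraction Fraction of target genes truly differential.
#' @param de_log2fc_location,de_log2fc_scale Location/scale of the absolute
#'   true log2 fold changes (sign is random).
#' @param nb_dispersion Negative-binomial dispersion (0 = Poisson).
#' @param proximity_enrichment Probability that a true-DE gene is placed
#'   within `proximity_distance` of a feature site.
#' @param proximity_distance Enrichment distance in bp (default 2000).
#' @param spike_mass_fraction Expected spike-in share of total counts in the
#'   reference condition (default 0.10, i.e. 90:10 target:spike mass).
#' @param seed Integer seed; every generator call is deterministic given it.
#' @param n_chromosomes,n_spike_chromosomes Chromosome counts for the two
#'   organisms (spike-in genes live on dedicated chromosomes).
#' @param chrom_length Optional fixed target-chromosome length; by default
#'   chromosomes are sized so genes occupy about `gene_density` of them.
#' @param gene_density Fraction of the genome covered by genes when sizing
#'   chromosomes automatically.
#' @param gene_length_range Gene lengths are drawn log-uniformly from this
#'   range (bp).
#' @param site_width Width of each feature site (bp).
#' @param families Named integer vector of genomic copy numbers per
#'   transposon family; defaults follow the budding-yeast Ty complement.
#' @param family_length Length of each transposon copy (bp).
#' @param base_mean_meanlog,base_mean_sdlog Log-normal parameters of per-gene
#'   baseline expression means.
#' @param depth_sdlog Log-normal sd of per-sample sequencing-depth factors.
#' @param read_length Simulated read length (bp).
#' @param a_rich_window,a_rich_prob Downstream window (bp) and adenine
#'   probability used when simulating TES-proximal A-richness.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_target_genes = 2000,
                       n_spikein_genes = 400,
                       n_feature_sites = 60,
                       n_samples_per_condition = 3,
                       global_scale = c(control = 1, treated = 1 / 2.6),
                       de_fraction = 0.1,
                       de_log2fc_location = 2,
                       de_log2fc_scale = 0.25,
                       nb_dispersion = 0.05,
                       proximity_enrichment = 0.8,
                       proximity_distance = 2000,
                       spike_mass_fraction = 0.10,
                       seed = 1L,
                       n_chromosomes = 4,
                       n_spike_chromosomes = 2,
                       chrom_length = NULL,
                       gene_density = 0.35,
                       gene_length_range = c(500, 5000),
                       site_width = 200,
                       families = c(Ty1 = 31, Ty2 = 13, Ty3 = 2, Ty4 = 3,
                                    Ty5 = 1),
                       family_length = 1300,
                       base_mean_meanlog = log(100),
                       base_mean_sdlog = 1,
                       depth_sdlog = 0.05,
                       read_length = 76,
                       a_rich_window = 100,
                       a_rich_prob = 0.6) {
  cfg <- as.list(environment())
  for (nm in c("n_target_genes", "n_spikein_genes", "n_feature_sites",
               "n_samples_per_condition")) {
    assert_scalar_number(cfg[[nm]], nm, lower = 1)
  }
  for (nm in c("de_fraction", "proximity_enrichment", "spike_mass_fraction")) {
    assert_scalar_number(cfg[[nm]], nm, lower = 0, upper = 1)
  }
  if (any(global_scale <= 0) || is.null(names(global_scale)) ||
      length(global_scale) < 2) {
    stop_data("`global_scale` must be a named positive vector with >= 2 conditions")
  }
  assert_scalar_number(nb_dispersion, "nb_dispersion", lower = 0)
  assert_scalar_number(seed, "seed")
  if (any(families < 1)) stop_data("family copy numbers must be >= 1")
  structure(cfg, class = "sim_config")
}

with_sim_seed <- function(config, offset, code) {
  withr::with_seed(as.integer(config$seed) + offset, code)
}

#' Simulate a two-organism genome annotation with feature sites
#'
#' Places non-overlapping genes on target chromosomes, dedicated spike-in
#' chromosomes, and multi-copy transposon families. A fraction
#' `proximity_enrichment` of the truly differential genes is placed within
#' `proximity_distance` of a feature site; all other genes are placed
#' uniformly. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with elements `annotation` (gene tibble carrying a
#'   `chrom_sizes` attribute), `feature_sites` (interval tibble) and `truth`
#'   (list with `true_de` tibble of `gene_id`, `log2fc`, `site_linked`;
#'   `global_scale`; `family_abundances`; `copy_numbers`).
#' @export
simulate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config, 1L, {
    lr <- config$gene_length_range
    gene_len <- round(exp(runif(config$n_target_genes, log(lr[1]), log(lr[2]))))
    ty_fam <- rep(names(config$families), config$families)
    ty_len <- rep(config$family_length, length(ty_fam))
    total_bp <- sum(gene_len) + sum(ty_len)
    if (is.null(config$chrom_length)) {
      chrom_len <- ceiling(total_bp / config$gene_density /
                             config$n_chromosomes)
    } else {
      chrom_len <- config$chrom_length
    }
    if (total_bp > 0.9 * chrom_len * config$n_chromosomes) {
      stop_data("requested genes exceed chromosome capacity (", total_bp,
                " bp of genes on ", chrom_len * config$n_chromosomes,
                " bp of genome)")
    }
    chroms <- paste0("chr", seq_len(config$n_chromosomes))
    sizes <- setNames(rep(chrom_len, config$n_chromosomes), chroms)

    # Feature sites: uniform over target chromosomes.
    site_chrom <- sample(chroms, config$n_feature_sites, replace = TRUE)
    site_start <- vapply(site_chrom, function(ch) {
      sample.int(sizes[[ch]] - config$site_width, 1L) - 1L
    }, integer(1))
    sites <- tibble(chrom = site_chrom, start = as.integer(site_start),
                    end = as.integer(site_start + config$site_width),
                    strand = ".",
                    name = sprintf("site_%03d", seq_len(config$n_feature_sites)))

    # Truth: which genes are differential, with what effect, and whether
    # they are placed near a site.
    n_de <- round(config$de_fraction * config$n_target_genes)
    de_idx <- sort(sample.int(config$n_target_genes, n_de))
    lfc <- sample(c(-1, 1), n_de, replace = TRUE) *
      abs(config$de_log2fc_location +
            config$de_log2fc_scale * rnorm(n_de))
    linked <- runif(n_de) < config$proximity_enrichment

    # Incremental non-overlapping placement with rejection sampling.
    occ_start <- setNames(rep(list(integer()), length(chroms)), chroms)
    occ_end <- occ_start
    place_uniform <- function(len) {
      for (try in 1:500) {
        ch <- sample(chroms, 1L)
        if (sizes[[ch]] <= len) next
        s <- sample.int(sizes[[ch]] - len, 1L) - 1L
        e <- s + len
        if (!any(s < occ_end[[ch]] & e > occ_start[[ch]])) {
          occ_start[[ch]] <<- c(occ_start[[ch]], s)
          occ_end[[ch]] <<- c(occ_end[[ch]], e)
          return(c(ch = ch, start = s))
        }
      }
      stop_data("requested genes exceed chromosome capacity ",
                "(placement failed after 500 attempts)")
    }
    near_candidate <- function(i, d, left, len) {
      ch <- sites$chrom[i]
      if (left) {
        e <- sites$start[i] - d
        s <- e - len
      } else {
        s <- sites$end[i] + d
        e <- s + len
      }
      if (s < 0 || e > sizes[[ch]]) return(NULL)
      if (any(s < occ_end[[ch]] & e > occ_start[[ch]])) return(NULL)
      occ_start[[ch]] <<- c(occ_start[[ch]], s)
      occ_end[[ch]] <<- c(occ_end[[ch]], e)
      c(ch = ch, start = s)
    }
    place_near_site <- function(len) {
      for (try in 1:1000) {
        hit <- near_candidate(sample.int(nrow(sites), 1L),
                              sample.int(config$proximity_distance + 1L,
                                         1L) - 1L,
                              runif(1) < 0.5, len)
        if (!is.null(hit)) return(hit)
      }
      # dense neighbourhood: sweep sites and offsets systematically
      for (i in sample.int(nrow(sites))) {
        for (d in seq(0, config$proximity_distance, by = 25)) {
          for (left in c(TRUE, FALSE)) {
            hit <- near_candidate(i, d, left, len)
            if (!is.null(hit)) return(hit)
          }
        }
      }
      stop_data("could not place a site-linked gene within the configured ",
                "distance of any feature site; genome too dense")
    }

    gene_chrom <- character(config$n_target_genes)
    gene_start <- integer(config$n_target_genes)
    linked_ids <- de_idx[linked]
    # Linked DE genes first, longest first (tightest placement constraint),
    # then everything else in index order.
    linked_ids <- linked_ids[order(-gene_len[linked_ids])]
    for (i in c(linked_ids, setdiff(seq_len(config$n_target_genes),
                                    linked_ids))) {
      hit <- if (i %in% linked_ids) place_near_site(gene_len[i]) else
        place_uniform(gene_len[i])
      gene_chrom[i] <- hit[["ch"]]
      gene_start[i] <- as.integer(hit[["start"]])
    }
    target <- tibble(
      gene_id = sprintf("gene_%05d", seq_len(config$n_target_genes)),
      chrom = gene_chrom, start = gene_start,
      end = gene_start + as.integer(gene_len),
      strand = sample(c("+", "-"), config$n_target_genes, replace = TRUE),
      organism = "target", biotype = "protein_coding", family = NA_character_
    )

    ty_chrom <- character(length(ty_fam))
    ty_start <- integer(length(ty_fam))
    for (i in seq_along(ty_fam)) {
      hit <- place_uniform(ty_len[i])
      ty_chrom[i] <- hit[["ch"]]
      ty_start[i] <- as.integer(hit[["start"]])
    }
    ty <- tibble(
      gene_id = paste0(ty_fam, "_c",
                       stats::ave(seq_along(ty_fam), ty_fam, FUN = seq_along)),
      chrom = ty_chrom, start = ty_start,
      end = ty_start + as.integer(ty_len),
      strand = sample(c("+", "-"), length(ty_fam), replace = TRUE),
      organism = "target", biotype = "transposon_gag", family = ty_fam
    )

    # Spike-in organism: dedicated chromosomes, sequential dense layout.
    sp_len <- round(exp(runif(config$n_spikein_genes, log(lr[1]), log(lr[2]))))
    sp_chroms <- paste0("spike_chr", seq_len(config$n_spike_chromosomes))
    sp_assign <- rep(sp_chroms, length.out = config$n_spikein_genes)
    spike <- dplyr::bind_rows(lapply(sp_chroms, function(ch) {
      len <- sp_len[sp_assign == ch]
      gaps <- sample.int(500, length(len), replace = TRUE)
      start <- cumsum(c(0L, head(len + gaps, -1)))
      tibble(chrom = ch, start = as.integer(start),
             end = as.integer(start + len),
             strand = sample(c("+", "-"), length(len), replace = TRUE))
    }))
    spike <- dplyr::mutate(
      spike,
      gene_id = sprintf("spike_%05d", dplyr::row_number()),
      organism = "spikein", biotype = "protein_coding",
      family = NA_character_, .before = 1
    )
    sp_sizes <- vapply(sp_chroms, function(ch) {
      max(spike$end[spike$chrom == ch]) + 1000L
    }, integer(1))

    annotation <- dplyr::bind_rows(target, ty, spike)
    attr(annotation, "chrom_sizes") <- c(sizes, setNames(sp_sizes, sp_chroms))

    truth <- list(
      true_de = tibble(gene_id = target$gene_id[de_idx], log2fc = lfc,
                       site_linked = linked),
      global_scale = config$global_scale,
      family_abundances = setNames(
        stats::rlnorm(length(config$families), meanlog = 0, sdlog = 0.5),
        names(config$families)),
      copy_numbers = config$families
    )
    list(annotation = annotation, feature_sites = sites, truth = truth)
  })
}

#' Simulate a negative-binomial count matrix
#'
#' Counts for gene i in sample j are drawn from a negative binomial with
#' mean `base_i * effect_ij * scale_j * depth_j`: the true log2 fold change
#' applies only to target genes in non-reference conditions; `scale_j` is
#' the condition's global transcription multiplier for target genes and 1
#' for spike-in genes (the spike-in mass is constant); `depth_j` is a
#' per-sample sequencing-depth factor. Spike-in baselines are scaled so the
#' spike-in share of reference-condition counts equals
#' `spike_mass_fraction`.
#'
#' @param annotation Annotation tibble from [simulate_genome()].
#' @param truth Truth list from [simulate_genome()].
#' @param config The same [sim_config()].
#' @return A list with `counts` (tibble, `gene_id` + one column per sample)
#'   and `samples` (tibble with `sample`, `condition`).
#' @export
simulate_counts <- function(annotation, truth, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(annotation) == 0) stop_data("empty annotation")
  if (!any(annotation$organism == "spikein")) {
    stop_data("annotation contains no spike-in genes")
  }
  with_sim_seed(config, 2L, {
    n <- nrow(annotation)
    is_target <- annotation$organism == "target"
    base <- stats::rlnorm(n, config$base_mean_meanlog, config$base_mean_sdlog)
    # Constant spike mass: anchor the expected spike-in share to the
    # reference condition's target output.
    f <- config$spike_mass_fraction
    ref_target_mass <- sum(base[is_target]) * config$global_scale[[1]]
    if (f > 0) {
      base[!is_target] <- base[!is_target] *
        (f / (1 - f)) * ref_target_mass / sum(base[!is_target])
    } else {
      base[!is_target] <- 0
    }

    conditions <- names(config$global_scale)
    samples <- tibble(
      sample = paste(rep(conditions, each = config$n_samples_per_condition),
                     rep(seq_len(config$n_samples_per_condition),
                         times = length(conditions)), sep = "_"),
      condition = rep(conditions, each = config$n_samples_per_condition)
    )
    depth <- stats::rlnorm(nrow(samples), 0, config$depth_sdlog)

    lfc <- setNames(rep(0, n), annotation$gene_id)
    lfc[truth$true_de$gene_id] <- truth$true_de$log2fc

    counts <- matrix(0, nrow = n, ncol = nrow(samples))
    for (j in seq_len(nrow(samples))) {
      cond <- samples$condition[j]
      scale_j <- ifelse(is_target, config$global_scale[[cond]], 1)
      effect <- ifelse(is_target & cond != conditions[1], 2^lfc, 1)
      mu <- base * effect * scale_j * depth[j]
      counts[, j] <- if (config$nb_dispersion == 0) {
        rpois(n, mu)
      } else {
        rnbinom(n, mu = mu, size = 1 / config$nb_dispersion)
      }
    }
    colnames(counts) <- samples$sample
    list(counts = dplyr::bind_cols(tibble(gene_id = annotation$gene_id),
                                   as_tibble(counts)),
         samples = samples)
  })
}

#' Extract transposon-family copy intervals from an annotation
#'
#' @param annotation Annotation tibble with `family` labels on repeat copies.
#' @return Tibble of copy intervals: `family`, `name`, `chrom`, `start`,
#'   `end`, `strand`.
#' @export
family_intervals <- function(annotation) {
  annotation |>
    dplyr::filter(!is.na(.data$family)) |>
    dplyr::transmute(family = .data$family, name = .data$gene_id,
                     chrom = .data$chrom, start = .data$start,
                     end = .data$end, strand = .data$strand)
}

#' Simulate multi-mapping reads from repeat families
#'
#' Each read is drawn from a family with probability proportional to its
#' abundance and is reported at the homologous position in every genomic
#' copy of that family (k = copy number), with one location flagged primary
#' and a single mismatch count shared by all locations (the copies are
#' simulated as perfect repeats, so all locations tie at the read's best
#' mismatch count).
#'
#' @param families Copy-interval tibble as from [family_intervals()].
#' @param abundances Named non-negative vector of true per-family expression;
#'   names must match `families$family`.
#' @param n_reads Number of reads to simulate.
#' @param config A [sim_config()] (seed, read length).
#' @return An alignment tibble (one row per mapping location).
#' @export
simulate_multimap_reads <- function(families, abundances, n_reads,
                                    config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (sum(abundances) <= 0) stop_data("total family abundance is zero")
  if (!all(names(abundances) %in% families$family)) {
    stop_data("abundance names missing from the family table")
  }
  with_sim_seed(config, 3L, {
    rl <- config$read_length
    fam <- sample(names(abundances), n_reads, replace = TRUE,
                  prob = abundances)
    mism <- sample(0:2, n_reads, replace = TRUE, prob = c(0.7, 0.2, 0.1))
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    rows <- lapply(names(abundances), function(f) {
      idx <- which(fam == f)
      if (length(idx) == 0) return(NULL)
      copies <- families[families$family == f, ]
      len <- min(copies$end - copies$start)
      if (len < rl) stop_data("family ", f, " copies shorter than read length")
      offset <- sample.int(len - rl + 1L, length(idx), replace = TRUE) - 1L
      primary_copy <- sample.int(nrow(copies), length(idx), replace = TRUE)
      k <- nrow(copies)
      tibble(
        read_id = rep(sprintf("read_%06d", idx), each = k),
        chrom = rep(copies$chrom, times = length(idx)),
        start = rep(copies$start, times = length(idx)) +
          rep(offset, each = k),
        end = rep(copies$start, times = length(idx)) +
          rep(offset, each = k) + rl,
        strand = rep(strand[idx], each = k),
        mismatches = rep(mism[idx], each = k),
        is_primary = rep(copies$name, times = length(idx)) ==
          rep(copies$name[primary_copy], each = k)
      )
    })
    out <- dplyr::bind_rows(rows) |> dplyr::arrange(.data$read_id)
    out$start <- as.integer(out$start)
    out$end <- as.integer(out$end)
    out
  })
}

#' Simulate uniquely mapping reads over gene bodies
#'
#' Generates single-location alignments falling entirely within target
#' protein-coding genes, with read strand opposite the gene strand (a
#' reverse-stranded library). Genes are sampled proportionally to length,
#' giving roughly uniform coverage within and across gene bodies; used to
#' exercise gene counting, coverage and metagene profiling.
#'
#' @param annotation Annotation tibble.
#' @param n_reads Number of reads.
#' @param config A [sim_config()].
#' @return An alignment tibble of uniquely mapping primary reads.
#' @export
simulate_gene_alignments <- function(annotation, n_reads,
                                     config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  genes <- annotation |>
    dplyr::filter(.data$organism == "target",
                  .data$biotype == "protein_coding")
  rl <- config$read_length
  genes <- genes[genes$end - genes$start >= rl, ]
  if (nrow(genes) == 0) stop_data("no target genes long enough for reads")
  with_sim_seed(config, 5L, {
    len <- genes$end - genes$start
    gi <- sample.int(nrow(genes), n_reads, replace = TRUE, prob = len)
    offset <- floor(runif(n_reads) * (len[gi] - rl + 1))
    tibble(
      read_id = sprintf("galn_%06d", seq_len(n_reads)),
      chrom = genes$chrom[gi],
      start = as.integer(genes$start[gi] + offset),
      end = as.integer(genes$start[gi] + offset + rl),
      strand = ifelse(genes$strand[gi] == "+", "-", "+"),
      mismatches = 0L, is_primary = TRUE
    )
  })
}

#' Simulate a genome sequence, optionally A-rich downstream of gene ends
#'
#' Background base composition is uniform. With `a_rich_downstream = TRUE`,
#' the `a_rich_window` bases immediately downstream of every gene's
#' transcription end site carry elevated sense-strand adenine probability
#' (`a_rich_prob`), emulating the A-richness that biases 4-TU-based nascent
#' RNA recovery near gene ends.
#'
#' @param annotation Annotation tibble (uses its `chrom_sizes` attribute
#'   unless `chrom_sizes` is given).
#' @param a_rich_downstream Add the downstream adenine enrichment?
#' @param config A [sim_config()].
#' @param chrom_sizes Optional named vector of chromosome lengths.
#' @return A [Biostrings::DNAStringSet] with one sequence per chromosome.
#' @export
simulate_sequences <- function(annotation, a_rich_downstream = TRUE,
                               config = sim_config(), chrom_sizes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  sizes <- chrom_sizes %||% attr(annotation, "chrom_sizes")
  if (is.null(sizes)) stop_data("chromosome sizes unavailable")
  with_sim_seed(config, 4L, {
    bases <- c("A", "C", "G", "T")
    seqs <- lapply(sizes, function(L) {
      sample(bases, L, replace = TRUE)
    })
    if (a_rich_downstream) {
      w <- config$a_rich_window
      p <- config$a_rich_prob
      p_other <- (1 - p) / 3
      for (i in seq_len(nrow(annotation))) {
        ch <- annotation$chrom[i]
        L <- sizes[[ch]]
        if (annotation$strand[i] == "+") {
          pos <- annotation$end[i] + seq_len(w) - 1L  # 0-based end..end+w-1
          pos <- pos[pos < L]
          seqs[[ch]][pos + 1L] <- sample(
            bases, length(pos), replace = TRUE,
            prob = c(p, p_other, p_other, p_other))
        } else {
          pos <- annotation$start[i] - seq_len(w)     # 0-based start-1..start-w
          pos <- pos[pos >= 0]
          # sense-strand A on a minus gene is a reference-strand T
          seqs[[ch]][pos + 1L] <- sample(
            bases, length(pos), replace = TRUE,
            prob = c(p_other, p_other, p_other, p))
        }
      }
    }
    Biostrings::DNAStringSet(
      setNames(vapply(seqs, paste, character(1), collapse = ""), names(sizes))
    )
  })
}
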