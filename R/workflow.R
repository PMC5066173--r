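#' ZDR content of a set of peaks
#'
#' Scans the sequence under each peak for Z-DNA-forming regions at the
#' given superhelical density cutoff. Peaks are scanned jointly (their
#' sequences concatenated with N spacers, which no window can cross), so
#' the result equals a per-peak scan.
#'
#' @param genome named character vector of chromosome sequences.
#' @param peaks interval data.frame.
#' @param sigma_cutoff negative superhelical density cutoff.
#' @param config an [energetics_config()].
#' @return List with `has_zdr` (logical per peak) and `calls` (ZDR calls in
#'   genomic coordinates, with a `peak` index column).
#' @export
zdrs_in_peaks <- function(genome, peaks, sigma_cutoff,
                          config = energetics_config()) {
  n <- nrow(peaks)
  empty_calls <- data.frame(chrom = character(0), start = integer(0),
                            end = integer(0), sigma_required = numeric(0),
                            phase = integer(0), dg_total = numeric(0),
                            peak = integer(0))
  if (n == 0L) return(list(has_zdr = logical(0), calls = empty_calls))
  seqs <- substring(genome[peaks$chrom], peaks$start + 1L, peaks$end)
  sep <- strrep("N", 60L)
  concat <- paste(seqs, collapse = sep)
  offs <- cumsum(c(0L, nchar(seqs) + 60L))[seq_len(n)]  # concat offsets
  calls <- scan_zdrs(concat, sigma_cutoff, config, chrom = "concat")
  if (nrow(calls) == 0L)
    return(list(has_zdr = logical(n), calls = empty_calls))
  pk <- findInterval(calls$start, offs)
  calls$chrom <- peaks$chrom[pk]
  shift <- peaks$start[pk] - offs[pk]
  calls$start <- calls$start + shift
  calls$end <- calls$end + shift
  calls$peak <- pk
  has <- logical(n)
  has[unique(pk)] <- TRUE
  list(has_zdr = has, calls = calls)
}

#' Mean superhelicity profile over a set of peaks
#'
#' Averages the sliding-window sigma profile across peak centers (the
#' Fig-3B-style landscape: required superhelical density as a function of
#' distance from the peak center).
#'
#' @param genome named character vector of chromosome sequences.
#' @param peaks interval data.frame.
#' @param config an [energetics_config()].
#' @param flank profile half-width, bp.
#' @param max_peaks profile at most this many peaks (subsampled
#'   deterministically by taking the first `max_peaks`).
#' @return List with `offsets` and `mean_sigma` (NA-aware column means).
#' @export
mean_sigma_profile <- function(genome, peaks, config = energetics_config(),
                               flank = 2000L, max_peaks = 500L) {
  use <- peaks[seq_len(min(nrow(peaks), max_peaks)), , drop = FALSE]
  vals <- NULL
  for (i in seq_len(nrow(use))) {
    pr <- sigma_profile(genome[[use$chrom[i]]], interval_midpoint(use[i, ]),
                        config, flank = flank)
    vals <- rbind(vals, pr$values)
  }
  list(offsets = seq(-flank, flank - 20L, by = 2L),
       mean_sigma = colMeans(vals, na.rm = TRUE), n = nrow(use))
}

#' Assemble a run configuration
#'
#' Exactly one of synthetic mode or a full set of real input paths must be
#' given. All module parameters live here with their defaults; the seed
#' drives every stochastic step and is echoed into every output header.
#'
#' @param synthetic generate inputs with the synthetic module.
#' @param seed integer master seed.
#' @param outdir output directory (created if missing); `NULL` to skip
#'   writing files.
#' @param genome_fasta,gene_table,blacklist_bed paths for real-input mode.
#' @param read_beds named list of BED paths (`rep1..repN`, `IgG`, `input`)
#'   for real-input mode.
#' @param energetics an [energetics_config()].
#' @param pipeline a [pipeline_config()].
#' @param sigma_cutoffs the two ZDR cutoffs.
#' @param promoter_bp promoter half-width, bp.
#' @param n_random_peaks size of the random-peak null set.
#' @param n_top,n_mid expression group sizes.
#' @param synth list of overrides passed to [synth_genome()] /
#'   [synth_chip_experiment()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(synthetic = TRUE, seed = 1L, outdir = NULL,
                       genome_fasta = NULL, gene_table = NULL,
                       blacklist_bed = NULL, read_beds = NULL,
                       energetics = energetics_config(),
                       pipeline = pipeline_config(seed = seed),
                       sigma_cutoffs = c(-0.08, -0.07),
                       promoter_bp = 2000L, n_random_peaks = 10000L,
                       n_top = 30L, n_mid = 30L, synth = list()) {
  real <- !is.null(genome_fasta)
  if (synthetic == real)
    stop("exactly one of synthetic mode or real input paths is required")
  if (real && (is.null(gene_table) || is.null(read_beds)))
    stop("real-input mode needs genome_fasta, gene_table and read_beds")
  structure(list(synthetic = synthetic, seed = as.integer(seed),
                 outdir = outdir, genome_fasta = genome_fasta,
                 gene_table = gene_table, blacklist_bed = blacklist_bed,
                 read_beds = read_beds, energetics = energetics,
                 pipeline = pipeline, sigma_cutoffs = sigma_cutoffs,
                 promoter_bp = as.integer(promoter_bp),
                 n_random_peaks = as.integer(n_random_peaks),
                 n_top = as.integer(n_top), n_mid = as.integer(n_mid),
                 synth = synth),
            class = "run_config")
}

header_lines <- function(cfg, extra = character(0)) {
  c(sprintf("# zfscan run: seed=%d N_domain=%g idr_self=%g idr_pooled=%g idr_pair=%g promoter_bp=%d",
            cfg$seed, cfg$energetics$N_domain, cfg$pipeline$idr_self,
            cfg$pipeline$idr_pooled, cfg$pipeline$idr_pair,
            cfg$promoter_bp),
    extra)
}

#' Run the full ZFS discovery and characterization analysis
#'
#' Orchestrates generate (or load) -> per-replicate peak calling ->
#' pseudoreplicate and replicate-pair IDR analysis -> maximum-cutoff
#' selection -> top-N pooled peaks -> blacklist filtering (final ZFSs) ->
#' cross-sample correlation -> ZDR scanning at both sigma cutoffs with a
#' length-matched random-peak null -> region classification -> mean
#' superhelicity profiles -> expression groups, TSS profiles, Pol II
#' overlap, location-stratified expression, and enrichment matrices. In
#' synthetic mode the final ZFSs are also scored against the planted truth.
#'
#' @param cfg a [run_config()].
#' @return A report list (class `zfs_report`) with counts for every stage,
#'   the three pairwise consistent-peak counts and selected cutoff, the
#'   correlation matrix, enrichment and association tests, recovery
#'   metrics (synthetic mode) and a manifest of written files.
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  seed <- cfg$seed
  if (cfg$synthetic) {
    sg_args <- utils::modifyList(list(seed = seed),
                                 cfg$synth[intersect(names(cfg$synth),
                                   names(formals(synth_genome)))])
    sg <- do.call(synth_genome, sg_args)
    ce_args <- utils::modifyList(list(synth = sg, seed = seed),
                                 cfg$synth[intersect(names(cfg$synth),
                                   names(formals(synth_chip_experiment)))])
    reads <- do.call(synth_chip_experiment, ce_args)
    expr_sim <- synth_expression(sg, seed = seed)
    genome <- sg$genome
    genes <- sg$genes
    blacklist <- sg$blacklist
    chrom_sizes <- sg$chrom_sizes
    truth <- sg$truth
    expression <- expr_sim$expression
    polii <- expr_sim$polii_peaks
    mrna_total <- expr_sim$total_mapped
  } else {
    for (p in c(cfg$genome_fasta, cfg$gene_table, unlist(cfg$read_beds),
                cfg$blacklist_bed))
      if (!is.null(p) && !file.exists(p)) stop("missing input: ", p)
    genome <- read_fasta(cfg$genome_fasta)
    genes <- read_gene_table(cfg$gene_table)
    blacklist <- if (is.null(cfg$blacklist_bed))
      genomic_intervals(character(0), integer(0), integer(0))
      else read_bed(cfg$blacklist_bed)
    reads <- lapply(cfg$read_beds, read_bed)
    chrom_sizes <- stats::setNames(nchar(genome), names(genome))
    truth <- NULL
    expression <- NULL
    polii <- NULL
    mrna_total <- NA
  }
  pc <- cfg$pipeline
  rep_names <- grep("^rep", names(reads), value = TRUE)
  n_reps <- length(rep_names)
  igg <- reads$IgG

  # per-replicate peaks against IgG
  rep_peaks <- lapply(rep_names, function(r)
    call_enriched_windows(reads[[r]], igg, chrom_sizes, pc))
  names(rep_peaks) <- rep_names

  idr_count <- function(p1, p2, thr) {
    pairs <- match_peak_pairs(p1, p2)
    fit <- fit_idr(pairs$score1, pairs$score2)
    count_reproducible(fit, thr)
  }

  # self-consistency: pseudoreplicates within each replicate (QC)
  self_counts <- vapply(seq_len(n_reps), function(i) {
    halves <- split_pseudoreplicate(reads[[rep_names[i]]],
                                    derive_seed(seed, 300L + i))
    pa <- call_enriched_windows(halves$half_A, igg, chrom_sizes, pc)
    pb <- call_enriched_windows(halves$half_B, igg, chrom_sizes, pc)
    idr_count(pa, pb, pc$idr_self)
  }, integer(1))

  # pooled-pseudoreplicate consistency (QC)
  pooled_reads <- do.call(rbind, reads[rep_names])
  ph <- split_pseudoreplicate(pooled_reads, derive_seed(seed, 310L))
  pooled_pseudo_count <- idr_count(
    call_enriched_windows(ph$half_A, igg, chrom_sizes, pc),
    call_enriched_windows(ph$half_B, igg, chrom_sizes, pc),
    pc$idr_pooled)

  # replicate-pair consistency -> the cutoff
  pair_idx <- utils::combn(n_reps, 2)
  pairwise_counts <- apply(pair_idx, 2, function(ij)
    idr_count(rep_peaks[[ij[1]]], rep_peaks[[ij[2]]], pc$idr_pair))
  cutoff <- select_cutoff(pairwise_counts)

  # pooled peaks, top-N, blacklist -> ZFS
  pooled_peaks <- call_enriched_windows(pooled_reads, igg, chrom_sizes, pc)
  cutoff_used <- min(cutoff, nrow(pooled_peaks))
  zfs <- finalize_zfs(pooled_peaks, cutoff_used, blacklist)
  n_blacklisted <- cutoff_used - nrow(zfs)

  correlations <- correlate_samples(reads, zfs)

  # random-peak null + ZDR content + regions
  random_peaks <- generate_random_peaks(
    cfg$n_random_peaks, zfs$end - zfs$start, chrom_sizes,
    derive_seed(seed, 320L))
  zdr <- list()
  for (sc in cfg$sigma_cutoffs) {
    key <- sprintf("%g", sc)
    zz <- zdrs_in_peaks(genome, zfs, sc, cfg$energetics)
    zr <- zdrs_in_peaks(genome, random_peaks, sc, cfg$energetics)
    zdr[[key]] <- list(
      zfs_with_zdr = sum(zz$has_zdr), zfs_total = nrow(zfs),
      random_with_zdr = sum(zr$has_zdr), random_total = nrow(random_peaks),
      calls = zz$calls,
      test = zdr_enrichment_test(sum(zz$has_zdr), nrow(zfs),
                                 sum(zr$has_zdr), nrow(random_peaks)))
  }

  index <- annotation_index(genes, chrom_sizes, cfg$promoter_bp)
  regions_zfs <- summarize_regions(zfs, index)
  regions_random <- summarize_regions(random_peaks, index)

  prof_zfs <- mean_sigma_profile(genome, zfs, cfg$energetics)
  prof_random <- mean_sigma_profile(genome, random_peaks, cfg$energetics)

  # transcription association (needs expression + Pol II peaks)
  assoc <- NULL
  if (!is.null(expression)) {
    grouped <- assign_groups(expression, cfg$n_top, cfg$n_mid)
    profile <- tss_profile(pooled_reads, genes, grouped$group,
                           total_mapped = nrow(pooled_reads))
    polii_test <- overlap_fisher(zfs, polii, random_peaks)
    strata <- strata_from_zfs(zfs, index)
    expr_loc <- expression_by_location(expression, strata)
    heat <- zfs_heatmap_matrix(
      list(Zaa = pooled_reads, IgG = igg, input = reads$input),
      zfs, pooled_reads)
    assoc <- list(grouped = grouped, tss_profile = profile,
                  polii_test = polii_test, strata = strata,
                  expression_by_location = expr_loc, heatmap = heat)
  }

  recovery <- NULL
  if (!is.null(truth)) {
    hit_truth <- overlaps_any(truth$zfs, zfs)
    hit_zfs <- overlaps_any(zfs, truth$zfs)
    recovery <- list(recall = mean(hit_truth), precision = mean(hit_zfs),
                     n_planted = nrow(truth$zfs), n_called = nrow(zfs))
  }

  report <- structure(list(
    seed = seed,
    n_reps = n_reps,
    rep_peak_counts = vapply(rep_peaks, nrow, integer(1)),
    self_consistent_counts = self_counts,
    pooled_pseudo_count = pooled_pseudo_count,
    pairwise_counts = as.integer(pairwise_counts),
    cutoff = cutoff, cutoff_used = cutoff_used,
    n_pooled_peaks = nrow(pooled_peaks),
    n_blacklisted = n_blacklisted,
    n_zfs = nrow(zfs),
    zfs = zfs, pooled_peaks = pooled_peaks, random_peaks = random_peaks,
    correlations = correlations, zdr = zdr,
    regions_zfs = regions_zfs, regions_random = regions_random,
    sigma_profile_zfs = prof_zfs, sigma_profile_random = prof_random,
    assoc = assoc, recovery = recovery, truth = truth,
    files = character(0)), class = "zfs_report")

  if (!is.null(cfg$outdir)) report <- write_run_outputs(report, cfg)
  report
}

# Write the standard output files for a finished run; returns the report
# with its file manifest filled in.
write_run_outputs <- function(report, cfg) {
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  hdr <- header_lines(cfg)
  out <- function(name) file.path(cfg$outdir, name)
  files <- character(0)

  write_bed(report$zfs, out("zfs.bed"), header = hdr)
  files <- c(files, out("zfs.bed"))
  for (key in names(report$zdr)) {
    calls <- report$zdr[[key]]$calls
    bed <- genomic_intervals(calls$chrom, calls$start, calls$end,
                             name = sprintf("zdr%04d", seq_len(nrow(calls))),
                             score = round(calls$sigma_required * 1000))
    f <- out(sprintf("zdr_sigma_%s.bed", gsub("-", "m", key)))
    write_bed(bed, f, header = hdr)
    files <- c(files, f)
  }
  write_bed(report$random_peaks, out("random_peaks.bed"), header = hdr)
  files <- c(files, out("random_peaks.bed"))

  reg <- rbind(cbind(set = "zfs", report$regions_zfs),
               cbind(set = "random", report$regions_random))
  utils::write.table(reg, out("region_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, out("region_summary.tsv"))

  prof <- data.frame(offset = report$sigma_profile_zfs$offsets,
                     mean_sigma_zfs = report$sigma_profile_zfs$mean_sigma,
                     mean_sigma_random = report$sigma_profile_random$mean_sigma)
  utils::write.table(prof, out("sigma_profile.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, out("sigma_profile.tsv"))

  if (!is.null(report$assoc)) {
    utils::write.table(report$assoc$grouped, out("expression_groups.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, out("expression_groups.tsv"))
    pm <- report$assoc$tss_profile
    mat <- data.frame(offset = pm$offsets, t(pm$profiles),
                      p_top_bottom = pm$p_top_bottom)
    utils::write.table(mat, out("tss_profile.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, out("tss_profile.tsv"))
  }

  lines <- c(hdr,
    sprintf("n_reps\t%d", report$n_reps),
    sprintf("rep_peaks\t%s", paste(report$rep_peak_counts, collapse = ",")),
    sprintf("self_consistent\t%s",
            paste(report$self_consistent_counts, collapse = ",")),
    sprintf("pooled_pseudo_consistent\t%d", report$pooled_pseudo_count),
    sprintf("pairwise_consistent\t%s",
            paste(report$pairwise_counts, collapse = ",")),
    sprintf("cutoff_max_pairwise\t%d", report$cutoff),
    sprintf("cutoff_used\t%d", report$cutoff_used),
    sprintf("blacklist_removed\t%d", report$n_blacklisted),
    sprintf("final_zfs\t%d", report$n_zfs))
  if (!is.null(report$recovery))
    lines <- c(lines,
      sprintf("planted_recall\t%.4f", report$recovery$recall),
      sprintf("planted_precision\t%.4f", report$recovery$precision))
  writeLines(lines, out("report.tsv"))
  files <- c(files, out("report.tsv"))

  report$files <- files
  report
}
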