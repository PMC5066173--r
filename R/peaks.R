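#' Peak-pipeline configuration
#'
#' IDR thresholds follow the replicated-ChIP convention: pseudoreplicate
#' self-consistency at 0.01, pooled-pseudoreplicate consistency at 0.001,
#' true replicate pairs at 0.05.
#'
#' @param idr_self IDR threshold for within-replicate pseudoreplicate pairs.
#' @param idr_pooled IDR threshold for pooled-pseudoreplicate pairs.
#' @param idr_pair IDR threshold for true replicate pairs.
#' @param bin_bp genome bin width for the Poisson caller, bp.
#' @param fragment_extension_bp length to which each read is extended from
#'   its 5' end, bp.
#' @param alpha_call per-bin Poisson significance for calling a bin enriched.
#' @param control_local_bp width of the window over which the control rate
#'   is estimated (floored at the genome-wide rate); estimating the
#'   expectation from single control bins would let control sampling noise
#'   masquerade as treatment enrichment.
#' @param seed RNG seed used by stochastic steps (pseudoreplicate splits).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(idr_self = 0.01, idr_pooled = 0.001,
                            idr_pair = 0.05, bin_bp = 50L,
                            fragment_extension_bp = 150L,
                            alpha_call = 1e-5, control_local_bp = 1000L,
                            seed = 1L) {
  stopifnot(idr_self > 0, idr_self < 1, idr_pooled > 0, idr_pooled < 1,
            idr_pair > 0, idr_pair < 1, bin_bp > 0,
            fragment_extension_bp > 0, alpha_call > 0, alpha_call < 1,
            control_local_bp >= bin_bp)
  structure(list(idr_self = idr_self, idr_pooled = idr_pooled,
                 idr_pair = idr_pair, bin_bp = as.integer(bin_bp),
                 fragment_extension_bp = as.integer(fragment_extension_bp),
                 alpha_call = alpha_call,
                 control_local_bp = as.integer(control_local_bp),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# 5' coordinate of a read interval (0-based).
read_pos5 <- function(reads) {
  ifelse(!is.na(reads$strand) & reads$strand == "-",
         reads$end - 1L, reads$start)
}

# Extend reads to fragments of the configured length from their 5' ends,
# clipped to [0, chrom size). Returns an interval data.frame.
extend_reads <- function(reads, chrom_sizes, ext) {
  p5 <- read_pos5(reads)
  minus <- !is.na(reads$strand) & reads$strand == "-"
  start <- ifelse(minus, p5 - ext + 1L, p5)
  end <- start + ext
  sz <- chrom_sizes[reads$chrom]
  data.frame(chrom = reads$chrom,
             start = pmax(0L, as.integer(start)),
             end = pmin(as.integer(sz), as.integer(end)),
             stringsAsFactors = FALSE)
}

#' Call enriched windows against a control with a Poisson model
#'
#' Reads are extended to fragments, counted in fixed genome bins, and each
#' bin's treatment count is tested against a depth-scaled control
#' expectation (one pseudocount) under a Poisson model. Significant adjacent
#' bins are merged into peaks; a peak's score is the -log10 of its best bin
#' p-value. Peaks are ranked by score, ties broken by coordinate.
#'
#' @param treatment,control read interval data.frames (BED-like, one row per
#'   mapped tag, strand used for 5'-end extension).
#' @param chrom_sizes named integer vector of chromosome sizes, bp.
#' @param config a [pipeline_config()].
#' @return data.frame of ranked peaks: `chrom`, `start`, `end`, `score`
#'   (-log10 best Poisson p), `rank` (1 = best).
#' @export
call_enriched_windows <- function(treatment, control, chrom_sizes,
                                  config = pipeline_config()) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), score = numeric(0), rank = integer(0))
  if (nrow(treatment) == 0L) {
    warning("empty treatment read set; no peaks called")
    return(empty)
  }
  if (nrow(control) == 0L) stop("empty control read set")
  miss <- setdiff(unique(c(treatment$chrom, control$chrom)),
                  names(chrom_sizes))
  if (length(miss)) stop("chromosome absent from sizes: ", miss[1])
  ext <- config$fragment_extension_bp
  bw <- config$bin_bp
  tfrag <- extend_reads(treatment, chrom_sizes, ext)
  cfrag <- extend_reads(control, chrom_sizes, ext)
  scale <- nrow(treatment) / nrow(control)
  peaks <- empty
  for (ch in names(chrom_sizes)) {
    nb <- as.integer(ceiling(chrom_sizes[[ch]] / bw))
    if (nb == 0L) next
    bins <- IRanges::IRanges(start = (seq_len(nb) - 1L) * bw + 1L,
                             end = pmin(seq_len(nb) * bw, chrom_sizes[[ch]]))
    tc <- IRanges::countOverlaps(
      bins, as_iranges0(tfrag[tfrag$chrom == ch, , drop = FALSE]))
    cc <- IRanges::countOverlaps(
      bins, as_iranges0(cfrag[cfrag$chrom == ch, , drop = FALSE]))
    # control rate per bin: local running mean floored at the chromosome
    # mean, plus one pseudocount, depth-scaled
    k <- max(1L, as.integer(round(config$control_local_bp / bw)))
    if (k %% 2L == 0L) k <- k + 1L
    local <- as.numeric(stats::filter(cc, rep(1 / k, k), sides = 2))
    local[is.na(local)] <- mean(cc)
    lambda <- (pmax(local, mean(cc)) + 1) * scale
    logp <- stats::ppois(tc - 1L, lambda, lower.tail = FALSE, log.p = TRUE)
    sig <- which(logp < log(config$alpha_call))
    if (!length(sig)) next
    runs <- IRanges::reduce(IRanges::IRanges(start = sig, end = sig))
    hit <- IRanges::findOverlaps(IRanges::IRanges(sig, sig), runs)
    best <- tapply(-logp[sig] / log(10), S4Vectors::subjectHits(hit), max)
    peaks <- rbind(peaks, data.frame(
      chrom = ch,
      start = (IRanges::start(runs) - 1L) * bw,
      end = pmin(IRanges::end(runs) * bw, chrom_sizes[[ch]]),
      score = as.numeric(best[as.character(seq_along(runs))]),
      rank = NA_integer_, stringsAsFactors = FALSE))
  }
  if (nrow(peaks) == 0L) return(empty)
  o <- order(-peaks$score, peaks$chrom, peaks$start)
  peaks <- peaks[o, , drop = FALSE]
  peaks$rank <- seq_len(nrow(peaks))
  rownames(peaks) <- NULL
  peaks
}

#' Split a read set into two pseudoreplicates
#'
#' Random equal partition of the reads (sizes differing by at most one),
#' deterministic for a given seed.
#'
#' @param reads read interval data.frame with at least 2 rows.
#' @param seed integer seed.
#' @return List with elements `half_A` and `half_B`.
#' @export
split_pseudoreplicate <- function(reads, seed) {
  n <- nrow(reads)
  if (n < 2L) stop("need at least 2 reads to split")
  idx <- withr::with_seed(seed, sample.int(n, size = n %/% 2L))
  list(half_A = reads[idx, , drop = FALSE],
       half_B = reads[-idx, , drop = FALSE])
}

#' Match peaks between two ranked lists by overlap
#'
#' Peaks are paired by any-overlap; each peak matches at most once, chosen
#' greedily by combined rank (best-ranked pairs first). Unmatched peaks are
#' excluded.
#'
#' @param peaks1,peaks2 ranked peak data.frames from
#'   [call_enriched_windows()].
#' @return data.frame with columns `i1`, `i2` (row indices) and `score1`,
#'   `score2`.
#' @export
match_peak_pairs <- function(peaks1, peaks2) {
  hits <- overlap_hits(peaks1, peaks2)
  out <- data.frame(i1 = integer(0), i2 = integer(0),
                    score1 = numeric(0), score2 = numeric(0))
  if (nrow(hits) == 0L) return(out)
  comb <- peaks1$rank[hits$q] + peaks2$rank[hits$s]
  hits <- hits[order(comb, peaks1$rank[hits$q]), , drop = FALSE]
  used1 <- logical(nrow(peaks1)); used2 <- logical(nrow(peaks2))
  keep <- logical(nrow(hits))
  for (k in seq_len(nrow(hits))) {
    if (!used1[hits$q[k]] && !used2[hits$s[k]]) {
      keep[k] <- TRUE
      used1[hits$q[k]] <- TRUE
      used2[hits$s[k]] <- TRUE
    }
  }
  hits <- hits[keep, , drop = FALSE]
  data.frame(i1 = hits$q, i2 = hits$s,
             score1 = peaks1$score[hits$q], score2 = peaks2$score[hits$s])
}

#' Select the consistency cutoff from pairwise consistent-peak counts
#'
#' The number of peaks to carry forward from the pooled list is the maximum
#' of the three replicate-pair consistent-peak counts.
#'
#' @param pairwise_counts integer vector of three non-negative counts.
#' @return The maximum count.
#' @export
#' @examples
#' select_cutoff(c(197, 229, 427))  # 427
select_cutoff <- function(pairwise_counts) {
  stopifnot(length(pairwise_counts) == 3L, all(pairwise_counts >= 0))
  as.integer(max(pairwise_counts))
}

#' Finalize ZFSs: top-N pooled peaks minus blacklist
#'
#' Takes the `cutoff` best-ranked pooled peaks, removes any peak overlapping
#' a blacklist region by at least one bp, and returns the survivors sorted
#' by coordinate.
#'
#' @param pooled_peaks ranked peak data.frame (pooled replicates).
#' @param cutoff number of top peaks to keep before filtering.
#' @param blacklist interval data.frame of regions to exclude (may be
#'   empty).
#' @return Sorted interval data.frame of final ZFSs.
#' @export
finalize_zfs <- function(pooled_peaks, cutoff, blacklist) {
  if (cutoff > nrow(pooled_peaks))
    stop("cutoff ", cutoff, " exceeds available peaks (",
         nrow(pooled_peaks), ")")
  top <- pooled_peaks[pooled_peaks$rank <= cutoff, , drop = FALSE]
  drop <- overlaps_any(top, blacklist)
  out <- sort_intervals(top[!drop, , drop = FALSE])
  if (nrow(out) == 0L) warning("all top peaks removed by blacklist")
  rownames(out) <- NULL
  out
}

#' Pearson correlation of per-ZFS read counts across samples
#'
#' Counts, for every sample, the reads overlapping each ZFS and returns the
#' Pearson correlation matrix of the count vectors.
#'
#' @param read_sets named list of read interval data.frames.
#' @param zfs interval data.frame of ZFSs (>= 2 rows).
#' @return Symmetric correlation matrix with unit diagonal; entries
#'   involving a zero-variance count vector are `NA` (with a warning).
#' @export
correlate_samples <- function(read_sets, zfs) {
  stopifnot(length(read_sets) >= 2L, nrow(zfs) >= 2L)
  counts <- vapply(read_sets, function(r) {
    hits <- overlap_hits(zfs, r)
    tabulate(hits$q, nbins = nrow(zfs))
  }, numeric(nrow(zfs)))
  v <- apply(counts, 2, stats::var)
  if (any(v == 0)) warning("zero-variance read-count vector for sample(s): ",
                           paste(colnames(counts)[v == 0], collapse = ", "))
  suppressWarnings(m <- stats::cor(counts, method = "pearson"))
  diag(m) <- 1
  m
}
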