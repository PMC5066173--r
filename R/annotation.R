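#' Build a promoter / gene-body annotation index
#'
#' Promoters are the strand-aware TSS plus/minus `promoter_bp` (boundary
#' inclusive on both sides); gene bodies are the gene spans. Classification
#' applies promoter precedence, so the promoter window effectively masks
#' the overlapping part of its gene body.
#'
#' @param genes gene-model data.frame (see [read_gene_table()]).
#' @param chrom_sizes named integer vector of chromosome sizes.
#' @param promoter_bp promoter half-width around the TSS, bp.
#' @return An object of class `annotation_index`.
#' @export
annotation_index <- function(genes, chrom_sizes, promoter_bp = 2000L) {
  stopifnot(promoter_bp > 0)
  tss <- gene_tss(genes)
  promoters <- data.frame(
    chrom = genes$chrom,
    start = pmax(0L, tss - as.integer(promoter_bp)),
    end = pmin(as.integer(chrom_sizes[genes$chrom]),
               tss + as.integer(promoter_bp) + 1L),
    name = genes$gene_id, score = NA_real_, strand = genes$strand,
    stringsAsFactors = FALSE
  )
  bodies <- data.frame(
    chrom = genes$chrom, start = genes$start, end = genes$end,
    name = genes$gene_id, score = NA_real_, strand = genes$strand,
    stringsAsFactors = FALSE
  )
  structure(list(promoters = promoters, bodies = bodies,
                 chrom_sizes = chrom_sizes,
                 promoter_bp = as.integer(promoter_bp)),
            class = "annotation_index")
}

#' Classify intervals as promoter, gene body or intergenic
#'
#' Classification is by interval midpoint with precedence
#' promoter > gene body > intergenic. A midpoint exactly `promoter_bp` from
#' a TSS is a promoter (boundary inclusive).
#'
#' @param x interval data.frame.
#' @param index an [annotation_index()].
#' @return Character vector of classes, one per interval.
#' @export
classify_intervals <- function(x, index) {
  unknown <- setdiff(unique(x$chrom), names(index$chrom_sizes))
  if (length(unknown)) stop("unknown chromosome: ", unknown[1])
  if (nrow(x) == 0L) return(character(0))
  mid <- interval_midpoint(x)
  pts <- data.frame(chrom = x$chrom, start = mid, end = mid + 1L,
                    stringsAsFactors = FALSE)
  cls <- rep("intergenic", nrow(x))
  cls[overlaps_any(pts, index$bodies)] <- "gene_body"
  cls[overlaps_any(pts, index$promoters)] <- "promoter"
  cls
}

#' Summarize region classes of a set of intervals
#'
#' @param x interval data.frame (>= 1 row).
#' @param index an [annotation_index()].
#' @return data.frame with one row per class (`promoter`, `gene_body`,
#'   `intergenic`): `count` and `fraction` (fractions sum to 1).
#' @export
summarize_regions <- function(x, index) {
  stopifnot(nrow(x) >= 1L)
  cls <- factor(classify_intervals(x, index),
                levels = c("promoter", "gene_body", "intergenic"))
  counts <- as.integer(table(cls))
  data.frame(class = levels(cls), count = counts,
             fraction = counts / nrow(x), stringsAsFactors = FALSE)
}

#' Generate length-matched random peaks
#'
#' Draws peak lengths with replacement from an empirical length sample
#' (typically ZFS lengths) and places each peak uniformly over the genome:
#' chromosome chosen proportionally to its size, start uniform, redrawn if
#' the peak would overrun the chromosome end. Deterministic given the seed.
#'
#' @param n number of peaks.
#' @param length_sample non-empty integer vector of lengths to draw from.
#' @param chrom_sizes named integer vector of chromosome sizes.
#' @param seed integer seed.
#' @return Interval data.frame of `n` random peaks (named `rp1..rpn`).
#' @export
generate_random_peaks <- function(n, length_sample, chrom_sizes, seed) {
  stopifnot(n >= 0, length(length_sample) >= 1L)
  if (max(length_sample) > max(chrom_sizes))
    stop("length sample contains a value larger than any chromosome")
  if (n == 0L)
    return(genomic_intervals(character(0), integer(0), integer(0)))
  withr::with_seed(seed, {
    len <- sample(as.integer(length_sample), n, replace = TRUE)
    chrom <- sample(names(chrom_sizes), n, replace = TRUE,
                    prob = chrom_sizes / sum(chrom_sizes))
    sz <- as.integer(chrom_sizes[chrom])
    start <- as.integer(floor(stats::runif(n) * sz))
    bad <- which(start + len > sz)
    while (length(bad)) {
      start[bad] <- as.integer(floor(stats::runif(length(bad)) * sz[bad]))
      bad <- bad[start[bad] + len[bad] > sz[bad]]
    }
    genomic_intervals(chrom, start, start + len,
                      name = paste0("rp", seq_len(n)))
  })
}

#' Two-proportion test of ZDR content in ZFSs versus random peaks
#'
#' Compares the fraction of ZFSs containing at least one predicted ZDR with
#' the corresponding fraction of length-matched random peaks: Pearson
#' chi-square test on the 2x2 table and a 99% confidence interval for the
#' difference of proportions.
#'
#' @param k1,n1 ZDR-containing count and total for ZFSs.
#' @param k2,n2 ZDR-containing count and total for random peaks.
#' @return List with `f1`, `f2`, `ratio` (`f1/f2`, `NA` if `f2 == 0`),
#'   `p_chisq` and `ci99` (99% CI for `f1 - f2`).
#' @export
#' @examples
#' zdr_enrichment_test(197, 391, 1009, 10000)$ratio  # about 5
zdr_enrichment_test <- function(k1, n1, k2, n2) {
  stopifnot(k1 >= 0, k1 <= n1, n1 > 0, k2 >= 0, k2 <= n2, n2 > 0)
  f1 <- k1 / n1
  f2 <- k2 / n2
  ratio <- if (f2 == 0) {
    warning("random-peak ZDR fraction is zero; ratio undefined")
    NA_real_
  } else f1 / f2
  pt <- suppressWarnings(
    stats::prop.test(c(k1, k2), c(n1, n2), conf.level = 0.99,
                     correct = FALSE))
  list(f1 = f1, f2 = f2, ratio = ratio,
       p_chisq = pt$p.value, ci99 = unname(pt$conf.int))
}

#' Nearest gene to an interval
#'
#' Returns the gene minimizing the distance between the interval midpoint
#' and the gene's TSS, with distance 0 when the midpoint falls inside the
#' gene span; ties broken by lexicographically smaller `gene_id`.
#'
#' @param interval single-row interval data.frame.
#' @param genes gene-model data.frame.
#' @return List with `gene_id` and `distance` (bp; `NA`/flagged if no gene
#'   shares the chromosome).
#' @export
nearest_gene <- function(interval, genes) {
  stopifnot(nrow(interval) == 1L)
  g <- genes[genes$chrom == interval$chrom, , drop = FALSE]
  if (nrow(g) == 0L)
    return(list(gene_id = NA_character_, distance = NA_real_,
                unassigned = TRUE))
  mid <- interval_midpoint(interval)
  inside <- mid >= g$start & mid < g$end
  d <- ifelse(inside, 0, abs(mid - gene_tss(g)))
  o <- order(d, g$gene_id)
  list(gene_id = g$gene_id[o[1]], distance = d[o[1]], unassigned = FALSE)
}
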