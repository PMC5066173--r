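#' Reads per kilobase of exon per million aligned tags
#'
#' @param exon_reads reads falling in the gene's exons.
#' @param exon_length_bp total exon length, bp (> 0).
#' @param total_mapped total aligned tags in the library (> 0).
#' @return RPKM: `exon_reads * 1e9 / (exon_length_bp * total_mapped)`.
#' @export
#' @examples
#' compute_rpkm(10, 2000, 1e6)  # 5
compute_rpkm <- function(exon_reads, exon_length_bp, total_mapped) {
  if (any(exon_length_bp <= 0)) stop("exon length must be positive")
  if (any(total_mapped <= 0)) stop("library size must be positive")
  exon_reads * 1e9 / (exon_length_bp * total_mapped)
}

#' Assign genes to expression groups
#'
#' `top` = the `n_top` highest-RPKM genes; `bottom` = all unexpressed genes
#' (RPKM = 0); `mid` = `n_mid` genes drawn at evenly spaced ranks from the
#' expressed genes strictly between top and bottom; everything else `none`.
#'
#' @param expression data.frame with columns `gene_id` and `rpkm`.
#' @param n_top,n_mid group sizes.
#' @return The input with a `group` column added.
#' @export
assign_groups <- function(expression, n_top = 1000L, n_mid = 1000L) {
  stopifnot(all(c("gene_id", "rpkm") %in% names(expression)))
  pos <- which(expression$rpkm > 0)
  if (length(pos) < n_top)
    stop("fewer than n_top (", n_top, ") genes with rpkm > 0: ",
         length(pos))
  o <- pos[order(-expression$rpkm[pos], expression$gene_id[pos])]
  group <- rep("none", nrow(expression))
  group[expression$rpkm == 0] <- "bottom"
  group[o[seq_len(n_top)]] <- "top"
  inter <- o[-seq_len(n_top)]
  if (length(inter) && n_mid > 0) {
    k <- min(n_mid, length(inter))
    pick <- inter[unique(round(seq(1, length(inter), length.out = k)))]
    group[pick] <- "mid"
  }
  expression$group <- group
  expression
}

# Bin read 5' ends around anchor points, strand-oriented. Returns an
# n_anchor x n_bin count matrix. Anchors: data.frame(chrom, pos, strand).
bin_reads_around <- function(reads, anchors, flank, bin) {
  n_bin <- as.integer(ceiling(2 * flank / bin))
  mat <- matrix(0, nrow = nrow(anchors), ncol = n_bin)
  if (nrow(reads) == 0L || nrow(anchors) == 0L) return(mat)
  p5 <- read_pos5(reads)
  for (ch in unique(anchors$chrom)) {
    ai <- which(anchors$chrom == ch)
    rp <- p5[reads$chrom == ch]
    if (!length(rp)) next
    rp <- sort(rp)
    for (j in ai) {
      rel <- rp - anchors$pos[j]
      if (!is.na(anchors$strand[j]) && anchors$strand[j] == "-") rel <- -rel
      b <- floor((rel + flank) / bin) + 1
      b <- b[b >= 1 & b <= n_bin]
      if (length(b)) mat[j, ] <- mat[j, ] + tabulate(b, nbins = n_bin)
    }
  }
  mat
}

#' TSS metaprofiles by expression group
#'
#' Counts read 5' ends in fixed bins around every gene's TSS
#' (strand-oriented, minus-strand genes flipped), normalizes to reads per
#' million mapped, and averages within each expression group. A per-bin
#' two-sided Mann-Whitney test between the top and bottom groups gives the
#' significance mask.
#'
#' @param reads read interval data.frame.
#' @param genes gene-model data.frame.
#' @param groups character vector of group labels aligned with `genes`.
#' @param flank half-width around the TSS, bp.
#' @param bin bin width, bp.
#' @param total_mapped library size used for per-million normalization
#'   (default: `nrow(reads)`).
#' @return List of class `tss_profile`: `offsets` (bin start offsets),
#'   `profiles` (matrix group x bin of mean normalized counts), `p_top_bottom`
#'   (per-bin Mann-Whitney p, `NA` where a group is empty).
#' @export
tss_profile <- function(reads, genes, groups, flank = 5000L, bin = 50L,
                        total_mapped = NULL) {
  stopifnot(length(groups) == nrow(genes))
  if (is.null(total_mapped)) total_mapped <- nrow(reads)
  if (nrow(reads) == 0L) warning("empty read set; zero profiles")
  anchors <- data.frame(chrom = genes$chrom, pos = gene_tss(genes),
                        strand = genes$strand, stringsAsFactors = FALSE)
  counts <- bin_reads_around(reads, anchors, flank, bin)
  norm <- counts * 1e6 / max(total_mapped, 1)
  lv <- intersect(c("top", "mid", "bottom", "none"), unique(groups))
  profiles <- t(vapply(lv, function(g)
    colMeans(norm[groups == g, , drop = FALSE]), numeric(ncol(norm))))
  rownames(profiles) <- lv
  n_bin <- ncol(norm)
  p <- rep(NA_real_, n_bin)
  ti <- which(groups == "top"); bi <- which(groups == "bottom")
  if (length(ti) >= 2L && length(bi) >= 2L) {
    for (b in seq_len(n_bin)) {
      x <- norm[ti, b]; y <- norm[bi, b]
      if (length(unique(c(x, y))) > 1L)
        p[b] <- suppressWarnings(
          stats::wilcox.test(x, y, exact = FALSE)$p.value)
    }
  }
  structure(list(offsets = seq(-flank, flank - bin, by = bin),
                 profiles = profiles, p_top_bottom = p,
                 flank = flank, bin = bin),
            class = "tss_profile")
}

#' Enrichment matrices over ZFSs for a panel of marks
#'
#' For each mark, counts read 5' ends in fixed bins across every ZFS
#' midpoint plus/minus `flank`, normalized to reads per million mapped.
#' Rows (ZFSs) are ordered identically in all matrices, by decreasing
#' probe (Zaa) enrichment computed as the normalized read count in the same
#' window.
#'
#' @param marks named list of read interval data.frames (one per mark).
#' @param zfs interval data.frame of ZFSs.
#' @param zaa_reads read set used to rank ZFSs by enrichment.
#' @param flank half-width around ZFS midpoints, bp.
#' @param bin bin width, bp.
#' @return List of class `zfs_heatmap`: `matrices` (named list, rows in
#'   ranked order), `order` (ZFS row permutation), `enrichment` (per-ZFS
#'   normalized Zaa counts, in input order).
#' @export
zfs_heatmap_matrix <- function(marks, zfs, zaa_reads, flank = 3000L,
                               bin = 50L) {
  stopifnot(nrow(zfs) >= 1L)
  anchors <- data.frame(chrom = zfs$chrom, pos = interval_midpoint(zfs),
                        strand = ".", stringsAsFactors = FALSE)
  zaa <- bin_reads_around(zaa_reads, anchors, flank, bin)
  enrich <- rowSums(zaa) * 1e6 / max(nrow(zaa_reads), 1)
  o <- order(-enrich)
  mats <- lapply(marks, function(r) {
    m <- bin_reads_around(r, anchors, flank, bin) * 1e6 / max(nrow(r), 1)
    m[o, , drop = FALSE]
  })
  structure(list(matrices = mats, order = o, enrichment = enrich,
                 offsets = seq(-flank, flank - bin, by = bin)),
            class = "zfs_heatmap")
}

#' Overlap of ZFSs with another peak set, with Fisher's exact test
#'
#' Counts ZFSs overlapping the other peak set (any overlap) and compares
#' against length-matched random peaks via a two-sided Fisher's exact test
#' on the 2x2 table {ZFS, random} x {overlapping, not}.
#'
#' @param zfs interval data.frame (non-empty).
#' @param other_peaks interval data.frame (e.g. Pol II peaks).
#' @param random_peaks interval data.frame of matched random peaks.
#' @return List with `overlap`, `fraction`, `p_fisher`, and the random-peak
#'   counterpart counts.
#' @export
overlap_fisher <- function(zfs, other_peaks, random_peaks) {
  if (nrow(zfs) == 0L) stop("empty ZFS set")
  ov_z <- sum(overlaps_any(zfs, other_peaks))
  ov_r <- sum(overlaps_any(random_peaks, other_peaks))
  tab <- matrix(c(ov_z, nrow(zfs) - ov_z,
                  ov_r, nrow(random_peaks) - ov_r), nrow = 2, byrow = TRUE)
  list(overlap = ov_z, fraction = ov_z / nrow(zfs),
       random_overlap = ov_r,
       random_fraction = ov_r / nrow(random_peaks),
       p_fisher = stats::fisher.test(tab)$p.value)
}

#' Expression stratified by ZFS location
#'
#' Strata are: genes with a ZFS (midpoint) in their promoter, genes with a
#' ZFS in their gene body (promoter precedence applied, exclusive), and all
#' genes. Two-sided Mann-Whitney tests compare promoter vs gene body,
#' total vs gene body, and total vs promoter RPKM distributions.
#'
#' @param expression data.frame with `gene_id` and `rpkm`.
#' @param gene_class named character vector: for each gene with a ZFS, its
#'   stratum (`"promoter"` or `"gene_body"`), names = gene ids (see
#'   [strata_from_zfs()]).
#' @return data.frame with one row per comparison: `comparison`, `p`,
#'   `median_1`, `median_2`, `skipped`.
#' @export
expression_by_location <- function(expression, gene_class) {
  rp <- stats::setNames(expression$rpkm, expression$gene_id)
  prom <- rp[names(gene_class)[gene_class == "promoter"]]
  body <- rp[names(gene_class)[gene_class == "gene_body"]]
  all_g <- rp
  one <- function(label, x, y) {
    if (length(x) < 2L || length(y) < 2L)
      return(data.frame(comparison = label, p = NA_real_,
                        median_1 = NA_real_, median_2 = NA_real_,
                        skipped = TRUE))
    p <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
    data.frame(comparison = label, p = p,
               median_1 = stats::median(x), median_2 = stats::median(y),
               skipped = FALSE)
  }
  rbind(one("promoter_vs_gene_body", prom, body),
        one("total_vs_gene_body", all_g, body),
        one("total_vs_promoter", all_g, prom))
}

#' Per-gene ZFS stratum (promoter or gene body)
#'
#' A gene is in the promoter stratum if any ZFS midpoint lies in its
#' promoter window; otherwise in the gene-body stratum if any ZFS midpoint
#' lies within its span (promoter precedence; a gene appears once).
#'
#' @param zfs interval data.frame of ZFSs.
#' @param index an [annotation_index()].
#' @return Named character vector of strata, names = gene ids.
#' @export
strata_from_zfs <- function(zfs, index) {
  mid <- interval_midpoint(zfs)
  pts <- data.frame(chrom = zfs$chrom, start = mid, end = mid + 1L,
                    stringsAsFactors = FALSE)
  ph <- overlap_hits(pts, index$promoters)
  bh <- overlap_hits(pts, index$bodies)
  prom_genes <- unique(index$promoters$name[ph$s])
  body_genes <- setdiff(unique(index$bodies$name[bh$s]), prom_genes)
  c(stats::setNames(rep("promoter", length(prom_genes)), prom_genes),
    stats::setNames(rep("gene_body", length(body_genes)), body_genes))
}

#' Reporter fold change
#'
#' Fold change of relative luciferase activity: each construct is
#' normalized to the empty-vector baseline, then the ZFS construct is
#' divided by the negative control. The baseline cancels algebraically.
#'
#' @param luc_zfs,luc_negative,luc_baseline positive luciferase activities.
#' @return `(luc_zfs / luc_baseline) / (luc_negative / luc_baseline)`.
#' @export
#' @examples
#' reporter_fold_change(8, 2, 4)  # 4
reporter_fold_change <- function(luc_zfs, luc_negative, luc_baseline) {
  if (any(c(luc_zfs, luc_negative, luc_baseline) <= 0))
    stop("luciferase activities must be positive")
  (luc_zfs / luc_baseline) / (luc_negative / luc_baseline)
}
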