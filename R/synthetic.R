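# Synthetic study generator: a toy genome with gene models, planted
# Z-forming repeats at promoters (and a configurable fraction inside gene
# bodies), replicated ChIP read sets with background controls, and
# expression tied to gene activity -- with full ground truth, so every
# pipeline stage can be scored without external data.

zdr_insert_seqs <- function() {
  c(CG12 = strrep("CG", 12),
    CA14 = strrep("CA", 14),
    CGGG6 = strrep("CGGG", 6),
    NONALT = strrep("GGAA", 6))  # no Pu/Py alternation: never a ZDR
}

#' Generate a synthetic genome, gene models and planted truth
#'
#' Background sequence is i.i.d. at the stated GC content. Genes are placed
#' on a regular grid with jitter (non-overlapping). A fraction of active
#' genes receives a planted Z-forming insert -- drawn from (CG)12, (CA)14,
#' (CGGG)6 or a non-alternating control repeat -- either near the TSS
#' (promoter placement) or deep inside the gene body; every insert defines
#' a planted ZFS with a known ChIP enrichment fold. Deterministic given the
#' seed.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_bp chromosome length, bp. The default gives one gene per
#'   80 kb, so that promoters cover only a few percent of the genome --
#'   without this sparseness (comparable to real mammalian gene density)
#'   promoter enrichment of planted sites over a random null cannot
#'   manifest.
#' @param n_genes total number of genes (divided evenly across
#'   chromosomes).
#' @param gc GC content of the background sequence.
#' @param frac_active fraction of genes transcriptionally active.
#' @param frac_sites fraction of active genes receiving a planted site.
#' @param site_promoter_frac fraction of planted sites placed at promoters
#'   (within TSS +/- 500 bp); the remainder go inside gene bodies (> 2 kb
#'   from the TSS).
#' @param fold mean ChIP enrichment fold of planted sites; per-site folds
#'   are drawn uniformly in `fold * (1 +/- fold_jitter)` and recorded in
#'   the truth.
#' @param fold_jitter relative half-range of per-site fold variation.
#' @param insert_props named proportions of the four insert types.
#' @param zfs_halfwidth half-width of the planted enriched window, bp.
#' @param n_blacklist,blacklist_bp number and size of synthetic blacklist
#'   regions (placed away from planted sites).
#' @param seed integer seed.
#' @return List with `genome` (named character vector), `genes`
#'   (gene-model data.frame), `blacklist` (interval data.frame) and `truth`
#'   (planted ZFSs with folds, inserts with sequences, per-gene activity
#'   and expression means, and the seed).
#' @export
synth_genome <- function(n_chroms = 2L, chrom_bp = 8e6, n_genes = 200L,
                         gc = 0.45, frac_active = 0.5, frac_sites = 0.6,
                         site_promoter_frac = 0.75, fold = 8,
                         fold_jitter = 0.25,
                         insert_props = c(CG12 = 0.4, CA14 = 0.3,
                                          CGGG6 = 0.2, NONALT = 0.1),
                         zfs_halfwidth = 200L, n_blacklist = 5L,
                         blacklist_bp = 1000L, seed = 1L) {
  stopifnot(n_chroms >= 1, chrom_bp > 0, n_genes >= n_chroms, fold > 0)
  gpc <- n_genes %/% n_chroms
  spacing <- as.integer(chrom_bp) %/% gpc
  if (spacing < 8000L)
    stop("too many genes for the genome size (need >= 8 kb per gene slot)")
  withr::with_seed(seed, {
    base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    chroms <- paste0("chr", seq_len(n_chroms))
    genome <- stats::setNames(vapply(chroms, function(ch)
      paste(sample(names(base_p), chrom_bp, replace = TRUE, prob = base_p),
            collapse = ""), character(1)), chroms)

    # gene grid with jitter
    rows <- list()
    for (ci in seq_len(n_chroms)) {
      for (gi in seq_len(gpc)) {
        slot <- (gi - 1L) * spacing
        len <- as.integer(round(stats::runif(1, 4000, min(7000, spacing - 3000))))
        off <- as.integer(round(stats::runif(1, 1000, spacing - len - 1000)))
        start <- slot + off
        strand <- sample(c("+", "-"), 1L)
        k <- sample(2:4, 1L)
        block <- len %/% k
        es <- start + (seq_len(k) - 1L) * block
        ee <- es + as.integer(round(block * stats::runif(k, 0.4, 0.8)))
        rows[[length(rows) + 1L]] <- list(
          gene_id = sprintf("g%03d", (ci - 1L) * gpc + gi),
          chrom = chroms[ci], strand = strand,
          start = start, end = start + len,
          exon_starts = as.integer(es), exon_ends = as.integer(ee))
      }
    }
    genes <- data.frame(
      gene_id = vapply(rows, `[[`, character(1), "gene_id"),
      chrom = vapply(rows, `[[`, character(1), "chrom"),
      strand = vapply(rows, `[[`, character(1), "strand"),
      start = vapply(rows, `[[`, integer(1), "start"),
      end = vapply(rows, `[[`, integer(1), "end"),
      stringsAsFactors = FALSE)
    genes$exon_starts <- lapply(rows, `[[`, "exon_starts")
    genes$exon_ends <- lapply(rows, `[[`, "exon_ends")
    genes$tss <- gene_tss(genes)
    genes$exon_length <- vapply(seq_len(nrow(genes)), function(i)
      sum(genes$exon_ends[[i]] - genes$exon_starts[[i]]), integer(1))

    ng <- nrow(genes)
    active <- rep(FALSE, ng)
    active[sample.int(ng, round(frac_active * ng))] <- TRUE
    act_idx <- which(active)
    n_sites <- round(frac_sites * length(act_idx))
    site_genes <- sample(act_idx, n_sites)
    n_prom <- round(site_promoter_frac * n_sites)
    placement <- rep("gene_body", n_sites)
    placement[seq_len(n_prom)] <- "promoter"
    ins_seqs <- zdr_insert_seqs()
    ins_type <- sample(names(insert_props), n_sites, replace = TRUE,
                       prob = insert_props)
    site_fold <- fold * stats::runif(n_sites, 1 - fold_jitter,
                                     1 + fold_jitter)

    site_rows <- vector("list", n_sites)
    for (s in seq_len(n_sites)) {
      gi <- site_genes[s]
      tss <- genes$tss[gi]
      dirn <- if (genes$strand[gi] == "+") 1L else -1L
      d <- if (placement[s] == "promoter") {
        as.integer(round(stats::runif(1, -500, 500)))
      } else {
        glen <- genes$end[gi] - genes$start[gi]
        dirn * as.integer(round(stats::runif(1, 2500, glen - 300)))
      }
      center <- tss + d
      ins <- ins_seqs[[ins_type[s]]]
      ins_start <- center - nchar(ins) %/% 2L
      ch <- genes$chrom[gi]
      substr(genome[[ch]], ins_start + 1L,
             ins_start + nchar(ins)) <- ins
      site_rows[[s]] <- list(
        chrom = ch, center = center, ins_start = ins_start,
        ins_len = nchar(ins), type = ins_type[s],
        gene_id = genes$gene_id[gi], placement = placement[s])
    }
    zfs <- data.frame(
      chrom = vapply(site_rows, `[[`, character(1), "chrom"),
      start = vapply(site_rows, `[[`, integer(1), "center") - zfs_halfwidth,
      end = vapply(site_rows, `[[`, integer(1), "center") + zfs_halfwidth,
      name = sprintf("site%03d", seq_len(n_sites)),
      score = NA_real_, strand = ".",
      fold = site_fold,
      gene_id = vapply(site_rows, `[[`, character(1), "gene_id"),
      placement = vapply(site_rows, `[[`, character(1), "placement"),
      insert_type = vapply(site_rows, `[[`, character(1), "type"),
      stringsAsFactors = FALSE)
    inserts <- data.frame(
      chrom = zfs$chrom,
      start = vapply(site_rows, `[[`, integer(1), "ins_start"),
      end = vapply(site_rows, `[[`, integer(1), "ins_start") +
        vapply(site_rows, `[[`, integer(1), "ins_len"),
      type = zfs$insert_type,
      seq = unname(ins_seqs[zfs$insert_type]),
      gene_id = zfs$gene_id, stringsAsFactors = FALSE)

    # expression means by placement stratum (silent genes stay at 0)
    meanlog <- ifelse(active, 3.0, NA_real_)
    meanlog[site_genes[placement == "promoter"]] <- 3.8
    meanlog[site_genes[placement == "gene_body"]] <- 2.2
    truth_genes <- data.frame(gene_id = genes$gene_id, active = active,
                              meanlog = meanlog, stringsAsFactors = FALSE)

    # blacklist away from planted sites
    chrom_sizes <- stats::setNames(rep(as.integer(chrom_bp), n_chroms),
                                   chroms)
    bl <- genomic_intervals(character(0), integer(0), integer(0))
    guard <- zfs
    guard$start <- pmax(0L, guard$start - 2000L)
    guard$end <- guard$end + 2000L
    tries <- 0L
    while (nrow(bl) < n_blacklist && tries < 1000L) {
      tries <- tries + 1L
      ch <- sample(chroms, 1L)
      st <- as.integer(floor(stats::runif(1) *
                               (chrom_bp - blacklist_bp)))
      cand <- genomic_intervals(ch, st, st + as.integer(blacklist_bp),
                                name = paste0("bl", nrow(bl) + 1L))
      if (!any(overlaps_any(cand, guard))) bl <- rbind(bl, cand)
    }

    list(genome = genome, genes = genes, blacklist = bl,
         chrom_sizes = chrom_sizes,
         truth = list(zfs = zfs, inserts = inserts, genes = truth_genes,
                      seed = seed, fold = fold))
  })
}

# Draw one sample's reads: background uniform over chromosomes plus
# enrichment mass at planted sites proportional to (fold - 1) x width.
draw_sample_reads <- function(chrom_sizes, sites, depth, frag, read_len,
                              seed) {
  withr::with_seed(seed, {
    w_bg <- as.numeric(chrom_sizes)
    w_site <- if (nrow(sites)) (sites$fold - 1) * (sites$end - sites$start)
              else numeric(0)
    counts <- as.vector(stats::rmultinom(1, depth, c(w_bg, w_site)))
    n_ch <- length(chrom_sizes)
    chs <- character(0); centers <- integer(0)
    for (i in seq_len(n_ch)) {
      k <- counts[i]
      if (!k) next
      chs <- c(chs, rep(names(chrom_sizes)[i], k))
      centers <- c(centers, as.integer(floor(
        stats::runif(k, frag / 2, chrom_sizes[[i]] - frag / 2))))
    }
    for (s in seq_len(nrow(sites))) {
      k <- counts[n_ch + s]
      if (!k) next
      chs <- c(chs, rep(sites$chrom[s], k))
      centers <- c(centers, as.integer(floor(
        stats::runif(k, sites$start[s], sites$end[s]))))
    }
    strand <- sample(c("+", "-"), length(chs), replace = TRUE)
    half <- frag %/% 2L
    start <- ifelse(strand == "+", centers - half,
                    centers + half - read_len)
    sz <- as.integer(chrom_sizes[chs])
    start <- pmax(0L, pmin(as.integer(start), sz - read_len))
    genomic_intervals(chs, start, start + read_len, strand = strand)
  })
}

#' Simulate a replicated ChIP experiment with background controls
#'
#' Treatment replicates draw reads uniformly over the genome plus extra
#' mass at every planted site proportional to its enrichment fold; IgG and
#' input draw background only. Read 5' ends sit at the fragment boundaries
#' so that fragment extension in the caller re-centers coverage on the
#' sites. Each sample contains exactly `depth` reads; per-sample seeds are
#' derived from `seed`.
#'
#' @param synth result of [synth_genome()].
#' @param n_reps number of treatment replicates.
#' @param depth reads per sample.
#' @param frag fragment length, bp.
#' @param read_len read length, bp.
#' @param seed integer seed.
#' @return Named list of read interval data.frames:
#'   `rep1..repN`, `IgG`, `input`.
#' @export
synth_chip_experiment <- function(synth, n_reps = 3L, depth = 400000L,
                                  frag = 150L, read_len = 36L, seed = 1L) {
  stopifnot(depth > 0, n_reps >= 1)
  sizes <- synth$chrom_sizes
  sites <- synth$truth$zfs
  none <- sites[0, , drop = FALSE]
  out <- list()
  for (r in seq_len(n_reps))
    out[[paste0("rep", r)]] <-
      draw_sample_reads(sizes, sites, depth, frag, read_len,
                        derive_seed(seed, r))
  out$IgG <- draw_sample_reads(sizes, none, depth, frag, read_len,
                               derive_seed(seed, 101L))
  out$input <- draw_sample_reads(sizes, none, depth, frag, read_len,
                                 derive_seed(seed, 102L))
  out
}

#' Simulate expression and Pol II peaks tied to the planted truth
#'
#' Active genes draw RPKM from a log-normal with the per-gene mean recorded
#' in the truth (promoter-site genes highest, gene-body-site genes lowest);
#' silent genes have RPKM 0 and never get a Pol II peak. Pol II peaks cover
#' TSS +/- `polii_halfwidth` of active genes, with a dropout fraction.
#'
#' @param synth result of [synth_genome()].
#' @param sdlog log-normal sd of RPKM draws.
#' @param polii_halfwidth Pol II peak half-width around the TSS, bp.
#' @param polii_dropout fraction of active genes without a Pol II peak.
#' @param total_mapped nominal mRNA library size used to back-compute exon
#'   read counts from RPKM.
#' @param seed integer seed.
#' @return List with `expression` (gene_id, exon_reads, rpkm),
#'   `polii_peaks` (interval data.frame) and `total_mapped`.
#' @export
synth_expression <- function(synth, sdlog = 1, polii_halfwidth = 300L,
                             polii_dropout = 0.1, total_mapped = 1e6,
                             seed = 1L) {
  genes <- synth$genes
  tg <- synth$truth$genes
  withr::with_seed(derive_seed(seed, 201L), {
    rpkm <- numeric(nrow(genes))
    act <- tg$active
    rpkm[act] <- stats::rlnorm(sum(act), meanlog = tg$meanlog[act],
                               sdlog = sdlog)
    exon_reads <- as.integer(round(
      rpkm * genes$exon_length * total_mapped / 1e9))
    keep <- which(act)
    if (polii_dropout > 0 && length(keep))
      keep <- keep[stats::runif(length(keep)) >= polii_dropout]
    polii <- if (length(keep)) {
      tss <- genes$tss[keep]
      genomic_intervals(genes$chrom[keep],
                        pmax(0L, tss - as.integer(polii_halfwidth)),
                        tss + as.integer(polii_halfwidth) + 1L,
                        name = genes$gene_id[keep])
    } else genomic_intervals(character(0), integer(0), integer(0))
    list(expression = data.frame(gene_id = genes$gene_id,
                                 exon_reads = exon_reads, rpkm = rpkm,
                                 stringsAsFactors = FALSE),
         polii_peaks = polii, total_mapped = total_mapped)
  })
}

# Deterministic sub-seed derivation; stays below 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 65536) * 32749 + k)
}
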