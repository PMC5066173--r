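test_that("RPKM follows its closed form and invariances", {
  expect_equal(compute_rpkm(0, 1000, 1e6), 0)
  expect_equal(compute_rpkm(10, 2000, 1e6), 5)
  expect_equal(compute_rpkm(20, 2000, 2e6), compute_rpkm(10, 2000, 1e6))
  expect_error(compute_rpkm(1, 0, 1e6), "length")
  expect_error(compute_rpkm(1, 100, 0), "library")
})

test_that("expression groups partition as top / evenly-spaced mid / zero bottom", {
  ex <- data.frame(gene_id = sprintf("g%03d", 1:100),
                   rpkm = c(seq(100, 1, length.out = 60), rep(0, 40)))
  g <- assign_groups(ex, n_top = 20, n_mid = 20)
  expect_equal(sum(g$group == "top"), 20)
  expect_equal(sum(g$group == "mid"), 20)
  expect_equal(sum(g$group == "bottom"), 40)
  expect_true(all(g$rpkm[g$group == "bottom"] == 0))
  expect_true(min(g$rpkm[g$group == "top"]) >=
                max(g$rpkm[g$group %in% c("mid", "none")]))
  # groups depend on ranks only
  ex2 <- ex; ex2$rpkm <- ex2$rpkm * 2
  expect_identical(assign_groups(ex2, 20, 20)$group, g$group)
  expect_error(assign_groups(data.frame(gene_id = "a", rpkm = 0), 10, 10),
               "rpkm > 0")
  expect_error(assign_groups(ex, n_top = 80, n_mid = 10), "n_top")
})

# two-gene fixture for profiles: one plus-strand, one minus-strand
prof_genes <- local({
  g <- data.frame(gene_id = c("gp", "gm"), chrom = "c1",
                  strand = c("+", "-"), start = c(20000L, 60000L),
                  end = c(30000L, 70000L), stringsAsFactors = FALSE)
  g$exon_starts <- as.list(g$start); g$exon_ends <- as.list(g$end)
  g$tss <- gene_tss(g); g$exon_length <- g$end - g$start
  g
})

test_that("TSS profiles are strand-oriented and peak where reads sit", {
  expect_warning(
    p0 <- tss_profile(genomic_intervals(character(0), integer(0),
                                        integer(0)),
                      prof_genes, c("top", "bottom"), flank = 1000L,
                      bin = 50L, total_mapped = 1),
    "empty")
  expect_true(all(p0$profiles == 0))

  # reads 200 bp downstream of each TSS (strand-aware)
  dn_plus <- genomic_intervals("c1", 20200L, 20236L, strand = "+")
  dn_minus <- genomic_intervals("c1", 69763L, 69799L, strand = "-")
  reads <- rbind(dn_plus[rep(1, 50), ], dn_minus[rep(1, 50), ])
  p <- tss_profile(reads, prof_genes, c("top", "top"), flank = 1000L,
                   bin = 50L, total_mapped = 100)
  target_bin <- which(p$offsets == 200)
  expect_equal(unname(which.max(p$profiles["top", ])), target_bin)
  # both genes land in the same oriented bin: 50 reads each, per-million
  # normalized by the 100-read library, averaged over the 2 genes
  expect_equal(unname(p$profiles["top", target_bin]), 50 * 1e6 / 100)
})

test_that("top-vs-bottom bin significance reflects planted contrast", {
  genes <- do.call(rbind, lapply(0:19, function(i) {
    g <- prof_genes[1, ]
    g$gene_id <- paste0("g", i)
    g$start <- 5000L + i * 4000L; g$end <- g$start + 2000L
    g$tss <- g$start
    g
  }))
  genes$exon_starts <- as.list(genes$start)
  genes$exon_ends <- as.list(genes$end)
  groups <- rep(c("top", "bottom"), each = 10)
  top_tss <- genes$tss[groups == "top"]
  reads <- withr::with_seed(71, {
    pos <- rep(top_tss, each = 30) +
      as.integer(round(stats::rnorm(300, 0, 30)))
    genomic_intervals("c1", pos, pos + 36L, strand = "+")
  })
  p <- tss_profile(reads, genes, groups, flank = 500L, bin = 50L)
  center <- which(p$offsets == 0)
  expect_gt(p$profiles["top", center], 0)
  expect_equal(unname(p$profiles["bottom", center]), 0)
  expect_lt(p$p_top_bottom[center], 0.05)
})

test_that("heatmap rows are ordered by probe enrichment and match a recount", {
  zfs <- genomic_intervals("c1", seq(10000L, 100000L, by = 10000L),
                           seq(10400L, 100400L, by = 10000L))
  n <- nrow(zfs)
  strength <- withr::with_seed(72, sample(10:300, n))
  zaa <- do.call(rbind, lapply(seq_len(n), function(i) {
    mid <- (zfs$start[i] + zfs$end[i]) %/% 2L
    genomic_intervals("c1", rep(mid, strength[i]), rep(mid + 36L,
                                                       strength[i]),
                      strand = "+")
  }))
  hm <- zfs_heatmap_matrix(list(zaa = zaa), zfs, zaa, flank = 1000L,
                           bin = 50L)
  expect_equal(hm$order, order(-strength))
  m <- hm$matrices$zaa
  center_cols <- which(abs(hm$offsets) <= 50)
  expect_gt(mean(m[, center_cols]), 10 * mean(m[, -center_cols]))

  # near-uniform reads give no column structure
  ur <- uniform_reads(20000, c(c1 = 120000L), seed = 73)
  hu <- zfs_heatmap_matrix(list(u = ur), zfs, ur, flank = 1000L, bin = 50L)
  cm <- colMeans(hu$matrices$u)
  expect_lt(stats::sd(cm) / mean(cm), 0.25)
})

test_that("overlap testing equals hypergeometric enumeration at small n", {
  zfs <- genomic_intervals("c1", seq(0L, 19000L, by = 1000L),
                           seq(200L, 19200L, by = 1000L))
  expect_equal(overlap_fisher(zfs, zfs, zfs[1:5, ])$fraction, 1)
  far <- zfs; far$start <- far$start + 500L; far$end <- far$end + 500L
  expect_equal(overlap_fisher(zfs, far[0, ], far)$overlap, 0)

  other <- zfs[c(1:8), ]
  random <- far[1:10, ]
  got <- overlap_fisher(zfs, other, random)
  a <- got$overlap; b <- nrow(zfs) - a
  c2 <- got$random_overlap; d <- nrow(random) - c2
  expect_equal(got$p_fisher, oracle_fisher_p(a, b, c2, d),
               tolerance = 1e-9)
  expect_error(overlap_fisher(zfs[0, ], other, random), "empty")
})

test_that("location-stratified expression tests behave and match U counting", {
  ex <- data.frame(gene_id = sprintf("g%02d", 1:40),
                   rpkm = withr::with_seed(74, stats::rlnorm(40, 2, 1)))
  # identical strata -> p near 1
  res_id <- expression_by_location(
    ex, stats::setNames(rep(c("promoter", "gene_body"), each = 10),
                        rep(ex$gene_id[1:10], 2)))
  expect_gt(res_id$p[res_id$comparison == "promoter_vs_gene_body"], 0.9)

  # dominating promoter stratum -> small p, direction via medians
  ex2 <- ex
  ex2$rpkm[1:10] <- ex2$rpkm[1:10] + 100
  cls <- stats::setNames(rep(c("promoter", "gene_body"), each = 10),
                         ex$gene_id[1:20])
  res <- expression_by_location(ex2, cls)
  pvb <- res[res$comparison == "promoter_vs_gene_body", ]
  expect_lt(pvb$p, 0.01)
  expect_gt(pvb$median_1, pvb$median_2)

  # U from explicit pair counting reproduces the test statistic's p
  x <- ex2$rpkm[1:10]; y <- ex2$rpkm[11:20]
  u <- oracle_u_stat(x, y)
  w <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
  expect_equal(unname(w$statistic), u)

  skipped <- expression_by_location(
    ex, stats::setNames("promoter", ex$gene_id[1]))
  expect_true(all(skipped$skipped[
    skipped$comparison == "promoter_vs_gene_body"]))
})

test_that("reporter fold change divides out the baseline", {
  expect_equal(reporter_fold_change(2, 2, 5), 1)
  expect_equal(reporter_fold_change(8, 2, 4), 4)
  expect_equal(reporter_fold_change(8, 2, 4), reporter_fold_change(8, 2, 99))
  expect_error(reporter_fold_change(1, 0, 1), "positive")
})
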