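sizes <- c(chrA = 100000L)
pcfg <- pipeline_config(seed = 1)

# reads with a 10x-density planted region on a uniform background
planted_reads <- function(n_bg, region = c(40000L, 40500L), fold = 10,
                          seed = 1, read_len = 36L) {
  bg <- uniform_reads(n_bg, sizes, seed = seed, read_len = read_len)
  n_extra <- as.integer(round((fold - 1) * n_bg *
                                (region[2] - region[1]) / sizes[[1]]))
  withr::with_seed(seed + 1, {
    start <- as.integer(floor(stats::runif(n_extra, region[1],
                                           region[2] - read_len)))
    extra <- genomic_intervals("chrA", start, start + read_len,
                               strand = sample(c("+", "-"), n_extra,
                                               replace = TRUE))
  })
  rbind(bg, extra)
}

test_that("matched treatment and control yield no peaks", {
  tr <- uniform_reads(20000, sizes, seed = 2)
  ct <- uniform_reads(20000, sizes, seed = 3)
  expect_equal(nrow(call_enriched_windows(tr, ct, sizes, pcfg)), 0)
})

test_that("a planted 10x region is recovered as one covering peak", {
  tr <- planted_reads(5000, seed = 7)
  ct <- uniform_reads(5000, sizes, seed = 8)
  pk <- call_enriched_windows(tr, ct, sizes, pcfg)
  expect_equal(nrow(pk), 1)
  overlap <- min(pk$end, 40500) - max(pk$start, 40000)
  expect_gte(overlap / 500, 0.8)
  expect_equal(pk$rank, 1L)

  # doubling both depths moves peak edges by at most one bin
  pk2 <- call_enriched_windows(rbind(tr, planted_reads(5000, seed = 17)),
                               rbind(ct, uniform_reads(5000, sizes,
                                                       seed = 18)),
                               sizes, pcfg)
  best2 <- pk2[1, ]
  expect_lte(abs(best2$start - pk$start), pcfg$bin_bp)
  expect_lte(abs(best2$end - pk$end), pcfg$bin_bp)
})

test_that("caller validates inputs", {
  ct <- uniform_reads(100, sizes, seed = 4)
  expect_warning(out <- call_enriched_windows(ct[0, ], ct, sizes, pcfg),
                 "empty treatment")
  expect_equal(nrow(out), 0)
  bad <- genomic_intervals("chrX", 0L, 36L)
  expect_error(call_enriched_windows(bad, ct, sizes, pcfg),
               "absent from sizes")
})

test_that("pseudoreplicate splits are equal, disjoint, exhaustive and seeded", {
  r <- uniform_reads(10, sizes, seed = 5)
  h <- split_pseudoreplicate(r, 42)
  expect_equal(nrow(h$half_A), 5)
  expect_equal(nrow(h$half_B), 5)
  r11 <- uniform_reads(11, sizes, seed = 6)
  h11 <- split_pseudoreplicate(r11, 42)
  expect_setequal(c(nrow(h11$half_A), nrow(h11$half_B)), c(5, 6))
  key <- function(x) sort(paste(x$chrom, x$start, x$strand))
  expect_setequal(c(key(h11$half_A), key(h11$half_B)), key(r11))
  h_rep <- split_pseudoreplicate(r11, 42)
  expect_identical(h11$half_A, h_rep$half_A)
  h_other <- split_pseudoreplicate(r11, 43)
  expect_false(identical(h11$half_A, h_other$half_A))
  expect_error(split_pseudoreplicate(r[1, ], 1), "at least 2")
})

test_that("peak matching is one-to-one by overlap, greedy by combined rank", {
  pk <- data.frame(chrom = "chrA", start = c(100L, 900L, 2000L),
                   end = c(300L, 1100L, 2300L), score = c(9, 5, 3),
                   rank = 1:3)
  m <- match_peak_pairs(pk, pk)
  expect_equal(nrow(m), 3)
  expect_equal(m$score1, m$score2)

  far <- pk; far$start <- far$start + 10000L; far$end <- far$end + 10000L
  expect_equal(nrow(match_peak_pairs(pk, far)), 0)

  shifted <- pk; shifted$start <- shifted$start + 50L
  shifted$end <- shifted$end + 50L
  m1 <- match_peak_pairs(pk, shifted)
  m2 <- match_peak_pairs(shifted, pk)
  expect_equal(nrow(m1), 3)
  expect_equal(m1$i1, m2$i2[order(m2$i2)])  # order-independent pairing
})

test_that("IDR separates reproducible from independent rank structure", {
  d <- simulate_idr_pairs(300, 1, 0.95, seed = 11)
  f <- fit_idr(d$s1, d$s2)
  expect_gte(mean(f$global_idr <= 0.05), 0.95)

  d0 <- simulate_idr_pairs(300, 0, 0.95, seed = 12)
  f0 <- fit_idr(d0$s1, d0$s2)
  expect_lte(mean(f0$global_idr <= 0.05), 0.05)

  expect_error(fit_idr(rnorm(30), rnorm(30)), ">= 50")
  expect_error(fit_idr(rep(1, 60), rep(1, 60)), "tied")
})

test_that("IDR EM recovers the generating mixture parameters", {
  d <- simulate_idr_pairs(5000, 0.7, 0.8, seed = 13)
  f <- fit_idr(d$s1, d$s2)
  expect_lt(abs(f$p_repro - 0.7), 0.05)
  expect_lt(abs(f$rho - 0.8), 0.1)
})

test_that("reproducible counting equals a sort-and-filter oracle", {
  d <- simulate_idr_pairs(400, 0.6, 0.85, seed = 14)
  f <- fit_idr(d$s1, d$s2)
  for (thr in c(0.01, 0.05, 0.2)) {
    gl <- sort(f$local_idr)
    oracle <- sum(cumsum(gl) / seq_along(gl) <= thr)
    expect_equal(count_reproducible(f, thr), oracle)
  }
  expect_equal(count_reproducible(f, 1 - 1e-9), 400)
  tiny <- min(f$global_idr) / 2
  if (tiny > 0) expect_equal(count_reproducible(f, tiny), 0)
  expect_error(count_reproducible(f, 0), "in \\(0, 1\\)")
})

test_that("the consistency cutoff is the maximum pairwise count", {
  expect_equal(select_cutoff(c(197, 229, 427)), 427L)
  expect_equal(select_cutoff(c(5, 5, 5)), 5L)
  expect_equal(select_cutoff(c(0, 0, 3)), 3L)
})

test_that("finalizing applies top-N then blacklist, as in the worked counts", {
  n <- 427
  pk <- data.frame(chrom = "chrA", start = seq(0L, by = 1000L,
                                               length.out = n + 50),
                   end = seq(400L, by = 1000L, length.out = n + 50),
                   score = rev(seq_len(n + 50)), rank = seq_len(n + 50))
  bl_rows <- sample(seq_len(n), 36)
  blacklist <- genomic_intervals("chrA", pk$start[bl_rows] + 10L,
                                 pk$start[bl_rows] + 20L)
  zfs <- finalize_zfs(pk, n, blacklist)
  expect_equal(nrow(zfs), 391)
  expect_true(all(diff(zfs$start) > 0))

  empty_bl <- genomic_intervals(character(0), integer(0), integer(0))
  expect_equal(nrow(finalize_zfs(pk, n, empty_bl)), n)
  whole <- genomic_intervals("chrA", 0L, 10000000L)
  expect_warning(all_gone <- finalize_zfs(pk, n, whole), "blacklist")
  expect_equal(nrow(all_gone), 0)
  expect_error(finalize_zfs(pk, nrow(pk) + 1, empty_bl), "exceeds")
})

test_that("sample correlations are Pearson on per-ZFS counts", {
  zfs <- genomic_intervals("chrA", seq(0L, 90000L, by = 10000L),
                           seq(500L, 90500L, by = 10000L))
  r1 <- planted_reads(3000, seed = 21)
  r2 <- rbind(r1, r1)  # doubled depth: identical count pattern scaled
  m <- correlate_samples(list(a = r1, b = r2), zfs)
  expect_equal(m["a", "a"], 1)
  expect_equal(m["a", "b"], 1)
  expect_true(isSymmetric(m))
  flat <- genomic_intervals("chrA", c(95000L, 96000L), c(95010L, 96010L))
  expect_warning(correlate_samples(list(a = r1[1:5, ], b = r1[6:10, ]),
                                   flat), "zero-variance")
})
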