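cfg <- energetics_config()

test_that("transition free energy matches the brute-force table oracle", {
  expect_equal(delta_g_bz("CGCGCGCG", 0L, cfg),
               oracle_delta_g("CGCGCGCG", 0L, cfg))
  expect_equal(delta_g_bz("CGCGCGCG", 1L, cfg),
               oracle_delta_g("CGCGCGCG", 1L, cfg))
  # one-dinucleotide segment: min over phases = favourable entry + both
  # junctions
  expect_equal(min(delta_g_bz("CG", 0L, cfg), delta_g_bz("CG", 1L, cfg)),
               cfg$dg_favorable[["CG"]] + 2 * cfg$dg_junction)
  for (s in 1:20) {
    seg <- random_dna(2 * sample(3:20, 1), seed = 500 + s)
    ph <- sample(0:1, 1)
    expect_equal(delta_g_bz(seg, ph, cfg), oracle_delta_g(seg, ph, cfg))
  }
  expect_error(delta_g_bz("ACG", 0L, cfg), "even")
  expect_error(delta_g_bz("ACGN", 0L, cfg), "non-ACGT")
  # transition always costs energy at sigma = 0
  for (s in 1:10)
    expect_gt(delta_g_bz(random_dna(20, seed = 600 + s), 0L, cfg), 0)
})

test_that("per-dinucleotide energies follow the Z-forming propensity order", {
  per_dinuc <- function(repeat_unit, n) {
    seg <- strrep(repeat_unit, n)
    (min(delta_g_bz(seg, 0L, cfg), delta_g_bz(seg, 1L, cfg)) -
       2 * cfg$dg_junction) / (nchar(seg) / 2)
  }
  gc <- per_dinuc("GC", 10); ca <- per_dinuc("CA", 10)
  at <- per_dinuc("AT", 10)
  expect_lt(gc, ca)
  expect_lt(ca, at)
})

test_that("closed-form sigma agrees with numeric root finding", {
  for (s in 1:100) {
    seg <- random_dna(20, seed = 700 + s)
    expect_lt(abs(sigma_required(seg, cfg) - oracle_sigma_root(seg, cfg)),
              1e-6)
  }
})

test_that("sigma ordering, cutoff direction and repeat-length behaviour", {
  s_gc <- sigma_required(strrep("GC", 10), cfg)
  s_ca <- sigma_required(strrep("CA", 10), cfg)
  s_at <- sigma_required(strrep("AT", 10), cfg)
  expect_true(all(c(s_gc, s_ca, s_at) < 0))
  expect_gt(s_gc, s_ca)  # closer to zero = more Z-prone
  expect_gt(s_ca, s_at)

  # a window needing sigma = -0.075 forms at -0.08 but not at -0.07
  expect_true(-0.075 >= -0.08)
  expect_false(-0.075 >= -0.07)

  # (CG)n: sigma moves toward zero with repeat count, then flattens
  sig <- vapply(6:25, function(m) sigma_required(strrep("CG", m), cfg),
                numeric(1))
  expect_true(all(diff(sig) >= 0))
  expect_lt(diff(sig)[19], diff(sig)[1])  # amortized junction cost

  # doubling the junction penalty never helps
  cfg2 <- energetics_config(dg_junction = 2 * cfg$dg_junction)
  for (s in 1:10) {
    seg <- random_dna(24, seed = 800 + s)
    expect_lte(sigma_required(seg, cfg2), sigma_required(seg, cfg))
  }
})

test_that("sigma is reverse-complement symmetric under the default table", {
  for (s in 1:30) {
    seg <- random_dna(2 * sample(6:25, 1), seed = 900 + s)
    expect_equal(sigma_required(seg, cfg), sigma_required(revcomp(seg), cfg),
                 tolerance = 1e-12)
  }
})

test_that("ZDR scanning equals the exhaustive all-window oracle", {
  # background with one planted island
  bg <- random_dna(1200, seed = 41)
  island <- paste0(substr(bg, 1, 600), strrep("CG", 12),
                   substr(bg, 625, 1200))
  for (seqs in list(bg, island, paste0(substr(bg, 1, 100), "NNNN",
                                       substr(bg, 105, 400)))) {
    for (cut in c(-0.08, -0.07)) {
      got <- scan_zdrs(seqs, cut, cfg)
      want <- oracle_scan(seqs, cut, cfg)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$sigma_required, want$sigma_required, tolerance = 1e-12)
    }
  }
})

test_that("scan finds nothing in homopolymer, the island in background, and nests across cutoffs", {
  expect_equal(nrow(scan_zdrs(strrep("A", 400), -0.08, cfg)), 0)

  # a single (CG)12 island in a non-alternating (purine-only) background,
  # which the oracle confirms is clean
  bg <- withr::with_seed(55, paste(sample(c("A", "G"), 2000, TRUE),
                                   collapse = ""))
  stopifnot(nrow(oracle_scan(bg, -0.08, cfg)) == 0)
  seqs <- paste0(substr(bg, 1, 1000), strrep("CG", 12),
                 substr(bg, 1025, 2000))
  z <- scan_zdrs(seqs, -0.08, cfg)
  expect_equal(nrow(z), 1)
  expect_lte(z$start, 1000)
  expect_gte(z$end, 1024)

  # calls at -0.07 are covered by calls at -0.08
  mixed <- paste0(substr(bg, 1, 500), strrep("CA", 14),
                  substr(bg, 529, 1000), strrep("AT", 15),
                  substr(bg, 1031, 1500))
  z8 <- scan_zdrs(mixed, -0.08, cfg)
  z7 <- scan_zdrs(mixed, -0.07, cfg)
  if (nrow(z7)) {
    covered <- vapply(seq_len(nrow(z7)), function(i)
      any(z8$start <= z7$start[i] & z8$end >= z7$end[i]), logical(1))
    expect_true(all(covered))
  }
  expect_error(scan_zdrs(bg, 0.08, cfg), "negative")
})

test_that("sigma profiles have the stated geometry and respond to planted ZDRs", {
  flank <- 2000L
  seqs <- paste0(random_dna(2100, seed = 61), strrep("CG", 20),
                 random_dna(2100, seed = 62))
  center <- 2120L
  pr <- sigma_profile(seqs, center, cfg, flank = flank)
  expect_length(pr$values, (2 * flank - 20) / 2 + 1)
  expect_false(pr$truncated)
  expect_true(all(pr$values[!is.na(pr$values)] < 0))

  # windows wholly inside a uniform (CG)n region share one value
  mid <- pr$values[pr$offsets >= -18 & pr$offsets <= -2]
  expect_true(all(abs(mid - mid[1]) < 1e-12))

  # center is closer to zero than background for the planted case
  bgp <- sigma_profile(random_dna(4300, seed = 63), 2150L, cfg,
                       flank = flank)
  expect_gt(pr$values[pr$offsets == -10],
            mean(bgp$values, na.rm = TRUE))

  # reverse-complementing the sequence mirrors the profile
  n <- nchar(seqs)
  prc <- sigma_profile(revcomp(seqs), n - center, cfg, flank = flank)
  fwd <- pr$values
  rev_vals <- rev(prc$values)
  keep <- !is.na(fwd) & !is.na(rev_vals)
  expect_equal(fwd[keep], rev_vals[keep], tolerance = 1e-9)

  # edge proximity flags truncation
  expect_true(sigma_profile(seqs, 100L, cfg, flank = flank)$truncated)
})
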