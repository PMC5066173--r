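# Shared fixtures and small utilities for the suite.

random_dna <- function(n, seed, gc = 0.45) {
  withr::with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), n, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
    collapse = ""))
}

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

# Uniform background reads over a chromosome set (interval representation).
uniform_reads <- function(n, chrom_sizes, seed, read_len = 36L) {
  withr::with_seed(seed, {
    chrom <- sample(names(chrom_sizes), n, replace = TRUE,
                    prob = chrom_sizes / sum(chrom_sizes))
    start <- as.integer(floor(stats::runif(n) *
                                (chrom_sizes[chrom] - read_len)))
    genomic_intervals(chrom, start, start + read_len,
                      strand = sample(c("+", "-"), n, replace = TRUE))
  })
}

# Bivariate mixture simulator for IDR tests: reproducible component
# N((mu,mu), sigma^2, rho), noise component standard bivariate normal.
simulate_idr_pairs <- function(n, p_repro, rho, mu = 2.5, sigma = 1,
                               seed = 1) {
  withr::with_seed(seed, {
    k <- stats::runif(n) < p_repro
    z1 <- numeric(n); z2 <- numeric(n)
    nr <- sum(!k)
    z1[!k] <- stats::rnorm(nr); z2[!k] <- stats::rnorm(nr)
    e1 <- stats::rnorm(sum(k)); e2 <- stats::rnorm(sum(k))
    z1[k] <- mu + sigma * e1
    z2[k] <- mu + sigma * (rho * e1 + sqrt(1 - rho^2) * e2)
    list(s1 = z1, s2 = z2, repro = k)
  })
}

# Memoised full synthetic run at generator defaults, shared between the
# workflow and acceptance tests so the end-to-end pipeline is executed once.
.run_cache <- new.env(parent = emptyenv())

cached_full_run <- function(seed = 1L) {
  key <- paste0("run_", seed)
  if (is.null(.run_cache[[key]])) {
    cfg <- run_config(synthetic = TRUE, seed = seed, outdir = NULL)
    .run_cache[[key]] <- run_full_analysis(cfg)
  }
  .run_cache[[key]]
}
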