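# Independent oracles used by both the module tests and the acceptance
# suite. These deliberately re-derive quantities by brute force, never
# through the code paths they check.

# Brute-force B->Z free energy: explicit table lookup over non-overlapping
# dinucleotides, both registers.
oracle_delta_g <- function(segment, phase, cfg) {
  tiles <- substring(segment, seq(1, nchar(segment) - 1, by = 2),
                     seq(2, nchar(segment), by = 2))
  sum(cfg$dg_dinuc[tiles, phase + 1L]) + 2 * cfg$dg_junction
}

# Numeric root of the supercoiling energy-balance equation in sigma.
oracle_sigma_root <- function(segment, cfg) {
  dg <- min(oracle_delta_g(segment, 0L, cfg), oracle_delta_g(segment, 1L, cfg))
  n <- nchar(segment)
  a <- cfg$K_sc * cfg$RT / cfg$N_domain
  r <- n * (1 / cfg$h_B + 1 / cfg$h_Z)
  released <- function(sigma) {
    lk0 <- sigma * cfg$N_domain / cfg$h_B
    a * lk0^2 - a * (lk0 + r)^2
  }
  stats::uniroot(function(s) released(s) - dg, c(-5, -1e-12),
                 tol = 1e-12)$root
}

# Exhaustive all-window ZDR scan: every even window length within bounds,
# every start, explicit energies; qualifying windows merged by union
# (adjacency closed), keeping the best sigma.
oracle_scan <- function(seq, cutoff, cfg) {
  n <- nchar(seq)
  wins <- list()
  for (L in seq(cfg$L_min, min(cfg$L_max, n), by = 2)) {
    for (s in 0:(n - L)) {
      seg <- substr(seq, s + 1, s + L)
      if (grepl("[^ACGT]", seg)) next
      dg <- min(oracle_delta_g(seg, 0L, cfg), oracle_delta_g(seg, 1L, cfg))
      a <- cfg$K_sc * cfg$RT / cfg$N_domain
      r <- L * (1 / cfg$h_B + 1 / cfg$h_Z)
      sigma <- -(dg / a + r^2) * cfg$h_B / (2 * r * cfg$N_domain)
      if (sigma >= cutoff)
        wins[[length(wins) + 1L]] <- c(s, s + L, sigma)
    }
  }
  if (!length(wins))
    return(data.frame(start = integer(0), end = integer(0),
                      sigma_required = numeric(0)))
  m <- do.call(rbind, wins)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  out <- list()
  cur <- m[1, ]
  for (i in seq_len(nrow(m))[-1]) {
    if (m[i, 1] <= cur[2]) {  # overlap or adjacency
      cur[2] <- max(cur[2], m[i, 2])
      cur[3] <- max(cur[3], m[i, 3])
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- m[i, ]
    }
  }
  out[[length(out) + 1L]] <- cur
  m2 <- do.call(rbind, out)
  data.frame(start = as.integer(m2[, 1]), end = as.integer(m2[, 2]),
             sigma_required = m2[, 3])
}

# Per-interval brute-force region classifier: explicit distance to every
# TSS and containment in every gene span.
oracle_classify <- function(x, genes, promoter_bp = 2000L) {
  vapply(seq_len(nrow(x)), function(i) {
    mid <- floor((x$start[i] + x$end[i]) / 2)
    g <- genes[genes$chrom == x$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) return("intergenic")
    tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
    if (any(abs(mid - tss) <= promoter_bp)) return("promoter")
    if (any(mid >= g$start & mid < g$end)) return("gene_body")
    "intergenic"
  }, character(1))
}

# Exact two-sided Fisher p for a 2x2 table by enumerating the
# hypergeometric distribution over all feasible tables.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Mann-Whitney U by explicit pair counting.
oracle_u_stat <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}
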