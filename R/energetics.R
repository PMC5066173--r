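#' Configuration of the B-to-Z transition energy model
#'
#' Houses every thermodynamic constant of the zipper model. A candidate Z
#' segment of even length n is treated as n/2 dinucleotide units, each in one
#' of two anti/syn registers; the segment free energy at sigma = 0 is the sum
#' of per-dinucleotide terms (for the chosen register) plus two B-Z junction
#' penalties. The supercoiling free energy of a topological domain with
#' residual linking difference dLk is the usual quadratic
#' G(dLk) = K_sc * RT * dLk^2 / N_domain.
#'
#' The default dinucleotide table assigns, in the favourable register,
#' 0.66 kcal/mol to d(CG)/d(GC) units, 1.33 to d(CA)/d(TG) (and AC/GT),
#' 2.40 to d(TA)/d(AT), and `dg_nonalt` (default 4.5) to dinucleotides that
#' break the purine-pyrimidine alternation as well as to any dinucleotide in
#' its unfavourable register. Out-of-alternation dinucleotides are therefore
#' permitted, at a high but finite cost. These defaults reproduce the
#' canonical propensity ordering d(GC) > d(CA/TG) > d(TA/AT) (most to least
#' Z-prone) and are symmetric under reverse complement. The junction
#' penalty and non-alternation cost are calibrated (once, as model
#' defaults) so that the conventional cutoffs sigma = -0.08 and -0.07
#' discriminate: alternating repeats qualify well before random sequence,
#' and random 45%-GC background contains a ZDR at -0.08 in roughly a third
#' of 500-bp windows but almost never at -0.07.
#'
#' @param dg_junction kcal/mol per B-Z junction (two junctions per segment).
#' @param dg_nonalt kcal/mol per dinucleotide out of alternation or in the
#'   unfavourable register.
#' @param dg_favorable named numeric: favourable-register energy per
#'   dinucleotide class, names `CG`, `CA`, `TA` (kcal/mol).
#' @param h_B,h_Z helical repeats of B- and Z-DNA, bp/turn.
#' @param K_sc supercoiling free-energy constant, units of RT*bp.
#' @param RT kcal/mol (0.616 at 37 C).
#' @param N_domain topological domain length, bp.
#' @param L_min,L_max even bounds on candidate Z-segment length, bp.
#' @return An object of class `energetics_config`.
#' @export
#' @examples
#' cfg <- energetics_config()
#' sigma_required(strrep("CG", 10), cfg)
energetics_config <- function(dg_junction = 7.0, dg_nonalt = 4.5,
                              dg_favorable = c(CG = 0.66, CA = 1.33, TA = 2.40),
                              h_B = 10.5, h_Z = 12.0, K_sc = 1100,
                              RT = 0.616, N_domain = 5000,
                              L_min = 12L, L_max = 50L) {
  stopifnot(h_B > 0, h_Z > 0, K_sc > 0, RT > 0, N_domain > 0,
            L_min <= L_max, L_min %% 2 == 0, L_max %% 2 == 0,
            all(is.finite(c(dg_junction, dg_nonalt, dg_favorable))),
            all(c("CG", "CA", "TA") %in% names(dg_favorable)))
  if (!(dg_favorable["CG"] < dg_favorable["CA"] &&
        dg_favorable["CA"] < dg_favorable["TA"]))
    stop("dinucleotide energies must order d(GC) < d(CA/TG) < d(TA/AT)")
  cfg <- list(dg_junction = dg_junction, dg_nonalt = dg_nonalt,
              dg_favorable = dg_favorable, h_B = h_B, h_Z = h_Z,
              K_sc = K_sc, RT = RT, N_domain = N_domain,
              L_min = as.integer(L_min), L_max = as.integer(L_max))
  cfg$dg_dinuc <- build_dinuc_table(cfg)
  class(cfg) <- "energetics_config"
  cfg
}

# 16 x 2 matrix of per-dinucleotide energies; rows named by dinucleotide,
# columns = the two anti/syn registers. Register 1 is favourable for
# purine-pyrimidine dinucleotides, register 2 for pyrimidine-purine ones;
# non-alternating dinucleotides pay dg_nonalt in both.
build_dinuc_table <- function(cfg) {
  bases <- c("A", "C", "G", "T")
  purine <- c(A = TRUE, C = FALSE, G = TRUE, T = FALSE)
  fav_class <- function(d) {
    if (d %in% c("CG", "GC")) return(cfg$dg_favorable[["CG"]])
    if (d %in% c("CA", "TG", "AC", "GT")) return(cfg$dg_favorable[["CA"]])
    cfg$dg_favorable[["TA"]]  # TA / AT
  }
  dinucs <- as.vector(outer(bases, bases, paste0))
  tab <- matrix(cfg$dg_nonalt, nrow = 16, ncol = 2,
                dimnames = list(dinucs, c("reg1", "reg2")))
  for (d in dinucs) {
    b1 <- substr(d, 1, 1); b2 <- substr(d, 2, 2)
    if (purine[[b1]] && !purine[[b2]]) tab[d, "reg1"] <- fav_class(d)
    if (!purine[[b1]] && purine[[b2]]) tab[d, "reg2"] <- fav_class(d)
  }
  tab
}

# Integer codes 1..4 for A,C,G,T; NA for N/other.
seq_codes <- function(seq) {
  x <- utf8ToInt(seq)
  code <- rep(NA_integer_, length(x))
  code[x == 65L] <- 1L  # A
  code[x == 67L] <- 2L  # C
  code[x == 71L] <- 3L  # G
  code[x == 84L] <- 4L  # T
  code
}

# Per-offset dinucleotide energies for both registers. Positions holding an
# N (or any non-ACGT base) get NA.
tile_energies <- function(seq, cfg) {
  code <- seq_codes(seq)
  n <- length(code)
  if (n < 2L) return(list(e1 = numeric(0), e2 = numeric(0), n = n))
  idx <- (code[-n] - 1L) * 4L + code[-1]  # row index into dg table
  bases <- c("A", "C", "G", "T")
  ord <- paste0(rep(bases, each = 4), rep(bases, 4))  # (first-1)*4 + second
  tab <- cfg$dg_dinuc[ord, , drop = FALSE]
  list(e1 = tab[idx, 1], e2 = tab[idx, 2], n = n)
}

#' Free energy of the B-to-Z transition of a segment at sigma = 0
#'
#' Sums the per-dinucleotide energies of the segment under the given
#' anti/syn register and adds two junction penalties. Always strictly
#' positive under the default configuration: the transition costs energy in
#' the absence of supercoiling.
#'
#' @param segment DNA string of even length >= 2, alphabet A/C/G/T.
#' @param phase register assignment, 0 or 1.
#' @param config an [energetics_config()].
#' @return Free energy in kcal/mol.
#' @export
delta_g_bz <- function(segment, phase, config = energetics_config()) {
  n <- nchar(segment)
  if (n < 2L || n %% 2L != 0L)
    stop("segment length must be even and >= 2, got ", n)
  if (grepl("[^ACGT]", segment))
    stop("segment contains a non-ACGT character")
  stopifnot(phase %in% c(0L, 1L))
  te <- tile_energies(segment, config)
  offs <- seq(1L, n - 1L, by = 2L)
  e <- if (phase == 0L) te$e1[offs] else te$e2[offs]
  sum(e) + 2 * config$dg_junction
}

# sigma required from transition free energy dg (kcal/mol) and segment
# length n (bp). The energy balance
#   G(dLk0) - G(dLk0 + r) = dg,  dLk0 = sigma * N / h_B,
#   r = n * (1/h_B + 1/h_Z),  G(x) = a x^2,  a = K_sc RT / N
# is linear in sigma; closed form:
#   sigma = -(dg / a + r^2) * h_B / (2 r N)
sigma_from_dg <- function(dg, n, cfg) {
  a <- cfg$K_sc * cfg$RT / cfg$N_domain
  r <- n * (1 / cfg$h_B + 1 / cfg$h_Z)
  -(dg / a + r^2) * cfg$h_B / (2 * r * cfg$N_domain)
}

#' Minimal superhelical density required for Z-DNA formation
#'
#' Translates the B-to-Z transition free energy of a segment (minimum over
#' the two anti/syn registers) into the least-negative superhelical density
#' sigma at which the supercoiling free energy released by converting the
#' segment from B (+n/h_B turns) to Z (-n/h_Z turns) pays for the
#' transition. Sequences that require less supercoiling (sigma closer to
#' zero) have greater Z-forming potential.
#'
#' @inheritParams delta_g_bz
#' @return Negative numeric sigma.
#' @export
sigma_required <- function(segment, config = energetics_config()) {
  dg <- min(delta_g_bz(segment, 0L, config), delta_g_bz(segment, 1L, config))
  sigma_from_dg(dg, nchar(segment), config)
}

# Sliding sums over a stride-2 subsequence: for every start s in
# 1..(length(e)-2*(m-1)) return sum(e[s], e[s+2], ..., e[s+2(m-1)]).
# NA entries are replaced by `big` so windows containing them never qualify.
stride2_window_sums <- function(e, m, big = 1e6) {
  e[is.na(e)] <- big
  ne <- length(e)
  span <- 2L * (m - 1L)
  if (ne < span + 1L) return(numeric(0))
  out <- numeric(ne - span)
  for (par in 0:1) {
    idx <- seq(1L + par, ne, by = 2L)
    cs <- cumsum(e[idx])
    k <- length(idx)
    if (k < m) next
    w <- cs[m:k] - c(0, cs)[1:(k - m + 1L)]
    out[idx[1:(k - m + 1L)]] <- w
  }
  out
}

#' Scan a sequence for Z-DNA-forming regions at a sigma cutoff
#'
#' Every even-length window with `L_min <= L <= L_max` whose required
#' superhelical density is at or above (less negative than) `sigma_cutoff`
#' qualifies; overlapping and adjacent qualifying windows are merged into
#' maximal calls. Each merged call reports the best (maximal, closest to
#' zero) `sigma_required` among its constituent windows, together with that
#' window's register and transition free energy. Windows containing N are
#' skipped.
#'
#' @param seq chromosome sequence (single string, A/C/G/T/N).
#' @param sigma_cutoff negative superhelical density cutoff (e.g. -0.08).
#' @param config an [energetics_config()].
#' @param chrom chromosome name attached to the calls.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `sigma_required`, `phase`, `dg_total`, sorted by start.
#' @export
scan_zdrs <- function(seq, sigma_cutoff, config = energetics_config(),
                      chrom = "chr") {
  if (!is.numeric(sigma_cutoff) || sigma_cutoff >= 0)
    stop("sigma_cutoff must be negative")
  cfg <- config
  te <- tile_energies(seq, cfg)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), sigma_required = numeric(0),
                      phase = integer(0), dg_total = numeric(0))
  if (te$n < cfg$L_min) return(empty)
  starts <- integer(0); lens <- integer(0)
  sig <- numeric(0); pha <- integer(0); dgs <- numeric(0)
  for (L in seq(cfg$L_min, min(cfg$L_max, 2L * (te$n %/% 2L)), by = 2L)) {
    m <- L %/% 2L
    s1 <- stride2_window_sums(te$e1, m)
    s2 <- stride2_window_sums(te$e2, m)
    if (!length(s1)) next
    smin <- pmin(s1, s2)
    dg <- smin + 2 * cfg$dg_junction
    ok <- which(smin < 5e5 & sigma_from_dg(dg, L, cfg) >= sigma_cutoff)
    if (!length(ok)) next
    starts <- c(starts, ok - 1L)  # back to 0-based
    lens <- c(lens, rep(L, length(ok)))
    sig <- c(sig, sigma_from_dg(dg[ok], L, cfg))
    pha <- c(pha, ifelse(s1[ok] <= s2[ok], 0L, 1L))
    dgs <- c(dgs, dg[ok])
  }
  if (!length(starts)) return(empty)
  win <- IRanges::IRanges(start = starts + 1L, width = lens)
  merged <- IRanges::reduce(win)  # merges overlapping and adjacent
  hits <- IRanges::findOverlaps(win, merged)
  best <- tapply(seq_along(starts)[S4Vectors::queryHits(hits)],
                 S4Vectors::subjectHits(hits),
                 function(ix) ix[which.max(sig[ix])])
  best <- unlist(best[as.character(seq_along(merged))])
  out <- data.frame(
    chrom = chrom,
    start = IRanges::start(merged) - 1L,
    end = IRanges::end(merged),
    sigma_required = sig[best],
    phase = pha[best],
    dg_total = dgs[best],
    stringsAsFactors = FALSE
  )
  out[order(out$start), , drop = FALSE]
}

#' Sliding-window superhelicity profile around a point
#'
#' Computes the required superhelical density of every `window_bp`-long
#' window, stepping by `step_bp`, across `center` plus/minus `flank` (the
#' default 20-bp windows overlapping by 18 bp). Windows containing N, or
#' lost to a chromosome edge, carry `NA`.
#'
#' @param seq chromosome sequence.
#' @param center 0-based genomic point on `seq`.
#' @param config an [energetics_config()].
#' @param flank half-width of the profiled region, bp.
#' @param window_bp window width (even), bp.
#' @param step_bp step between window starts, bp.
#' @return List of class `sigma_profile` with elements `center`,
#'   `window_bp`, `step_bp`, `offsets` (window starts relative to center),
#'   `values` (sigma per window) and `truncated`.
#' @export
sigma_profile <- function(seq, center, config = energetics_config(),
                          flank = 2000L, window_bp = 20L, step_bp = 2L) {
  stopifnot(window_bp %% 2L == 0L, step_bp >= 1L)
  n <- nchar(seq)
  offsets <- seq(-flank, flank - window_bp, by = step_bp)
  win_start <- center + offsets  # 0-based genomic window starts
  truncated <- any(win_start < 0L) || any(win_start + window_bp > n)
  lo <- max(0L, min(win_start))
  hi <- min(n, max(win_start) + window_bp)
  te <- tile_energies(substr(seq, lo + 1L, hi), config)
  m <- window_bp %/% 2L
  s1 <- stride2_window_sums(te$e1, m)
  s2 <- stride2_window_sums(te$e2, m)
  smin <- pmin(s1, s2)
  values <- rep(NA_real_, length(offsets))
  rel <- win_start - lo + 1L  # 1-based index into the window-sum vectors
  inside <- win_start >= 0L & (win_start + window_bp) <= n &
    rel >= 1L & rel <= length(smin)
  v <- smin[rel[inside]]
  v[v >= 5e5] <- NA_real_
  values[inside] <- sigma_from_dg(v + 2 * config$dg_junction, window_bp,
                                  config)
  structure(list(center = center, window_bp = window_bp, step_bp = step_bp,
                 offsets = offsets, values = values, truncated = truncated),
            class = "sigma_profile")
}
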