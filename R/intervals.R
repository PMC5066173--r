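#' Construct a table of genomic intervals
#'
#' Genomic intervals are the universal currency of the package: peaks, ZDRs,
#' genes, blacklist regions and aligned reads are all carried as plain
#' data.frames with BED-convention coordinates (0-based start, exclusive end).
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive start positions.
#' @param end integer vector, exclusive end positions (`end > start`).
#' @param name optional character labels (`NA` allowed).
#' @param score optional numeric scores (`NA` allowed).
#' @param strand optional strand, each element one of `"+"`, `"-"`, `"."`.
#'
#' @return A data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
#' @examples
#' genomic_intervals("chr1", 0L, 100L, name = "p1", score = 7, strand = "+")
genomic_intervals <- function(chrom, start, end, name = NA_character_,
                              score = NA_real_, strand = ".") {
  n <- length(chrom)
  rec <- function(v, as_fun) {
    v <- as_fun(v)
    if (length(v) == n) v else rep(v, length.out = n)
  }
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    name = rec(name, as.character),
    score = rec(score, as.numeric),
    strand = rec(strand, as.character),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  df
}

#' Validate a genomic-interval data.frame
#'
#' Checks the coordinate invariants (0 <= start < end, non-empty chromosome
#' names, strand in +/-/.) and stops with a descriptive error otherwise.
#'
#' @param x data.frame with at least `chrom`, `start`, `end` columns.
#' @return `x`, invisibly.
#' @export
validate_intervals <- function(x) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0L) return(invisible(x))
  if (anyNA(x$chrom) || any(!nzchar(x$chrom)))
    stop("interval with empty chromosome name")
  bad <- which(is.na(x$start) | is.na(x$end) | x$start < 0L | x$start >= x$end)
  if (length(bad))
    stop(sprintf("invalid interval coordinates at row %d: [%s, %s)",
                 bad[1], x$start[bad[1]], x$end[bad[1]]))
  if ("strand" %in% names(x)) {
    s <- x$strand[!is.na(x$strand)]
    if (length(s) && !all(s %in% c("+", "-", ".")))
      stop("strand must be one of '+', '-', '.'")
  }
  invisible(x)
}

# Midpoint of a 0-based half-open interval (integer floor).
interval_midpoint <- function(x) {
  as.integer(floor((x$start + x$end) / 2))
}

# 0-based half-open -> IRanges (1-based closed).
as_iranges0 <- function(x) {
  IRanges::IRanges(start = x$start + 1L, end = x$end)
}

# Any-overlap hits between two 0-based interval tables, chromosome-aware.
# Returns a data.frame with columns q (query row) and s (subject row).
overlap_hits <- function(query, subject) {
  if (nrow(query) == 0L || nrow(subject) == 0L)
    return(data.frame(q = integer(0), s = integer(0)))
  out_q <- integer(0)
  out_s <- integer(0)
  for (ch in intersect(unique(query$chrom), unique(subject$chrom))) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    hits <- IRanges::findOverlaps(as_iranges0(query[qi, , drop = FALSE]),
                                  as_iranges0(subject[si, , drop = FALSE]))
    out_q <- c(out_q, qi[S4Vectors::queryHits(hits)])
    out_s <- c(out_s, si[S4Vectors::subjectHits(hits)])
  }
  data.frame(q = out_q, s = out_s)
}

# Logical: does each query interval overlap any subject interval (>= 1 bp)?
overlaps_any <- function(query, subject) {
  res <- logical(nrow(query))
  if (nrow(query) == 0L || nrow(subject) == 0L) return(res)
  hits <- overlap_hits(query, subject)
  res[unique(hits$q)] <- TRUE
  res
}

# Sort intervals by chromosome then start then end.
sort_intervals <- function(x) {
  x[order(x$chrom, x$start, x$end), , drop = FALSE]
}
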