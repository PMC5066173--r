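#' Read a FASTA genome into a named character vector
#'
#' Sequences are folded to uppercase. The alphabet is restricted to
#' A/C/G/T/N; N bases are retained verbatim and must be handled explicitly
#' by downstream scanners.
#'
#' @param path path to a FASTA file.
#' @return Named character vector, one uppercase sequence per record. An
#'   empty file yields an empty vector.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0L) return(stats::setNames(character(0), character(0)))
  set <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm))
    stop("duplicate FASTA record name: ", nm[duplicated(nm)][1])
  if (any(Biostrings::width(set) == 0L))
    stop("empty FASTA record: ", nm[Biostrings::width(set) == 0L][1])
  seqs <- toupper(as.character(set))
  if (any(grepl("[^ACGTN]", seqs)))
    stop("FASTA contains characters outside A/C/G/T/N")
  stats::setNames(seqs, nm)
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a BED3/BED6 file
#'
#' Coordinates are taken verbatim as 0-based half-open. Optional columns 4-6
#' become `name`, `score`, `strand`. Malformed lines raise an error naming
#' the offending line number rather than being skipped.
#'
#' @param path path to a tab-separated BED file.
#' @return Interval data.frame (see [genomic_intervals()]); row order follows
#'   file order.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")  # headers/track lines
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(genomic_intervals(character(0), integer(0), integer(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("BED line %d has fewer than 3 tab-separated columns",
                 lineno[which(nf < 3L)[1]]))
  col <- function(i) vapply(fields, function(f)
    if (length(f) >= i) f[[i]] else NA_character_, character(1))
  start_chr <- col(2); end_chr <- col(3)
  start <- suppressWarnings(as.integer(start_chr))
  end <- suppressWarnings(as.integer(end_chr))
  bad_int <- which(is.na(start) | is.na(end) |
                   start_chr != as.character(start) |
                   end_chr != as.character(end))
  if (length(bad_int))
    stop(sprintf("BED line %d: non-integer coordinates",
                 lineno[bad_int[1]]))
  bad_ord <- which(start >= end | start < 0L)
  if (length(bad_ord))
    stop(sprintf("BED line %d: start >= end (or negative start)",
                 lineno[bad_ord[1]]))
  score <- suppressWarnings(as.numeric(col(5)))
  genomic_intervals(
    chrom = col(1), start = start, end = end,
    name = col(4), score = score,
    strand = ifelse(is.na(col(6)), ".", col(6))
  )
}

#' Write intervals as BED6 (or BED3)
#'
#' @param x interval data.frame.
#' @param path output path.
#' @param header optional character vector of `#`-prefixed header lines
#'   (written verbatim before the records).
#' @param bed3 if `TRUE` only the first three columns are written.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, header = NULL, bed3 = FALSE) {
  validate_intervals(x)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  if (nrow(x) == 0L) return(invisible(path))
  if (bed3) {
    writeLines(sprintf("%s\t%d\t%d", x$chrom, x$start, x$end), con)
  } else {
    n <- nrow(x)
    col <- function(nmv, default) {
      if (is.null(nmv)) rep(default, n) else ifelse(is.na(nmv), default,
                                                    as.character(nmv))
    }
    nm <- col(x$name, ".")
    sc <- if (is.null(x$score)) rep("0", n) else
      ifelse(is.na(x$score), "0", format(x$score, trim = TRUE,
                                         scientific = FALSE, digits = 10))
    st <- col(x$strand, ".")
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                       x$chrom, x$start, x$end, nm, sc, st), con)
  }
  invisible(path)
}

#' Write a 4-column bedGraph track
#'
#' @param x data.frame with columns `chrom`, `start`, `end`, `value`
#'   (0-based half-open coordinates).
#' @param path output path.
#' @param header optional `#`-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path, header = NULL) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(x)))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  if (nrow(x))
    writeLines(sprintf("%s\t%d\t%d\t%s", x$chrom, x$start, x$end,
                       format(x$value, trim = TRUE, digits = 8)), con)
  invisible(path)
}

#' Read a tab-delimited gene table
#'
#' Expected columns: `gene_id`, `chrom`, `strand`, `start`, `end`,
#' `exon_starts`, `exon_ends` (comma-separated coordinate lists, 0-based
#' half-open like the gene span). Exons are validated against the gene span
#' and sorted.
#'
#' @param path path to the gene table (a header line is required).
#' @return data.frame of gene models with list-columns `exon_starts` and
#'   `exon_ends` (sorted integer vectors) plus `tss` and `exon_length`.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop("gene table not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("gene_id", "chrom", "strand", "start", "end",
            "exon_starts", "exon_ends")
  if (!all(need %in% names(df)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  parse_list <- function(s) as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
  es <- lapply(df$exon_starts, parse_list)
  ee <- lapply(df$exon_ends, parse_list)
  for (i in seq_len(nrow(df))) {
    if (!df$strand[i] %in% c("+", "-"))
      stop("gene ", df$gene_id[i], ": strand must be '+' or '-'")
    if (length(es[[i]]) != length(ee[[i]]) || length(es[[i]]) == 0L)
      stop("gene ", df$gene_id[i], ": exon start/end lists malformed")
    o <- order(es[[i]])
    es[[i]] <- es[[i]][o]; ee[[i]] <- ee[[i]][o]
    if (any(es[[i]] >= ee[[i]]))
      stop("gene ", df$gene_id[i], ": exon with start >= end")
    if (any(es[[i]] < df$start[i]) || any(ee[[i]] > df$end[i]))
      stop("gene ", df$gene_id[i], ": exon outside gene span")
    if (length(es[[i]]) > 1L && any(es[[i]][-1] < ee[[i]][-length(ee[[i]])]))
      stop("gene ", df$gene_id[i], ": overlapping exons")
  }
  out <- data.frame(
    gene_id = df$gene_id, chrom = df$chrom, strand = df$strand,
    start = as.integer(df$start), end = as.integer(df$end),
    stringsAsFactors = FALSE
  )
  out$exon_starts <- es
  out$exon_ends <- ee
  out$tss <- gene_tss(out)
  out$exon_length <- vapply(seq_len(nrow(out)),
                            function(i) sum(ee[[i]] - es[[i]]), integer(1))
  out
}

#' Write a gene table
#'
#' @param genes gene-model data.frame as returned by [read_gene_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  df <- data.frame(
    gene_id = genes$gene_id, chrom = genes$chrom, strand = genes$strand,
    start = genes$start, end = genes$end,
    exon_starts = vapply(genes$exon_starts, paste, character(1),
                         collapse = ","),
    exon_ends = vapply(genes$exon_ends, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Strand-aware transcription start sites
#'
#' The TSS of a plus-strand gene is its `start`; of a minus-strand gene its
#' `end - 1` (the last base of the half-open span).
#'
#' @param genes gene-model data.frame with `start`, `end`, `strand`.
#' @return Integer vector of 0-based TSS coordinates.
#' @export
gene_tss <- function(genes) {
  as.integer(ifelse(genes$strand == "+", genes$start, genes$end - 1L))
}
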