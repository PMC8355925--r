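#' Genomic intervals in BED (0-based half-open) coordinates
#'
#' All interval geometry in this package uses a single convention: 0-based
#' starts, exclusive ends, exactly as in BED files. External 1-based
#' inclusive spans (browser-style `chr13:59341171-59343427`, GWAS-catalog
#' positions) must be converted at the parser boundary; see
#' [browser_span_to_interval()] and [read_snp_table()]. Strand is ignored
#' throughout: the overlap rule used by every downstream step is a
#' strand-free single-nucleotide intersection.
#'
#' Intervals are represented as a plain `data.frame` with columns `chrom`
#' (character), `start`, `end` (integer-valued doubles), and optionally
#' `name` and `score`.
#'
#' @param chrom character vector of chromosome names (nonempty strings)
#' @param start 0-based inclusive starts, `>= 0`
#' @param end exclusive ends, `> start`
#' @param name optional feature names
#' @param score optional numeric scores
#' @return a validated interval `data.frame`
#' @examples
#' genomic_intervals("chr1", 10, 20)
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL, score = NULL) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  if (!is.null(score)) df$score <- as.numeric(score)
  validate_intervals(df)
  df
}

#' Validate an interval data frame
#'
#' @param x data.frame with at least `chrom`, `start`, `end`
#' @return `x`, invisibly, after validation
#' @export
validate_intervals <- function(x) {
  stopifnot(is.data.frame(x))
  req <- c("chrom", "start", "end")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0)
    stop("interval table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom)))
    stop("interval chrom must be a nonempty string")
  if (any(is.na(x$start)) || any(is.na(x$end)))
    stop("interval coordinates must not be NA")
  if (any(x$start < 0))
    stop("interval start must be >= 0 (0-based BED coordinates)")
  bad <- which(x$start >= x$end)
  if (length(bad) > 0)
    stop("invalid interval(s) with start >= end at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  invisible(x)
}

#' Convert a 1-based inclusive browser span to a BED interval
#'
#' Browser-style spans such as `chr13:59341171-59343427` are 1-based and
#' inclusive; the corresponding BED interval starts one base earlier.
#'
#' @param span character vector like `"chr13:59341171-59343427"`
#' @return interval data.frame
#' @export
browser_span_to_interval <- function(span) {
  m <- regmatches(span, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", span))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("malformed browser span: ", span[bad][1])
  chrom <- vapply(m, `[`, "", 2L)
  s1 <- as.numeric(gsub(",", "", vapply(m, `[`, "", 3L)))
  e1 <- as.numeric(gsub(",", "", vapply(m, `[`, "", 4L)))
  genomic_intervals(chrom, s1 - 1, e1)
}

#' Read a BED3/BED6 file
#'
#' Tab-separated, no header. Columns beyond the third are mapped to
#' `name` (4) and `score` (5); strand (6) is read and discarded. BED
#' 0-based half-open semantics are preserved verbatim; intervals are
#' returned in file order.
#'
#' @param path path to an existing BED file
#' @return interval data.frame
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(genomic_intervals(character(), numeric(), numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf < 3L))
    stop("malformed BED line ", which(nf < 3L)[1], ": fewer than 3 fields")
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  if (any(is.na(start)) || any(is.na(end)))
    stop("malformed BED line ", which(is.na(start) | is.na(end))[1],
         ": non-numeric coordinates")
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (all(nf >= 4L)) df$name <- vapply(fields, `[`, "", 4L)
  if (all(nf >= 5L))
    df$score <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 5L)))
  validate_intervals(df)
  df
}

#' Write intervals as BED
#'
#' Writes the 3-column dialect by default; `name` and `score` columns are
#' appended when present. `read_bed()` then `write_bed()` round-trips a
#' 3-column file byte-identically.
#'
#' @param x interval data.frame
#' @param path output path
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  cols <- c("chrom", "start", "end")
  if (!is.null(x$name)) cols <- c(cols, "name")
  if (!is.null(x$score) && !is.null(x$name)) cols <- c(cols, "score")
  out <- x[, cols, drop = FALSE]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Single-nucleotide interval overlap
#'
#' Two intervals overlap when they share at least one base: same
#' chromosome and `a.start < b.end && b.start < a.end`. Half-open abutting
#' intervals do not overlap. Symmetric; any valid interval overlaps
#' itself.
#'
#' @param a,b single-row interval data.frames (or equal-length tables,
#'   compared row-wise)
#' @return logical vector
#' @export
overlaps <- function(a, b) {
  validate_intervals(a)
  validate_intervals(b)
  a$chrom == b$chrom & a$start < b$end & b$start < a$end
}

# Convert a BED-coordinate interval table to GRanges (1-based closed).
as_granges <- function(x) {
  validate_intervals(x)
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end))
}

#' Overlap query between two interval tables
#'
#' Returns the index pairs (rows of `query`, rows of `subject`) sharing at
#' least one base, via an interval-tree join.
#'
#' @param query,subject interval data.frames
#' @return data.frame with columns `query`, `subject` (row indices)
#' @export
overlap_pairs <- function(query, subject) {
  if (nrow(query) == 0 || nrow(subject) == 0)
    return(data.frame(query = integer(), subject = integer()))
  # suppress the seqlevel-mismatch note when chromosome sets differ
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges(query), as_granges(subject)))
  data.frame(query = S4Vectors::queryHits(hits),
             subject = S4Vectors::subjectHits(hits))
}

#' Which positions fall inside any interval
#'
#' @param chrom,pos vectors of chromosome and 0-based position
#' @param intervals interval data.frame
#' @return logical vector: `start <= pos < end` for some interval
#' @export
positions_in_intervals <- function(chrom, pos, intervals) {
  if (length(pos) == 0) return(logical(0))
  if (nrow(intervals) == 0) return(rep(FALSE, length(pos)))
  gr_pos <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1, pos + 1))
  suppressWarnings(IRanges::overlapsAny(gr_pos, as_granges(intervals)))
}
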