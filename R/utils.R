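#' Internal coordinate convention
#'
#' All intervals inside the package are 0-based half-open (`start` inclusive,
#' `end` exclusive), the BED convention. GTF I/O converts at the boundary
#' (GTF is 1-based inclusive). Report strings for human consumption are
#' 1-based inclusive with thousands separators.
#'
#' @name coordinates
#' @keywords internal
NULL

# Natural chromosome ordering: strip a "chr" prefix; purely numeric names sort
# numerically and come before non-numeric names, which sort lexicographically.
chrom_sort_key <- function(chrom) {
  stripped <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.numeric(stripped))
  is_num <- !is.na(num)
  order(!is_num, ifelse(is_num, num, NA), ifelse(is_num, NA_character_, stripped))
}

#' Order a feature table by chromosome then start
#'
#' Chromosome names are compared after stripping any `chr` prefix; numeric
#' names sort numerically ahead of non-numeric names (lexicographic). Within a
#' chromosome, features sort by start; the sort is stable.
#'
#' @param x A tibble with `chrom` and `start` columns.
#' @return `x`, reordered.
#' @export
sort_features <- function(x) {
  stopifnot(all(c("chrom", "start") %in% names(x)))
  x[chrom_order_index(x$chrom, x$start), , drop = FALSE]
}

chrom_order_index <- function(chrom, start) {
  stripped <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.numeric(stripped))
  is_num <- !is.na(num)
  order(!is_num, ifelse(is_num, num, Inf), ifelse(is_num, "", stripped), start)
}

#' Format an interval the way locus tables print it
#'
#' Converts an internal 0-based half-open interval to a 1-based inclusive
#' string with thousands separators, e.g. `chr3:101,700,268-101,700,695`.
#'
#' @param chrom,start,end Interval in internal coordinates.
#' @return Character vector of formatted location strings.
#' @export
#' @examples
#' format_location("chr3", 101700267, 101700695)
format_location <- function(chrom, start, end) {
  paste0(chrom, ":",
         formatC(start + 1, format = "d", big.mark = ","), "-",
         formatC(end, format = "d", big.mark = ","))
}

# Validate an interval table (0-based half-open).
check_intervals <- function(x, where = "interval table") {
  if (any(x$start < 0) || any(x$end <= x$start)) {
    abort(sprintf("%s: intervals must satisfy 0 <= start < end", where))
  }
  if (any(!nzchar(x$chrom))) abort(sprintf("%s: empty chromosome name", where))
  invisible(x)
}

# GRanges from a tibble with chrom/start/end (+ optional strand), internal
# 0-based half-open -> GRanges 1-based inclusive.
as_granges <- function(x) {
  strand <- if ("strand" %in% names(x)) {
    ifelse(x$strand %in% c("+", "-"), x$strand, "*")
  } else "*"
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

#' Reverse-complement a DNA string
#'
#' @param x Character vector of DNA strings over `{A,C,G,T,N}`.
#' @return Reverse-complemented strings.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Normalize residues: upper-case, U -> T. Errors on anything outside ACGTN.
normalize_dna <- function(x, where = "sequence") {
  x <- chartr("u", "t", toupper(x))
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    abort(sprintf("%s: residues outside {A,C,G,T,N,U} found", where))
  }
  x
}

run_seeded <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
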