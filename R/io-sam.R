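#' Read a SAM file into an alignment table
#'
#' Parses SAM text into one row per alignment record. FLAG bits are decoded
#' into logical columns; the reference span consumed by the CIGAR (M/D/N/=/X
#' operations) defines the record's interval, converted to 0-based half-open
#' coordinates. Optional tags are kept as a list column of `TAG=TYPE:VALUE`
#' strings parsed into named character vectors; tag values are opaque to the
#' package except for presence/absence of the configured multihit tag.
#'
#' Unmapped records (FLAG 0x4 or `*` reference) are dropped with a count in
#' the `n_unmapped` attribute.
#'
#' @param path Path to a SAM file (text, with header).
#' @return A tibble with columns `qname`, `flag`, `chrom`, `start`, `end`,
#'   `mapq`, `cigar`, the decoded flags `paired`, `proper_pair`,
#'   `reverse_strand`, `first_in_pair`, `secondary`, `supplementary`, and
#'   `tags` (list of named character vectors). The SAM header lines are
#'   attached as attribute `header`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) abort(sprintf("SAM file not found: %s", path))
  lines <- readr::read_lines(path)
  is_header <- grepl("^@", lines)
  if (length(lines) == 0 || !is_header[1]) {
    abort(sprintf("SAM '%s': missing header", path))
  }
  header <- lines[is_header]
  body <- lines[!is_header & nzchar(lines)]
  if (length(body) == 0) {
    out <- empty_alignments()
    attr(out, "header") <- header
    return(out)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11)) {
    abort(sprintf("SAM '%s': truncated record (fewer than 11 fields) at body line %d",
                  path, which(nf < 11)[1]))
  }
  flag <- as.integer(vapply(fields, `[[`, character(1), 2))
  rname <- vapply(fields, `[[`, character(1), 3)
  pos1 <- as.integer(vapply(fields, `[[`, character(1), 4))
  cigar <- vapply(fields, `[[`, character(1), 6)
  mapped <- !bitwAnd(flag, 4L) & rname != "*" & cigar != "*"
  n_unmapped <- sum(!mapped)
  fields <- fields[mapped]
  flag <- flag[mapped]
  ref_width <- cigar_ref_width(cigar[mapped])
  out <- tibble::tibble(
    qname = vapply(fields, `[[`, character(1), 1),
    flag = flag,
    chrom = rname[mapped],
    start = pos1[mapped] - 1L,
    end = pos1[mapped] - 1L + ref_width,
    mapq = as.integer(vapply(fields, `[[`, character(1), 5)),
    cigar = cigar[mapped],
    paired = bitwAnd(flag, 0x1L) > 0,
    proper_pair = bitwAnd(flag, 0x2L) > 0,
    reverse_strand = bitwAnd(flag, 0x10L) > 0,
    first_in_pair = bitwAnd(flag, 0x40L) > 0,
    secondary = bitwAnd(flag, 0x100L) > 0,
    supplementary = bitwAnd(flag, 0x800L) > 0,
    tags = lapply(fields, parse_sam_tags)
  )
  attr(out, "header") <- header
  attr(out, "n_unmapped") <- n_unmapped
  out
}

empty_alignments <- function() {
  tibble::tibble(
    qname = character(), flag = integer(), chrom = character(),
    start = integer(), end = integer(), mapq = integer(), cigar = character(),
    paired = logical(), proper_pair = logical(), reverse_strand = logical(),
    first_in_pair = logical(), secondary = logical(), supplementary = logical(),
    tags = list()
  )
}

# Reference-space width of a CIGAR string: sum of M/D/N/=/X operation lengths.
cigar_ref_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

# Optional SAM fields (columns 12+) as a named character vector TAG -> "TYPE:VALUE".
parse_sam_tags <- function(rec_fields) {
  if (length(rec_fields) <= 11) return(stats::setNames(character(0), character(0)))
  opt <- rec_fields[12:length(rec_fields)]
  keys <- substr(opt, 1, 2)
  vals <- substr(opt, 4, nchar(opt))
  stats::setNames(vals, keys)
}

#' Does a record carry a given optional tag?
#'
#' @param alignments Alignment tibble from [read_alignments].
#' @param tag Two-letter tag name, e.g. `"ZS"`.
#' @return Logical vector, one element per record.
#' @export
has_tag <- function(alignments, tag) {
  vapply(alignments$tags, function(t) tag %in% names(t), logical(1))
}

#' Write an alignment table as SAM text
#'
#' Inverse of [read_alignments] for the fields the package models. Sequence
#' and quality are emitted as `*` placeholders unless a `seq` column is
#' present.
#'
#' @param alignments Alignment tibble.
#' @param path Output path.
#' @param header Character vector of header lines; defaults to the `header`
#'   attribute of `alignments`, or a minimal header constructed from the
#'   observed chromosomes if absent.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, path, header = NULL) {
  header <- header %||% attr(alignments, "header")
  if (is.null(header)) {
    chroms <- unique(alignments$chrom)
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:%s\tLN:%d", chroms,
                        vapply(chroms, function(ch) max(alignments$end[alignments$chrom == ch]),
                               numeric(1))))
  }
  n <- nrow(alignments)
  tag_str <- vapply(seq_len(n), function(i) {
    t <- alignments$tags[[i]]
    if (length(t) == 0) return("")
    paste0("\t", paste0(names(t), ":", t, collapse = "\t"))
  }, character(1))
  seqf <- alignments[["seq"]] %||% rep("*", n)
  body <- paste0(
    alignments$qname, "\t", alignments$flag, "\t", alignments$chrom, "\t",
    alignments$start + 1L, "\t", alignments$mapq %||% rep(60L, n), "\t",
    alignments$cigar, "\t=\t0\t0\t", seqf, "\t*", tag_str
  )
  readr::write_lines(c(header, body), path)
  invisible(path)
}
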