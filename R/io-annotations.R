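#' Read a GTF file into an annotation table
#'
#' Parses a 9-column tab-separated GTF. Coordinates are converted from GTF's
#' 1-based inclusive convention to the package-internal 0-based half-open
#' convention (see [coordinates]). The attribute string is parsed into a named
#' character vector per feature; the `gene_id` key is required and becomes the
#' feature `id`.
#'
#' @param path Path to a GTF file.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`, `kind`
#'   (the GTF feature column), `id` (the `gene_id` attribute), `source`,
#'   `score`, `frame`, and `attributes` (list column of named character
#'   vectors).
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) abort(sprintf("GTF file not found: %s", path))
  lines <- readr::read_lines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(empty_annotation())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield != 9)) {
    abort(sprintf("GTF '%s' line %d: expected 9 tab-separated columns, got %d",
                  path, lineno[which(nfield != 9)[1]], nfield[nfield != 9][1]))
  }
  m <- matrix(unlist(fields), ncol = 9, byrow = TRUE)
  start1 <- suppressWarnings(as.integer(m[, 4]))
  end1 <- suppressWarnings(as.integer(m[, 5]))
  bad <- is.na(start1) | is.na(end1)
  if (any(bad)) {
    abort(sprintf("GTF '%s' line %d: non-integer coordinates", path, lineno[which(bad)[1]]))
  }
  bad <- start1 > end1 | start1 < 1
  if (any(bad)) {
    abort(sprintf("GTF '%s' line %d: start > end or start < 1", path, lineno[which(bad)[1]]))
  }
  attrs <- lapply(m[, 9], parse_gtf_attributes)
  ids <- vapply(attrs, function(a) a["gene_id"] %||% NA_character_, character(1))
  if (anyNA(ids)) {
    abort(sprintf("GTF '%s' line %d: missing required attribute 'gene_id'",
                  path, lineno[which(is.na(ids))[1]]))
  }
  tibble::tibble(
    chrom = m[, 1],
    start = start1 - 1L,
    end = end1,
    strand = ifelse(m[, 7] %in% c("+", "-"), m[, 7], "*"),
    kind = m[, 3],
    id = unname(ids),
    source = m[, 2],
    score = m[, 6],
    frame = m[, 8],
    attributes = attrs
  )
}

parse_gtf_attributes <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0) return(stats::setNames(character(0), character(0)))
  keys <- sub("^(\\S+)\\s.*$", "\\1", parts)
  vals <- sub("^\\S+\\s+", "", parts)
  vals <- gsub('^"|"$', "", vals)
  stats::setNames(vals, keys)
}

empty_annotation <- function() {
  tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), kind = character(), id = character(),
    source = character(), score = character(), frame = character(),
    attributes = list()
  )
}

#' Write an annotation table to GTF
#'
#' Serializes features in the row order of the input (use [merge_annotations]
#' or [sort_features] first for the canonical chromosome/start ordering).
#' Internal 0-based half-open coordinates are converted back to GTF's 1-based
#' inclusive convention.
#'
#' @param features Annotation tibble as returned by [read_gtf].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(features, path) {
  check_intervals(features, "write_gtf")
  attr_strings <- vapply(seq_len(nrow(features)), function(i) {
    a <- features$attributes[[i]]
    if (is.null(a) || length(a) == 0) a <- c(gene_id = features$id[i])
    if (!"gene_id" %in% names(a)) a <- c(gene_id = features$id[i], a)
    paste0(names(a), ' "', a, '";', collapse = " ")
  }, character(1))
  lines <- paste(
    features$chrom,
    features$source %||% "rcrekit",
    features$kind,
    features$start + 1L,
    features$end,
    features$score %||% ".",
    ifelse(features$strand %in% c("+", "-"), features$strand, "."),
    features$frame %||% ".",
    attr_strings,
    sep = "\t"
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a BED file (BED6 or narrower)
#'
#' BED is already 0-based half-open, matching the internal convention, so
#' coordinates pass through unchanged.
#'
#' @param path Path to a BED file.
#' @param kind Feature kind to assign to every record (BED carries none).
#' @return Annotation tibble (see [read_gtf]); `id` is the BED name column.
#' @export
read_bed <- function(path, kind = "LTR") {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       comment = "#", progress = FALSE)
  if (nrow(x) == 0) return(empty_annotation())
  if (ncol(x) < 3) abort(sprintf("BED '%s': need at least 3 columns", path))
  n <- nrow(x)
  out <- tibble::tibble(
    chrom = as.character(x[[1]]),
    start = as.integer(x[[2]]),
    end = as.integer(x[[3]]),
    strand = if (ncol(x) >= 6) ifelse(x[[6]] %in% c("+", "-"), x[[6]], "*") else rep("*", n),
    kind = kind,
    id = if (ncol(x) >= 4) as.character(x[[4]]) else paste0(kind, "_", seq_len(n)),
    source = rep("bed", n),
    score = if (ncol(x) >= 5) as.character(x[[5]]) else rep(".", n),
    frame = rep(".", n),
    attributes = lapply(seq_len(n), function(i) character(0))
  )
  check_intervals(out, path)
  out
}

#' Write intervals as BED6
#'
#' @param x Tibble with `chrom`, `start`, `end` and optionally `id`/`name`,
#'   `score`, `strand` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  check_intervals(x, "write_bed")
  name <- x[["id"]] %||% x[["name"]] %||% rep(".", nrow(x))
  score <- x[["score"]] %||% rep(0, nrow(x))
  strand <- x[["strand"]] %||% rep(".", nrow(x))
  strand <- ifelse(strand %in% c("+", "-"), strand, ".")
  readr::write_lines(
    paste(x$chrom, x$start, x$end, name, score, strand, sep = "\t"),
    path
  )
  invisible(path)
}

#' Merge a host annotation with a custom locus annotation
#'
#' Mirrors the merged-GTF construction used for proviral-locus counting: the
#' two feature sets are concatenated, then ordered by chromosome (numeric
#' names first, in numeric order; others lexicographic) and then by start
#' position, stably.
#'
#' @param host,custom Annotation tibbles (see [read_gtf]).
#' @return The merged, sorted annotation tibble.
#' @export
merge_annotations <- function(host, custom) {
  merged <- dplyr::bind_rows(host, custom)
  key <- paste(merged$kind, merged$id, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    abort(sprintf("merge_annotations: duplicate (kind, id) pair: (%s, %s)",
                  merged$kind[dup][1], merged$id[dup][1]))
  }
  sort_features(merged)
}

#' Find features overlapping a query interval
#'
#' Interval-overlap query against an annotation table, strand-blind.
#' Intervals overlap when they share at least one base.
#'
#' @param features Annotation tibble.
#' @param chrom,start,end Query interval (0-based half-open).
#' @return The rows of `features` overlapping the query.
#' @export
overlap_query <- function(features, chrom, start, end) {
  if (nrow(features) == 0) return(features)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  subj <- as_granges(features)
  hits <- GenomicRanges::findOverlaps(q, subj, ignore.strand = TRUE)
  features[S4Vectors::subjectHits(hits), , drop = FALSE]
}
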