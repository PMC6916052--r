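# Fixture builders shared across test files. Everything is generated in code
# at test time; no binary fixtures.

random_dna <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = ""))
}

# Substitute exactly n positions of a sequence (no indels), returning the
# mutant and the 1-based edited positions.
substitute_at <- function(seq, n_subs, seed) {
  withr::with_seed(seed, {
    chars <- strsplit(seq, "")[[1]]
    pos <- sample(length(chars), n_subs)
    for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    list(seq = paste(chars, collapse = ""), positions = sort(pos))
  })
}

# A minimal annotation tibble row set.
feature_row <- function(chrom, start, end, strand, kind, id, gene_name = NULL) {
  attrs <- c(gene_id = id)
  if (!is.null(gene_name)) attrs <- c(attrs, gene_name = gene_name)
  tibble::tibble(chrom = chrom, start = as.integer(start), end = as.integer(end),
                 strand = strand, kind = kind, id = id,
                 source = "test", score = ".", frame = ".",
                 attributes = list(attrs))
}

# Raw SAM text for one record.
sam_line <- function(qname, flag, chrom = "chr1", pos1 = 100, cigar = "100M",
                     tags = character(0)) {
  base <- paste(qname, flag, chrom, pos1, 60, cigar, "=", 0, 0, "*", "*",
                sep = "\t")
  if (length(tags)) base <- paste(c(base, tags), collapse = "\t")
  base
}

sam_header <- function(chroms = "chr1", len = 100000) {
  c("@HD\tVN:1.6\tSO:unsorted", sprintf("@SQ\tSN:%s\tLN:%d", chroms, len))
}

write_sam_text <- function(lines, path = tempfile(fileext = ".sam")) {
  writeLines(lines, path)
  path
}

# A two-locus repetitive fixture in annotation layout.
two_locus_annotation <- function() {
  dplyr::bind_rows(
    feature_row("chr1", 1000, 9000, "+", "locus", "provA"),
    feature_row("chr1", 20000, 28000, "-", "locus", "provB")
  )
}

# Literal re-implementation of the published unique-mapping filter command on
# SAM text (keep proper pairs, drop tag-bearing lines), plus the declared
# fragment-level consistency: a pair with any tagged line loses both mates.
# Works on text only; the independent oracle for filter_unique_pairs.
oracle_filter_sam_text <- function(lines, tag = "ZS") {
  body <- lines[!grepl("^@", lines)]
  f <- vapply(strsplit(body, "\t"), function(x) as.integer(x[2]), integer(1))
  qn <- vapply(strsplit(body, "\t"), `[[`, character(1), 1)
  proper <- bitwAnd(f, 2L) > 0
  tagged <- grepl(paste0("\t", tag, ":"), body)
  bad_qn <- unique(qn[proper & tagged])
  body[proper & !tagged & !(qn %in% bad_qn)]
}
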