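#' Scan a genome for degenerate copies of a query element
#'
#' Seed-and-extend search for diverged copies of a prototype element (such as
#' a ~433-nt RcRE) on both strands of every contig. Exact k-mer seeds
#' (default k = 12) locate candidate regions; each candidate window of query
#' length plus a margin is then aligned globally (query) against the window
#' (local in the subject) under BLASTN-like scoring, and hits at or above the
#' identity threshold are kept. Overlapping candidates are resolved greedily
#' by best alignment score, ties broken by leftmost coordinate then plus
#' strand. The result is deterministic for fixed inputs.
#'
#' @param genome Genome tibble from [read_fasta] (columns `name`, `seq`).
#' @param query Query element DNA string (no `N`s, length >= 50), optionally
#'   named.
#' @param threshold Minimum percent identity, in (50, 100]. Default 94, the
#'   usual cutoff for calling a degenerate RcRE copy.
#' @param params Scoring parameters from [scan_params].
#' @param min_len_frac,max_len_frac Accepted hit length relative to the query
#'   length (defaults 0.9 and 1.1).
#' @return Tibble of hits: `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `identity_pct`, `score`, `hit_seq` (query-strand oriented),
#'   `location` (1-based display string), and `alignment` (list of
#'   `rcre_alignment`). Sorted by chromosome and start.
#' @seealso [scan_genome_exhaustive] for the brute-force reference scanner.
#' @export
scan_genome <- function(genome, query, threshold = 94, params = scan_params(),
                        min_len_frac = 0.9, max_len_frac = 1.1) {
  stopifnot(all(c("name", "seq") %in% names(genome)), nrow(genome) > 0)
  if (threshold <= 50 || threshold > 100) {
    abort("scan_genome: threshold must be in (50, 100]")
  }
  query <- normalize_dna(query, "query")
  qlen <- nchar(query)
  if (qlen < 50) abort("scan_genome: query shorter than 50 nt")
  if (grepl("N", query, fixed = TRUE)) abort("scan_genome: query must not contain N")
  if (all(nchar(genome$seq) < qlen)) {
    abort("scan_genome: query is longer than every contig")
  }

  hits <- purrr::pmap(genome, function(name, seq, ...) {
    n <- nchar(seq)
    if (n < qlen) return(NULL)
    fwd <- scan_contig(seq, query, params, min_len_frac, max_len_frac)
    rev <- scan_contig(revcomp(seq), query, params, min_len_frac, max_len_frac)
    out <- list()
    if (nrow(fwd) > 0) out <- c(out, list(dplyr::mutate(fwd, strand = "+")))
    if (nrow(rev) > 0) {
      out <- c(out, list(dplyr::mutate(rev,
        strand = "-",
        tmp_start = n - .data$end,
        end = n - .data$start,
        start = .data$tmp_start
      ) |> dplyr::select(-"tmp_start")))
    }
    if (length(out) == 0) return(NULL)
    dplyr::mutate(dplyr::bind_rows(out), chrom = name)
  })
  hits <- dplyr::bind_rows(hits)
  if (nrow(hits) == 0) return(empty_hits())

  hits <- dplyr::filter(hits, .data$identity_pct >= threshold)
  if (nrow(hits) == 0) return(empty_hits())
  hits <- greedy_nonoverlap(hits)
  hits <- dplyr::mutate(hits, location = format_location(.data$chrom, .data$start, .data$end))
  sort_features(hits)[, c("chrom", "start", "end", "strand", "identity_pct",
                          "score", "hit_seq", "location", "alignment")]
}

empty_hits <- function() {
  tibble::tibble(
    chrom = character(), start = integer(), end = integer(), strand = character(),
    identity_pct = double(), score = double(), hit_seq = character(),
    location = character(), alignment = list()
  )
}

# Seeded scan of one contig orientation. Returns hits in the scanned
# orientation's coordinates (caller reflects minus-strand coordinates).
scan_contig <- function(seq, query, params, min_len_frac, max_len_frac) {
  qlen <- nchar(query)
  k <- params$k
  pad <- ceiling(0.1 * qlen) + 5L
  n <- nchar(seq)

  starts <- seed_projected_starts(seq, query, k)
  if (length(starts) == 0) return(empty_scan_rows())
  starts <- sort(starts)
  cluster <- cumsum(c(TRUE, diff(starts) > qlen %/% 2))
  windows <- tibble::tibble(proj = starts, cluster = cluster) |>
    dplyr::summarise(lo = min(.data$proj), hi = max(.data$proj), .by = "cluster") |>
    dplyr::mutate(
      win_start = pmax(0L, .data$lo - pad),
      win_end = pmin(n, .data$hi + qlen + pad)
    )

  subj <- Biostrings::DNAStringSet(substring(seq, windows$win_start + 1L, windows$win_end))
  rows <- purrr::map(seq_len(nrow(windows)), function(i) {
    al <- Biostrings::pairwiseAlignment(
      query, subj[[i]], type = "global-local",
      substitutionMatrix = params$submat,
      gapOpening = params$gap_open, gapExtension = params$gap_extend
    )
    s0 <- windows$win_start[i] + Biostrings::start(Biostrings::subject(al)) - 1L
    e0 <- windows$win_start[i] + Biostrings::end(Biostrings::subject(al))
    width <- e0 - s0
    if (width < min_len_frac * qlen || width > max_len_frac * qlen) return(NULL)
    aln <- new_rcre_alignment(
      aligned_a = as.character(Biostrings::alignedPattern(al)),
      aligned_b = as.character(Biostrings::alignedSubject(al)),
      score = Biostrings::score(al)
    )
    tibble::tibble(
      start = s0, end = e0,
      identity_pct = aln$identity_pct, score = aln$score,
      hit_seq = substring(seq, s0 + 1L, e0),
      alignment = list(aln)
    )
  })
  dplyr::bind_rows(rows)
}

empty_scan_rows <- function() {
  tibble::tibble(start = integer(), end = integer(), identity_pct = double(),
                 score = double(), hit_seq = character(), alignment = list())
}

# Exact k-mer seed positions, projected back to candidate hit start offsets
# (0-based) on the scanned sequence.
seed_projected_starts <- function(seq, query, k) {
  qlen <- nchar(query)
  kmers <- substring(query, seq_len(qlen - k + 1L), seq_len(qlen - k + 1L) + k - 1L)
  offsets <- seq_len(qlen - k + 1L) - 1L
  keep <- !duplicated(kmers)
  dict <- Biostrings::PDict(Biostrings::DNAStringSet(kmers[keep]))
  subject <- Biostrings::DNAString(seq)
  m <- Biostrings::matchPDict(dict, subject)
  starts <- Biostrings::startIndex(m)
  kept_kmers <- kmers[keep]
  proj <- purrr::imap(starts, function(pos, i) {
    if (is.null(pos) || length(pos) == 0) return(integer(0))
    # every query offset at which this k-mer occurs projects each genomic match
    qoffs <- offsets[kmers == kept_kmers[i]]
    as.integer(outer(pos - 1L, qoffs, "-"))
  })
  proj <- unlist(proj, use.names = FALSE)
  proj[proj >= -k & proj <= nchar(seq)]
}

# Greedy best-score selection of non-overlapping hits (genomic overlap,
# strand-blind). Ties: leftmost start, then plus strand first.
greedy_nonoverlap <- function(hits) {
  ord <- order(-hits$score, hits$start, hits$strand != "+")
  hits <- hits[ord, , drop = FALSE]
  kept <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    prior <- which(kept & hits$chrom == hits$chrom[i])
    clash <- any(hits$start[prior] < hits$end[i] & hits$end[prior] > hits$start[i])
    kept[i] <- !clash
  }
  hits[kept, , drop = FALSE]
}

#' Exhaustive sliding-window reference scanner
#'
#' Brute-force scanner used as the independent oracle for [scan_genome]: at
#' every offset on both strands it computes the ungapped percent identity of
#' the query against the same-length genomic window, keeps offsets at or
#' above the threshold, and collapses runs of overlapping qualifying offsets
#' to the best-identity offset (leftmost on ties). No seeding, no alignment
#' heuristics, no indels; intended for small genomes.
#'
#' @inheritParams scan_genome
#' @return Tibble with `chrom`, `start`, `end`, `strand`, `identity_pct`.
#' @export
scan_genome_exhaustive <- function(genome, query, threshold = 94) {
  query <- normalize_dna(query, "query")
  qlen <- nchar(query)
  qraw <- charToRaw(query)
  one_orientation <- function(seq) {
    n <- nchar(seq)
    noff <- n - qlen + 1L
    if (noff < 1L) return(integer(0))
    graw <- charToRaw(seq)
    counts <- integer(noff)
    for (i in seq_len(qlen)) {
      counts <- counts + (graw[i:(i + noff - 1L)] == qraw[i])
    }
    counts
  }
  rows <- purrr::pmap(genome, function(name, seq, ...) {
    n <- nchar(seq)
    out <- list()
    for (str in c("+", "-")) {
      s <- if (str == "+") seq else revcomp(seq)
      counts <- one_orientation(s)
      idpct <- 100 * counts / qlen
      offs <- which(idpct >= threshold) - 1L
      if (length(offs) == 0) next
      grp <- cumsum(c(TRUE, diff(offs) >= qlen))
      best <- tibble::tibble(off = offs, id = idpct[offs + 1L], grp = grp) |>
        dplyr::slice_max(.data$id, n = 1, by = "grp", with_ties = FALSE)
      start <- if (str == "+") best$off else n - best$off - qlen
      out <- c(out, list(tibble::tibble(
        chrom = name, start = start, end = start + qlen, strand = str,
        identity_pct = best$id
      )))
    }
    dplyr::bind_rows(out)
  })
  rows <- dplyr::bind_rows(rows)
  if (nrow(rows) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer(),
                          strand = character(), identity_pct = double()))
  }
  ord <- order(-rows$identity_pct, rows$start, rows$strand != "+")
  rows <- rows[ord, , drop = FALSE]
  kept <- logical(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    prior <- which(kept & rows$chrom == rows$chrom[i])
    clash <- any(rows$start[prior] < rows$end[i] & rows$end[prior] > rows$start[i])
    kept[i] <- !clash
  }
  sort_features(rows[kept, , drop = FALSE])
}

#' Write scan hits to BED6, TSV, and FASTA
#'
#' The BED score column carries `round(identity_pct * 10)`; the TSV includes
#' the 1-based display location string alongside identity and strand; the
#' FASTA holds the query-oriented hit sequences.
#'
#' @param hits Hit tibble from [scan_genome].
#' @param bed,tsv,fasta Output paths (any may be `NULL` to skip).
#' @return `hits`, invisibly.
#' @export
write_hits <- function(hits, bed = NULL, tsv = NULL, fasta = NULL) {
  if (!is.null(bed)) {
    write_bed(dplyr::mutate(hits,
      id = paste0("hit_", dplyr::row_number()),
      score = round(.data$identity_pct * 10)
    ), bed)
  }
  if (!is.null(tsv)) {
    readr::write_tsv(
      dplyr::select(hits, "chrom", "start", "end", "strand", "identity_pct",
                    "score", "location"),
      tsv
    )
  }
  if (!is.null(fasta)) {
    write_fasta(tibble::tibble(
      name = paste0(hits$chrom, "_", hits$start, "_", hits$strand),
      seq = hits$hit_seq
    ), fasta)
  }
  invisible(hits)
}
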