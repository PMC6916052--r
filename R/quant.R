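#' Unique-mapping filter configuration
#'
#' Mirrors the standard repetitive-locus filter: keep only proper pairs
#' (FLAG 0x2), drop secondary (0x100) and supplementary (0x800) records, and
#' drop any fragment in which either mate carries the aligner's
#' secondary-score tag (HISAT2 writes `ZS:` on reads with a scored secondary
#' hit; Bowtie2-style aligners use `XS`). A fragment with such a tag maps
#' acceptably well somewhere else and cannot be assigned unambiguously to
#' one proviral locus.
#'
#' @param multihit_tag Two-letter tag whose presence marks a non-unique
#'   alignment (default `"ZS"`).
#' @return A `filter_config` list.
#' @export
filter_config <- function(multihit_tag = "ZS") {
  if (!nzchar(multihit_tag)) abort("filter_config: multihit_tag must be non-empty")
  structure(list(multihit_tag = multihit_tag), class = "filter_config")
}

#' Filter alignments to uniquely-mapped proper pairs
#'
#' Applies [filter_config] semantics with fragment-level consistency: if
#' either mate of a pair carries the multihit tag, both mates are removed,
#' and a kept fragment always retains both mates (records whose mate is
#' absent are dropped as improper).
#'
#' @param alignments Alignment tibble from [read_alignments] (one sample).
#' @param config A [filter_config].
#' @return The kept alignment tibble, with a `filter_stats` attribute: a
#'   tibble with `n_input`, `n_not_proper`, `n_secondary`, `n_multihit`,
#'   `n_orphan`, `n_kept` (categories partition the input). Retrieve it with
#'   [filter_stats].
#' @export
filter_unique_pairs <- function(alignments, config = filter_config()) {
  n_input <- nrow(alignments)
  not_proper <- !alignments$paired | !alignments$proper_pair
  secondary <- !not_proper & (alignments$secondary | alignments$supplementary)
  cand <- !not_proper & !secondary
  tagged <- has_tag(alignments, config$multihit_tag)
  # fragment-level: any tagged primary mate poisons the whole fragment
  tagged_qnames <- unique(alignments$qname[cand & tagged])
  multihit <- cand & alignments$qname %in% tagged_qnames
  kept <- cand & !multihit
  # pair consistency: a kept record must have its mate present
  tab <- table(alignments$qname[kept])
  orphan_qnames <- names(tab)[tab < 2]
  orphan <- kept & alignments$qname %in% orphan_qnames
  kept <- kept & !orphan
  stats <- tibble::tibble(
    n_input = n_input,
    n_not_proper = sum(not_proper),
    n_secondary = sum(secondary),
    n_multihit = sum(multihit),
    n_orphan = sum(orphan),
    n_kept = sum(kept)
  )
  out <- alignments[kept, , drop = FALSE]
  attr(out, "filter_stats") <- stats
  attr(out, "header") <- attr(alignments, "header")
  out
}

#' Retrieve filter statistics
#'
#' @param filtered Output of [filter_unique_pairs].
#' @return The `filter_stats` tibble.
#' @export
filter_stats <- function(filtered) {
  attr(filtered, "filter_stats")
}

# Collapse mate records into fragments: per qname, the union interval of the
# two mates plus the strand implied by the first-in-pair read.
fragments_from_pairs <- function(alignments) {
  if (nrow(alignments) == 0) {
    return(tibble::tibble(qname = character(), chrom = character(),
                          start = integer(), end = integer(),
                          read1_reverse = logical()))
  }
  alignments |>
    dplyr::summarise(
      chrom = .data$chrom[1],
      start = min(.data$start),
      end = max(.data$end),
      read1_reverse = any(.data$reverse_strand[.data$first_in_pair]),
      .by = "qname"
    )
}

#' Count fragments per locus
#'
#' Assigns each fragment (mate pair) of a filtered alignment stream to a
#' locus when its union interval overlaps the locus by at least one base and
#' its orientation matches the library strandedness:
#'
#' * `"reverse"` (dUTP libraries): the first-in-pair read maps antisense to
#'   the locus strand;
#' * `"forward"`: first-in-pair maps sense;
#' * `"unstranded"`: orientation ignored.
#'
#' Fragments that pass the strand rule for two or more loci are discarded as
#' ambiguous (no fractional assignment).
#'
#' @param alignments Filtered alignment tibble (see [filter_unique_pairs]).
#' @param loci Annotation tibble of loci to count (e.g. from
#'   [merge_annotations]); all rows are used as counting targets.
#' @param strandedness One of `"reverse"` (default), `"forward"`,
#'   `"unstranded"`.
#' @return Tibble with `locus_id` and `count`, one row per locus (zero rows
#'   included), plus an `assignment_stats` attribute tibble with
#'   `n_fragments`, `n_assigned`, `n_ambiguous`, `n_wrong_strand`,
#'   `n_unassigned`.
#' @export
count_fragments <- function(alignments, loci,
                            strandedness = c("reverse", "forward", "unstranded")) {
  strandedness <- match.arg(strandedness)
  if (nrow(loci) == 0) abort("count_fragments: empty locus set")
  frags <- fragments_from_pairs(alignments)
  counts <- stats::setNames(integer(nrow(loci)), loci$id)
  stats <- tibble::tibble(n_fragments = nrow(frags), n_assigned = 0L,
                          n_ambiguous = 0L, n_wrong_strand = 0L, n_unassigned = 0L)
  if (nrow(frags) > 0) {
    fr_gr <- GenomicRanges::GRanges(frags$chrom,
                                    IRanges::IRanges(frags$start + 1L, frags$end))
    loci_gr <- as_granges(loci)
    ov <- GenomicRanges::findOverlaps(fr_gr, loci_gr, ignore.strand = TRUE)
    ovd <- tibble::tibble(
      frag = S4Vectors::queryHits(ov),
      locus = S4Vectors::subjectHits(ov)
    )
    if (strandedness != "unstranded") {
      locus_strand <- loci$strand[ovd$locus]
      # fragment orientation: strand the transcript would be on, given that
      # in a dUTP ("reverse") library read1 is antisense to the transcript
      r1rev <- frags$read1_reverse[ovd$frag]
      frag_sense <- ifelse(r1rev, "+", "-")       # reverse library
      if (strandedness == "forward") frag_sense <- ifelse(r1rev, "-", "+")
      ok <- locus_strand == frag_sense | !locus_strand %in% c("+", "-")
      wrong_frags <- setdiff(unique(ovd$frag), unique(ovd$frag[ok]))
      stats$n_wrong_strand <- length(wrong_frags)
      ovd <- ovd[ok, , drop = FALSE]
    }
    nhit <- table(ovd$frag)
    uniq <- as.integer(names(nhit)[nhit == 1])
    ambiguous <- as.integer(names(nhit)[nhit > 1])
    stats$n_ambiguous <- length(ambiguous)
    stats$n_assigned <- length(uniq)
    stats$n_unassigned <- nrow(frags) - stats$n_assigned - stats$n_ambiguous -
      stats$n_wrong_strand
    assigned <- ovd[ovd$frag %in% uniq, , drop = FALSE]
    tab <- table(factor(assigned$locus, levels = seq_len(nrow(loci))))
    counts <- stats::setNames(as.integer(tab), loci$id)
  }
  out <- tibble::tibble(locus_id = loci$id, count = unname(counts))
  attr(out, "assignment_stats") <- stats
  out
}

#' Retrieve fragment-assignment statistics
#'
#' @param counts Output of [count_fragments].
#' @return The `assignment_stats` tibble.
#' @export
assignment_stats <- function(counts) {
  attr(counts, "assignment_stats")
}

#' Normalized fragment coverage in fixed-width bins
#'
#' Bins every chromosome seen in the input into `bin_width`-nt windows and
#' reports, per bin, `overlapping fragments * 1e9 / (bin_width * total_kept)`
#' — fragments per kilobase of bin per million kept fragments (FPKM-style
#' track normalization).
#'
#' @param alignments Filtered alignment tibble.
#' @param bin_width Bin width in nt (default 50).
#' @param total_kept Library size used for normalization; defaults to the
#'   number of fragments in `alignments`.
#' @param chrom_sizes Optional named vector of chromosome lengths; defaults
#'   to the maximum end coordinate observed per chromosome.
#' @return Tibble with `chrom`, `start`, `end`, `value` (zero-valued bins
#'   included).
#' @export
coverage_track <- function(alignments, bin_width = 50, total_kept = NULL,
                           chrom_sizes = NULL) {
  if (bin_width < 1) abort("coverage_track: bin_width must be >= 1")
  frags <- fragments_from_pairs(alignments)
  total_kept <- total_kept %||% nrow(frags)
  if (is.null(total_kept) || total_kept == 0) {
    abort("coverage_track: total_kept is zero")
  }
  if (is.null(chrom_sizes)) {
    if (nrow(frags) == 0) {
      return(tibble::tibble(chrom = character(), start = integer(),
                            end = integer(), value = double()))
    }
    chrom_sizes <- tapply(frags$end, frags$chrom, max)
  }
  bins <- purrr::imap(as.list(chrom_sizes), function(len, ch) {
    starts <- seq(0L, len - 1L, by = bin_width)
    tibble::tibble(chrom = ch, start = as.integer(starts),
                   end = as.integer(pmin(starts + bin_width, len)))
  })
  bins <- dplyr::bind_rows(bins)
  value <- numeric(nrow(bins))
  if (nrow(frags) > 0) {
    bin_gr <- GenomicRanges::GRanges(bins$chrom, IRanges::IRanges(bins$start + 1L, bins$end))
    fr_gr <- GenomicRanges::GRanges(frags$chrom, IRanges::IRanges(frags$start + 1L, frags$end))
    value <- GenomicRanges::countOverlaps(bin_gr, fr_gr, ignore.strand = TRUE)
  }
  dplyr::mutate(bins, value = value * 1e9 / (bin_width * total_kept))
}

#' Write a coverage track as bedGraph
#'
#' @param track Output of [coverage_track].
#' @param path Output path.
#' @param track_name Name for the bedGraph track line.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, track_name = "coverage") {
  lines <- c(
    sprintf('track type=bedGraph name="%s"', track_name),
    paste(track$chrom, track$start, track$end,
          formatC(track$value, format = "g", digits = 8), sep = "\t")
  )
  readr::write_lines(lines, path)
  invisible(path)
}
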