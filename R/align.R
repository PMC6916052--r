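#' Scoring parameters for element alignment and scanning
#'
#' BLASTN-like defaults: match +2, mismatch -3, gap opening penalty 5, gap
#' extension penalty 2 (a gap of length L costs `5 + 2 L` score units). `N`
#' bases never match anything, including another `N`: they score as
#' mismatches and never count as identical columns.
#'
#' @param match Match score (positive).
#' @param mismatch Mismatch score (negative).
#' @param gap_open Gap opening penalty (positive cost).
#' @param gap_extend Per-base gap extension penalty (positive cost).
#' @param k Seed word length used by [scan_genome].
#' @return A list of scoring parameters with the substitution matrix attached.
#' @export
scan_params <- function(match = 2, mismatch = -3, gap_open = 5, gap_extend = 2,
                        k = 12) {
  bases <- c("A", "C", "G", "T", "N")
  sub <- matrix(mismatch, 5, 5, dimnames = list(bases, bases))
  diag(sub) <- match
  sub["N", "N"] <- mismatch   # N never matches, even itself
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend, k = k, submat = sub)
}

#' Optimal global (Needleman-Wunsch) alignment of two DNA strings
#'
#' Percent identity is the number of identical aligned columns divided by the
#' total number of alignment columns (gap columns count against identity),
#' the convention BLAST reports.
#'
#' @param a,b DNA strings over `{A,C,G,T,N}` (case-insensitive; `U` allowed).
#' @param params Scoring parameters from [scan_params].
#' @return An object of class `rcre_alignment`: a list with `aligned_a`,
#'   `aligned_b` (gapped strings of equal length), `n_match`, `n_columns`,
#'   `identity_pct`, and `score`.
#' @export
#' @examples
#' aln <- global_align("ACGT", "ACGA")
#' aln$identity_pct  # 75
global_align <- function(a, b, params = scan_params()) {
  if (!nzchar(a) || !nzchar(b)) abort("global_align: empty input sequence")
  a <- normalize_dna(a, "global_align input a")
  b <- normalize_dna(b, "global_align input b")
  al <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = params$submat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend
  )
  new_rcre_alignment(
    aligned_a = as.character(Biostrings::alignedPattern(al)),
    aligned_b = as.character(Biostrings::alignedSubject(al)),
    score = Biostrings::score(al)
  )
}

new_rcre_alignment <- function(aligned_a, aligned_b, score) {
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  is_match <- ca == cb & ca != "-" & ca != "N"
  structure(
    list(
      aligned_a = aligned_a,
      aligned_b = aligned_b,
      n_match = sum(is_match),
      n_columns = length(ca),
      identity_pct = 100 * sum(is_match) / length(ca),
      score = score
    ),
    class = "rcre_alignment"
  )
}

#' @export
print.rcre_alignment <- function(x, ...) {
  cat(sprintf("<rcre_alignment> %d columns, %d matches, identity %.2f%%, score %g\n",
              x$n_columns, x$n_match, x$identity_pct, x$score))
  invisible(x)
}

#' Mismatch (highlighter) track from a pairwise alignment
#'
#' Lists the alignment columns at which the two sequences differ, with the
#' substitution observed in the second sequence (or `gap`), the raw material
#' of a highlighter plot.
#'
#' @param alignment An `rcre_alignment` from [global_align].
#' @return Tibble with `column` (0-based alignment column), `ref_char`,
#'   `alt_char`, and `type` (one of `"A"`, `"C"`, `"G"`, `"T"`, `"N"`,
#'   `"gap"`).
#' @export
mismatch_track <- function(alignment) {
  ca <- strsplit(alignment$aligned_a, "")[[1]]
  cb <- strsplit(alignment$aligned_b, "")[[1]]
  diff <- !(ca == cb & ca != "-" & ca != "N")
  idx <- which(diff)
  tibble::tibble(
    column = idx - 1L,
    ref_char = ca[idx],
    alt_char = cb[idx],
    type = as.character(ifelse(ca[idx] == "-" | cb[idx] == "-", "gap", cb[idx]))
  )
}

#' Highlighter tracks for a set of sequences against one reference
#'
#' Globally aligns each sequence to the reference and reports the mismatch
#' columns, the data behind a highlighter mismatch plot.
#'
#' @param reference Reference DNA string.
#' @param others Character vector (optionally named) of DNA strings.
#' @param params Scoring parameters from [scan_params].
#' @return Tibble with one row per mismatch column: `seq_id`, `identity_pct`
#'   of that sequence, plus the [mismatch_track] columns. Sequences identical
#'   to the reference contribute zero rows but still appear in the
#'   `identities` attribute (a tibble of `seq_id`, `identity_pct`,
#'   `n_columns`).
#' @export
highlighter <- function(reference, others, params = scan_params()) {
  ids <- names(others) %||% paste0("seq", seq_along(others))
  alns <- purrr::map(others, ~ global_align(reference, .x, params))
  tracks <- purrr::map2(alns, ids, function(al, id) {
    dplyr::mutate(mismatch_track(al), seq_id = id, identity_pct = al$identity_pct,
                  .before = 1)
  })
  identities <- tibble::tibble(
    seq_id = ids,
    identity_pct = unname(purrr::map_dbl(alns, "identity_pct")),
    n_columns = unname(purrr::map_int(alns, ~ as.integer(.x$n_columns)))
  )
  out <- dplyr::bind_rows(tracks)
  if (nrow(out) == 0) {
    out <- tibble::tibble(seq_id = character(), identity_pct = double(),
                          column = integer(), ref_char = character(),
                          alt_char = character(), type = character())
  }
  attr(out, "identities") <- identities
  out
}

#' Highlighter mismatch plot
#'
#' Draws each sequence as a horizontal line with colored ticks at mismatch
#' columns, the usual way divergence from a prototype element is shown.
#'
#' @param tracks Output of [highlighter].
#' @param n_columns Alignment length used for the x-axis limit; defaults to
#'   the maximum mismatch column seen.
#' @return A ggplot object.
#' @export
plot_highlighter <- function(tracks, n_columns = NULL) {
  ids <- attr(tracks, "identities")
  seq_levels <- if (!is.null(ids)) rev(ids$seq_id) else rev(unique(tracks$seq_id))
  n_columns <- n_columns %||% (max(c(tracks$column, 0)) + 1)
  base <- tibble::tibble(seq_id = factor(seq_levels, levels = seq_levels))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = base,
      ggplot2::aes(x = 0, xend = n_columns, y = .data$seq_id, yend = .data$seq_id),
      linewidth = 0.4, colour = "grey60"
    ) +
    ggplot2::geom_point(
      data = dplyr::mutate(tracks, seq_id = factor(.data$seq_id, levels = seq_levels)),
      ggplot2::aes(x = .data$column, y = .data$seq_id, colour = .data$type),
      shape = "|", size = 4
    ) +
    ggplot2::scale_colour_manual(
      values = c(A = "#33a02c", C = "#1f78b4", G = "#ff7f00", T = "#e31a1c",
                 N = "grey40", gap = "grey20"),
      name = "mismatch"
    ) +
    ggplot2::labs(x = "alignment column", y = NULL) +
    ggplot2::theme_minimal()
}
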