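#' Place element hits in genomic context
#'
#' For each hit, reports the overlapping gene (if any), whether the hit is
#' sense or antisense to that gene's transcription, whether it falls in
#' exonic or intronic sequence, and the best-overlapping catalog LTR.
#'
#' Gene assignment uses the gene's full span (features of kind `"gene"`) and
#' requires the overlap to cover at least `min_gene_frac` of the hit length;
#' when a hit overlaps several genes the one with the largest overlap wins
#' (ambiguity is recorded in `n_genes_overlapped`). A hit assigned to a gene
#' is `exonic` if it overlaps any annotated exon of that gene (union of
#' exons across transcripts), else `intronic`; hits with no gene are
#' `intergenic` with orientation `not_applicable`. LTR membership requires
#' reciprocal overlap of at least `min_ltr_frac` in both directions.
#'
#' @param hits Hit tibble from [scan_genome] (needs `chrom`, `start`, `end`,
#'   `strand`; extra columns pass through).
#' @param genes Annotation tibble with features of kind `"gene"` and
#'   optionally `"exon"` (exons matched to genes by `id`).
#' @param ltr_catalog Annotation tibble of LTRs (e.g. from [read_bed]), or
#'   `NULL`.
#' @param min_gene_frac Minimum fraction of the hit covered by the gene span
#'   for assignment (default 0.5).
#' @param min_ltr_frac Minimum reciprocal-overlap fraction for an LTR match
#'   (default 0.8).
#' @return `hits` with added columns `gene_id`, `gene_name`, `gene_strand`,
#'   `orientation` (`sense`/`antisense`/`not_applicable`), `context`
#'   (`exonic`/`intronic`/`intergenic`), `ltr_id`, `n_genes_overlapped`.
#' @export
annotate_hits <- function(hits, genes, ltr_catalog = NULL,
                          min_gene_frac = 0.5, min_ltr_frac = 0.8) {
  gene_rows <- dplyr::filter(genes, .data$kind == "gene")
  exon_rows <- dplyr::filter(genes, .data$kind == "exon")
  n <- nrow(hits)
  ann <- tibble::tibble(
    gene_id = rep(NA_character_, n), gene_name = rep(NA_character_, n),
    gene_strand = rep(NA_character_, n),
    orientation = rep("not_applicable", n), context = rep("intergenic", n),
    ltr_id = rep(NA_character_, n), n_genes_overlapped = rep(0L, n)
  )
  for (i in seq_len(n)) {
    h <- hits[i, ]
    ov <- overlap_query(gene_rows, h$chrom, h$start, h$end)
    if (nrow(ov) > 0) {
      ovlen <- pmin(ov$end, h$end) - pmax(ov$start, h$start)
      enough <- ovlen >= min_gene_frac * (h$end - h$start)
      ov <- ov[enough, , drop = FALSE]
      ovlen <- ovlen[enough]
    }
    if (nrow(ov) > 0) {
      ann$n_genes_overlapped[i] <- nrow(ov)
      if (nrow(ov) > 1 && length(unique(ov$strand)) > 1) {
        warn(sprintf("hit %s:%d-%d overlaps genes on both strands; using largest overlap",
                     h$chrom, h$start, h$end))
      }
      best <- which.max(ovlen)
      g <- ov[best, ]
      ann$gene_id[i] <- g$id
      ann$gene_name[i] <- g$attributes[[1]]["gene_name"] %||% NA_character_
      ann$gene_strand[i] <- g$strand
      ann$orientation[i] <- if (h$strand == g$strand) "sense" else "antisense"
      gene_exons <- exon_rows[exon_rows$id == g$id, , drop = FALSE]
      ex <- overlap_query(gene_exons, h$chrom, h$start, h$end)
      ann$context[i] <- if (nrow(ex) > 0) "exonic" else "intronic"
    }
    if (!is.null(ltr_catalog) && nrow(ltr_catalog) > 0) {
      lov <- overlap_query(ltr_catalog, h$chrom, h$start, h$end)
      if (nrow(lov) > 0) {
        ovlen <- pmin(lov$end, h$end) - pmax(lov$start, h$start)
        hlen <- h$end - h$start
        recip <- ovlen >= min_ltr_frac * hlen & ovlen >= min_ltr_frac * (lov$end - lov$start)
        if (any(recip)) {
          ann$ltr_id[i] <- lov$id[recip][which.max(ovlen[recip])]
        }
      }
    }
  }
  dplyr::bind_cols(hits, ann)
}

#' Collapse hits with identical sequence into unique elements
#'
#' Degenerate element copies recovered at different genomic positions may be
#' letter-for-letter identical (e.g. the two direct-repeat solo LTRs inside
#' one gene region); this groups hits by exact `hit_seq` string and counts
#' the distinct annotated gene regions each unique sequence occupies.
#'
#' @param annotated_hits Output of [annotate_hits] (needs `hit_seq` and
#'   `gene_id`).
#' @return Tibble with one row per unique sequence: `group_id`,
#'   `representative_seq`, `n_hits`, `n_regions` (distinct non-missing
#'   `gene_id`s among members), and `members` (list of member row tibbles).
#' @export
collapse_unique <- function(annotated_hits) {
  stopifnot(all(c("hit_seq", "gene_id") %in% names(annotated_hits)))
  annotated_hits |>
    dplyr::group_by(representative_seq = .data$hit_seq) |>
    dplyr::summarise(
      n_hits = dplyr::n(),
      n_regions = dplyr::n_distinct(.data$gene_id[!is.na(.data$gene_id)]),
      members = list(dplyr::pick(dplyr::everything())),
      .groups = "drop"
    ) |>
    dplyr::mutate(group_id = paste0("uel_", dplyr::row_number()), .before = 1)
}

#' Write an annotated-hit table in locus-summary style
#'
#' Emits a TSV with gene id, gene name, a 1-based display location string,
#' orientation, genomic context, and LTR number — the layout of a summary
#' table of identified elements.
#'
#' @param annotated_hits Output of [annotate_hits].
#' @param path Output path.
#' @return The table written, invisibly.
#' @export
write_annotation_table <- function(annotated_hits, path) {
  out <- tibble::tibble(
    gene_id = annotated_hits$gene_id,
    gene_name = annotated_hits$gene_name,
    location = format_location(annotated_hits$chrom, annotated_hits$start,
                               annotated_hits$end),
    orientation = annotated_hits$orientation,
    context = annotated_hits$context,
    ltr = annotated_hits$ltr_id,
    identity_pct = round(annotated_hits$identity_pct, 1)
  )
  readr::write_tsv(out, path)
  invisible(out)
}
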