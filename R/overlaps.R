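#' Benjamini-Hochberg step-up adjusted p-values
#'
#' The classic FDR step-up: sort the m p-values ascending, set
#' q_(i) = min over j >= i of p_(j) * m / j, cap at 1, and return the
#' adjusted values in the original input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order as `p`.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("bh_adjust: p-values must be in [0, 1] and non-missing")
  }
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(1, cummin(rev(p[ord] * m / seq_len(m)))[m:1])
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Filter a differential-expression table at an FDR threshold
#'
#' Returns the genes whose BH-adjusted p-value is strictly below `alpha`
#' (the strict `< alpha` convention). If the table has no `q_value` column,
#' q-values are computed from `p_value` with [bh_adjust].
#'
#' @param de_table Tibble with `gene_id` and `p_value` (and optionally
#'   `q_value`) columns; gene ids must be unique.
#' @param alpha FDR threshold (default 0.01).
#' @return Character vector of gene ids passing the filter.
#' @export
filter_de <- function(de_table, alpha = 0.01) {
  if (nrow(de_table) == 0) return(character(0))
  stopifnot("gene_id" %in% names(de_table))
  if (anyDuplicated(de_table$gene_id)) abort("filter_de: duplicate gene ids")
  q <- de_table[["q_value"]] %||% bh_adjust(de_table$p_value)
  de_table$gene_id[q < alpha]
}

#' Three-way exclusive set partition (Venn regions)
#'
#' Partitions the union of three gene sets into the seven exclusive Venn
#' regions.
#'
#' @param a,b,c Character vectors (gene ids); duplicates are ignored.
#' @param names Length-3 labels for the sets, used in the `region` column.
#' @return Tibble with columns `region` (e.g. `"A"`, `"AB"`, `"ABC"` built
#'   from the labels), `n`, and `ids` (list of character vectors). Regions
#'   are pairwise disjoint and their union is `union(a, b, c)`.
#' @export
venn3 <- function(a, b, c, names = c("A", "B", "C")) {
  stopifnot(length(names) == 3)
  a <- unique(a); b <- unique(b); c <- unique(c)
  u <- unique(c(a, b, c))
  ina <- u %in% a; inb <- u %in% b; inc <- u %in% c
  regions <- list(
    ina & !inb & !inc, !ina & inb & !inc, !ina & !inb & inc,
    ina & inb & !inc, ina & !inb & inc, !ina & inb & inc,
    ina & inb & inc
  )
  labels <- c(names[1], names[2], names[3],
              paste0(names[1], "&", names[2]),
              paste0(names[1], "&", names[3]),
              paste0(names[2], "&", names[3]),
              paste0(names[1], "&", names[2], "&", names[3]))
  tibble::tibble(
    region = labels,
    n = vapply(regions, sum, integer(1)),
    ids = lapply(regions, function(sel) u[sel])
  )
}

#' Write Venn region counts as TSV
#'
#' @param partition Output of [venn3].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_venn <- function(partition, path) {
  readr::write_tsv(
    dplyr::mutate(partition,
                  ids = vapply(.data$ids, paste, character(1), collapse = ",")),
    path
  )
  invisible(path)
}

#' Bar chart of Venn region sizes
#'
#' @param partition Output of [venn3].
#' @return A ggplot object.
#' @export
plot_venn_counts <- function(partition) {
  d <- dplyr::mutate(partition, region = factor(.data$region, levels = .data$region))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$region, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4, size = 3) +
    ggplot2::labs(x = "exclusive region", y = "genes") +
    ggplot2::theme_minimal()
}
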