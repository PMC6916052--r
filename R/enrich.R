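#' Median-of-ratios size factors
#'
#' Per-sample scale factors for sequencing depth: the reference for each
#' locus is its geometric mean across samples (loci with any zero count are
#' excluded from the reference), and each sample's factor is the median over
#' loci of its counts divided by the reference.
#'
#' @param counts Count tibble: first column `locus_id`, one integer column
#'   per sample. A plain matrix with rownames also works.
#' @return Named numeric vector of size factors, one per sample.
#' @export
#' @examples
#' counts <- tibble::tibble(locus_id = c("L1", "L2"), s1 = c(10L, 100L),
#'                          s2 = c(20L, 200L))
#' size_factors(counts)  # 1/sqrt(2), sqrt(2)
size_factors <- function(counts) {
  m <- counts_to_matrix(counts)
  pos <- rowSums(m == 0) == 0
  if (!any(pos)) {
    abort(paste("size_factors: no locus has positive counts in all samples;",
                "consider a pseudo-reference (e.g. add loci or use poscounts-style estimation)"))
  }
  ref <- exp(rowMeans(log(m[pos, , drop = FALSE])))
  apply(m[pos, , drop = FALSE], 2, function(col) stats::median(col / ref))
}

counts_to_matrix <- function(counts) {
  if (is.matrix(counts)) {
    storage.mode(counts) <- "double"
    return(counts)
  }
  stopifnot("locus_id" %in% names(counts))
  m <- as.matrix(counts[setdiff(names(counts), "locus_id")])
  rownames(m) <- counts$locus_id
  if (any(m < 0) || any(m != round(m))) {
    abort("counts must be non-negative integers")
  }
  storage.mode(m) <- "double"
  m
}

#' Per-locus negative-binomial Wald test between two conditions
#'
#' A lightweight NB Wald test for proviral-locus counts: counts are
#' normalized by size factors, the per-locus dispersion is estimated by the
#' method of moments (`alpha = (var - mean) / mean^2` on normalized counts,
#' pooled within groups) and, by default, shared across loci as the mean of
#' the per-locus estimates; the log2 fold change is
#' `log2((mean_trt + 0.5) / (mean_ref + 0.5))` and its standard error comes
#' from the NB delta method. Two-sided normal (Wald) p-values are BH-adjusted
#' across the loci of the contrast. Loci with zero counts in both groups are
#' omitted. There is no shrinkage of fold changes or outlier filtering; the
#' test is validated by parameter recovery on simulated counts, not by
#' agreement with any particular DE package.
#'
#' @param counts Count tibble (see [size_factors]).
#' @param sample_meta Tibble with `sample_id`, `condition`, and optionally
#'   `compartment` columns describing the count columns.
#' @param contrast Length-2 character vector `c(treatment, reference)` of
#'   condition labels (e.g. `c("Rev", "EV")`).
#' @param compartment If given, the test is restricted to samples of this
#'   compartment (e.g. `"cytoplasmic"` or `"total"`).
#' @param factors Size factors; computed from the selected samples with
#'   [size_factors] if omitted.
#' @param dispersion One of `"pooled"` (method-of-moments dispersion shared
#'   across loci; default) or `"per-locus"`.
#' @return A tibble of class `rcre_de` with columns `locus_id`,
#'   `base_mean_ref`, `base_mean_trt`, `log2_fc`, `se`, `wald_p`, `q`,
#'   `fold_change`, and attributes `contrast`, `compartment`, `n_per_group`,
#'   `dispersion_used`.
#' @export
nb_wald_test <- function(counts, sample_meta, contrast, compartment = NULL,
                         factors = NULL, dispersion = c("pooled", "per-locus")) {
  dispersion <- match.arg(dispersion)
  stopifnot(length(contrast) == 2)
  meta <- sample_meta
  if (!is.null(compartment)) {
    stopifnot("compartment" %in% names(meta))
    meta <- meta[meta$compartment == compartment, , drop = FALSE]
  }
  trt_ids <- meta$sample_id[meta$condition == contrast[1]]
  ref_ids <- meta$sample_id[meta$condition == contrast[2]]
  if (length(trt_ids) < 2 || length(ref_ids) < 2) {
    abort(sprintf("nb_wald_test: need >= 2 replicates per group, got %d vs %d",
                  length(trt_ids), length(ref_ids)))
  }
  m <- counts_to_matrix(counts)[, c(trt_ids, ref_ids), drop = FALSE]
  if (is.null(factors)) {
    factors <- size_factors(m)
  } else {
    factors <- factors[c(trt_ids, ref_ids)]
  }
  norm <- sweep(m, 2, factors, "/")
  trt <- norm[, trt_ids, drop = FALSE]
  ref <- norm[, ref_ids, drop = FALSE]
  keep <- rowSums(m) > 0
  trt <- trt[keep, , drop = FALSE]
  ref <- ref[keep, , drop = FALSE]

  mt <- rowMeans(trt); mr <- rowMeans(ref)
  vt <- apply(trt, 1, stats::var); vr <- apply(ref, 1, stats::var)
  nt <- ncol(trt); nr <- ncol(ref)
  # method-of-moments dispersion pooled over the two groups
  alpha_raw <- ((vt - mt) * pmax(mt, 1e-8)^-2 * (nt - 1) +
                (vr - mr) * pmax(mr, 1e-8)^-2 * (nr - 1)) / (nt + nr - 2)
  alpha_raw <- pmax(alpha_raw, 1e-8)
  # pooling by the mean is nearly unbiased for the common dispersion (the
  # per-locus MoM estimate is noisy and right-skewed; its median sits below
  # the truth and makes the Wald test anti-conservative)
  alpha <- if (dispersion == "pooled" && length(alpha_raw) > 1) {
    rep(mean(alpha_raw), length(alpha_raw))
  } else {
    alpha_raw
  }

  log2_fc <- log2((mt + 0.5) / (mr + 0.5))
  var_mt <- (mt + alpha * mt^2) / nt
  var_mr <- (mr + alpha * mr^2) / nr
  se <- sqrt(var_mt / (mt + 0.5)^2 + var_mr / (mr + 0.5)^2) / log(2)
  se <- pmax(se, 1e-12)
  wald_p <- 2 * stats::pnorm(-abs(log2_fc / se))
  out <- tibble::tibble(
    locus_id = rownames(norm)[keep],
    base_mean_ref = mr,
    base_mean_trt = mt,
    log2_fc = log2_fc,
    se = se,
    wald_p = wald_p,
    q = bh_adjust(wald_p),
    fold_change = 2^log2_fc
  )
  structure(out,
            class = c("rcre_de", class(out)),
            contrast = contrast,
            compartment = compartment %||% NA_character_,
            n_per_group = c(treatment = nt, reference = nr),
            dispersion_used = alpha[1])
}

#' @method tidy rcre_de
#' @export
tidy.rcre_de <- function(x, ...) {
  tibble::as_tibble(unclass_attrs(x))
}

#' @method glance rcre_de
#' @export
glance.rcre_de <- function(x, ...) {
  tibble::tibble(
    n_loci = nrow(x),
    contrast = paste(attr(x, "contrast"), collapse = " vs "),
    compartment = attr(x, "compartment"),
    dispersion = attr(x, "dispersion_used"),
    n_signif_q01 = sum(x$q < 0.01),
    max_fold_change = if (nrow(x)) max(x$fold_change) else NA_real_
  )
}

unclass_attrs <- function(x) {
  attr(x, "contrast") <- NULL
  attr(x, "compartment") <- NULL
  attr(x, "n_per_group") <- NULL
  attr(x, "dispersion_used") <- NULL
  class(x) <- setdiff(class(x), "rcre_de")
  x
}

#' Volcano-style plot for a per-locus test
#'
#' @param object An `rcre_de` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rcre_de
#' @export
autoplot.rcre_de <- function(object, ...) {
  d <- tibble::as_tibble(unclass_attrs(object))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2_fc, y = -log10(pmax(.data$wald_p, 1e-300)))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$q < 0.01), alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick"),
                                 name = "q < 0.01") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 Wald p",
                  title = paste(attr(object, "contrast"), collapse = " vs ")) +
    ggplot2::theme_minimal()
}

#' Side-by-side total vs cytoplasmic fold changes
#'
#' Joins per-locus results from the total and cytoplasmic compartments (each
#' a condition-vs-control contrast computed within its compartment) and
#' flags loci whose cytoplasmic fold change exceeds the total fold change —
#' the signature of enhanced nucleocytoplasmic export rather than increased
#' transcription.
#'
#' @param total,cytoplasmic `rcre_de` results for the same contrast in the
#'   two compartments.
#' @return Tibble with `locus_id`, `fc_total`, `p_total`, `fc_cytoplasmic`,
#'   `p_cytoplasmic`, `export_enriched` (logical).
#' @export
compartment_report <- function(total, cytoplasmic) {
  common <- intersect(total$locus_id, cytoplasmic$locus_id)
  if (length(common) < length(union(total$locus_id, cytoplasmic$locus_id))) {
    warn("compartment_report: locus sets differ between compartments; using intersection")
  }
  t <- total[match(common, total$locus_id), ]
  c <- cytoplasmic[match(common, cytoplasmic$locus_id), ]
  tibble::tibble(
    locus_id = common,
    fc_total = t$fold_change,
    p_total = t$wald_p,
    fc_cytoplasmic = c$fold_change,
    p_cytoplasmic = c$wald_p,
    export_enriched = c$fold_change > t$fold_change
  )
}

#' SEAP-normalized relative reporter activity
#'
#' Each reporter measurement is a p24 capsid readout normalized by a
#' co-transfected SEAP transfection-efficiency control; activities are then
#' expressed relative to a reference export-factor/element pair, whose
#' activity is 1 by construction.
#'
#' @param measurements Tibble with columns `pair` (label of the
#'   export-factor/element combination), `p24` (ng/ml, >= 0), `seap`
#'   (relative light units, > 0).
#' @param reference_pair Label of the reference pair (e.g. the prototype
#'   Rec/RcRE combination).
#' @return `measurements` with an added `activity` column (unitless,
#'   reference = 1).
#' @export
reporter_relative_activity <- function(measurements, reference_pair) {
  stopifnot(all(c("pair", "p24", "seap") %in% names(measurements)))
  if (any(measurements$seap <= 0)) abort("reporter_relative_activity: SEAP values must be > 0")
  if (any(measurements$p24 < 0)) abort("reporter_relative_activity: p24 values must be >= 0")
  ref <- measurements[measurements$pair == reference_pair, , drop = FALSE]
  if (nrow(ref) == 0) {
    abort(sprintf("reference pair '%s' not found", reference_pair))
  }
  ref_ratio <- mean(ref$p24 / ref$seap)
  if (ref_ratio <= 0) abort("reporter_relative_activity: reference p24/SEAP ratio is zero")
  dplyr::mutate(measurements, activity = (.data$p24 / .data$seap) / ref_ratio)
}
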