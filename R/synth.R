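#' Generate a random genome sequence
#'
#' Pure function of its arguments: the same `(length, gc, seed)` always
#' yields the same sequence, with no effect on the caller's random state.
#'
#' @param length Sequence length in nt (>= 1000).
#' @param gc Target GC fraction (default 0.41, human-like).
#' @param seed Integer seed.
#' @param name Contig name.
#' @return Genome tibble (`name`, `seq`) with a single row.
#' @export
make_genome <- function(length, gc = 0.41, seed = 42, name = "chr1") {
  if (length < 1000) abort("make_genome: length must be >= 1000")
  run_seeded(seed, {
    bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    tibble::tibble(name = name, seq = paste(bases, collapse = ""))
  })
}

#' Generate a random query element sequence
#'
#' @param length Element length in nt (default 433, RcRE-like).
#' @param gc GC fraction.
#' @param seed Integer seed.
#' @return A DNA string.
#' @export
make_query <- function(length = 433, gc = 0.5, seed = 42) {
  run_seeded(seed, {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  })
}

# Mutate a sequence to a target percent identity. Edits are sampled uniformly
# over positions without replacement; substitutions draw uniformly from the
# three alternative bases; an indel_fraction of the edits become 1-2 nt
# insertions or deletions.
mutate_to_identity <- function(seq, target_identity, indel_fraction = 0) {
  L <- nchar(seq)
  n_edits <- round((1 - target_identity / 100) * L)
  if (n_edits == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(L, n_edits)
  n_indel <- round(indel_fraction * n_edits)
  indel_pos <- if (n_indel > 0) pos[seq_len(n_indel)] else integer(0)
  sub_pos <- setdiff(pos, indel_pos)
  for (p in sub_pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  out <- chars
  if (n_indel > 0) {
    # process right-to-left so positions stay valid
    for (p in sort(indel_pos, decreasing = TRUE)) {
      w <- sample(1:2, 1)
      if (stats::runif(1) < 0.5) {
        out <- out[-(p:min(p + w - 1, length(out)))]
      } else {
        ins <- sample(c("A", "C", "G", "T"), w, replace = TRUE)
        out <- append(out, ins, after = p)
      }
    }
  }
  paste(out, collapse = "")
}

#' Implant a degenerate copy of a query element into a genome
#'
#' Mutates the query to a target percent identity and writes it into the
#' genome by replacement (the genome length is unchanged). On the minus
#' strand the reverse complement of the mutated copy is written, so a
#' scanner reading the plus strand sees it only after reverse
#' complementation. The realized identity is measured with [global_align]
#' and recorded in the truth table.
#'
#' @param genome Genome tibble (single contigs are implanted in place by
#'   `name` matching; default first contig).
#' @param query Query element DNA string.
#' @param target_identity Percent identity to aim for, in (50, 100].
#' @param strand `"+"` or `"-"`.
#' @param location 0-based start offset, or `"random"`.
#' @param indel_fraction Fraction of edits realized as 1-2 nt indels
#'   (default 0: substitutions only).
#' @param seed Integer seed.
#' @param avoid Tibble of intervals (`start`, `end`) the implant must not
#'   overlap (e.g. truth rows of earlier implants); an overlap is an error
#'   for explicit locations and re-sampled for random ones.
#' @param contig Name of the contig to implant into.
#' @return List with `genome` (modified) and `truth`, a one-row tibble:
#'   `chrom`, `start`, `end`, `strand`, `target_identity`,
#'   `realized_identity`, `seq` (the query-oriented mutated copy).
#' @export
implant_element <- function(genome, query, target_identity, strand = "+",
                            location = "random", indel_fraction = 0, seed = 42,
                            avoid = NULL, contig = genome$name[1]) {
  stopifnot(target_identity > 50, target_identity <= 100, strand %in% c("+", "-"))
  row <- which(genome$name == contig)
  stopifnot(length(row) == 1)
  g <- genome$seq[row]
  run_seeded(seed, {
    mutated <- mutate_to_identity(query, target_identity, indel_fraction)
    L <- nchar(mutated)
    n <- nchar(g)
    if (n < L) abort("implant_element: query does not fit in contig")
    pick <- function() sample.int(n - L + 1L, 1) - 1L
    overlaps_avoid <- function(s) {
      !is.null(avoid) && nrow(avoid) > 0 &&
        any(avoid$start < s + L & avoid$end > s)
    }
    if (identical(location, "random")) {
      start <- pick()
      tries <- 0
      while (overlaps_avoid(start)) {
        tries <- tries + 1
        if (tries > 1000) abort("implant_element: could not place implant without overlap")
        start <- pick()
      }
    } else {
      start <- as.integer(location)
      if (start < 0 || start + L > n) abort("implant_element: location out of range")
      if (overlaps_avoid(start)) abort("implant_element: implant overlaps a previous implant")
    }
    inserted <- if (strand == "+") mutated else revcomp(mutated)
    genome$seq[row] <- paste0(substring(g, 1, start), inserted,
                              substring(g, start + L + 1L, n))
    realized <- global_align(query, mutated)$identity_pct
    list(
      genome = genome,
      truth = tibble::tibble(
        chrom = contig, start = start, end = start + L, strand = strand,
        target_identity = target_identity, realized_identity = realized,
        seq = mutated
      )
    )
  })
}

#' Implant several degenerate copies at once
#'
#' Convenience wrapper around [implant_element] placing each implant at a
#' random non-overlapping position (a guard band of one query length is kept
#' between implants, emulating dispersed solo LTRs).
#'
#' @param genome Genome tibble.
#' @param query Query DNA string.
#' @param identities Numeric vector of target identities, one per implant.
#' @param strands Strand per implant (recycled).
#' @param indel_fraction Fraction of edits realized as indels (recycled).
#' @param seed Integer seed.
#' @return List with `genome` and `truth` (one row per implant).
#' @export
implant_elements <- function(genome, query, identities, strands = "+",
                             indel_fraction = 0, seed = 42) {
  strands <- rep_len(strands, length(identities))
  indel_fraction <- rep_len(indel_fraction, length(identities))
  guard <- nchar(query)
  truth <- list()
  avoid <- tibble::tibble(start = integer(), end = integer())
  for (i in seq_along(identities)) {
    res <- implant_element(genome, query, identities[i], strands[i],
                           location = "random", indel_fraction = indel_fraction[i],
                           seed = seed + i, avoid = avoid)
    genome <- res$genome
    truth[[i]] <- res$truth
    avoid <- dplyr::bind_rows(
      avoid,
      tibble::tibble(start = res$truth$start - guard, end = res$truth$end + guard)
    )
  }
  list(genome = genome, truth = dplyr::bind_rows(truth))
}

#' Simulate stranded paired-end alignments over repetitive loci
#'
#' Emits SAM-style alignment records for a set of proviral-like loci, each
#' with a unique segment and (optionally) a segment shared verbatim with the
#' other loci. Fragments drawn from a shared segment are tagged with the
#' multihit tag (an aligner would find an equally good secondary hit);
#' fragments from unique segments carry no tag. The dUTP ("reverse")
#' orientation is honored: for a plus-strand locus the first-in-pair read is
#' on the minus strand.
#'
#' @param loci Tibble with `locus_id`, `chrom`, `start`, `end`, `strand`,
#'   `n_unique`, `n_shared` (fragment counts per segment class), and
#'   optionally `shared_frac` (fraction of the locus length, at the 5' end,
#'   that is the shared segment; default 0.4).
#' @param read_len Read length (default 100).
#' @param frag_len Fragment length (default 300).
#' @param strandedness Library type: `"reverse"` (dUTP, default) or
#'   `"forward"`.
#' @param multihit_tag Tag written on shared-segment fragments (default
#'   `"ZS"`, value `i:0`).
#' @param seed Integer seed.
#' @return List with `alignments` (alignment tibble in [read_alignments]
#'   layout, with header attribute) and `truth` (tibble `locus_id`,
#'   `n_unique`, `n_shared`): pipeline counts after the unique filter should
#'   equal `n_unique`.
#' @export
simulate_alignments <- function(loci, read_len = 100, frag_len = 300,
                                strandedness = c("reverse", "forward"),
                                multihit_tag = "ZS", seed = 42) {
  strandedness <- match.arg(strandedness)
  stopifnot(all(c("locus_id", "chrom", "start", "end", "strand",
                  "n_unique", "n_shared") %in% names(loci)))
  if (any(loci$end - loci$start < frag_len)) {
    abort("simulate_alignments: fragment longer than a locus")
  }
  shared_frac <- loci[["shared_frac"]] %||% rep(0.4, nrow(loci))
  run_seeded(seed, {
    recs <- list()
    idx <- 0L
    for (i in seq_len(nrow(loci))) {
      l <- loci[i, ]
      span <- l$end - l$start
      shared_end <- l$start + floor(shared_frac[i] * span)
      draw <- function(n, lo, hi, tagged) {
        if (n == 0 || hi - lo < frag_len) {
          if (n > 0) abort("simulate_alignments: segment shorter than fragment")
          return(NULL)
        }
        fstart <- lo + sample.int(hi - lo - frag_len + 1L, n, replace = TRUE) - 1L
        purrr::map(seq_len(n), function(j) {
          idx <<- idx + 1L
          qname <- sprintf("frag_%s_%05d", l$locus_id, idx)
          fragment_records(qname, l$chrom, fstart[j], frag_len, read_len,
                           locus_strand = l$strand, strandedness = strandedness,
                           tag = if (tagged) multihit_tag else NULL)
        })
      }
      recs <- c(recs,
                draw(l$n_shared, l$start, shared_end, tagged = TRUE),
                draw(l$n_unique, shared_end, l$end, tagged = FALSE))
    }
    aln <- dplyr::bind_rows(recs)
    if (nrow(aln) > 0) aln <- aln[order(aln$chrom, aln$start), ]
    chroms <- unique(loci$chrom)
    attr(aln, "header") <- c(
      "@HD\tVN:1.6\tSO:coordinate",
      sprintf("@SQ\tSN:%s\tLN:%d", chroms,
              vapply(chroms, function(ch) max(loci$end[loci$chrom == ch]) + 1000L,
                     integer(1)))
    )
    list(
      alignments = aln,
      truth = tibble::tibble(locus_id = loci$locus_id,
                             n_unique = loci$n_unique, n_shared = loci$n_shared)
    )
  })
}

# Two mate records for one fragment. For a "reverse" (dUTP) library the
# first-in-pair read is antisense to the locus.
fragment_records <- function(qname, chrom, fstart, frag_len, read_len,
                             locus_strand, strandedness, tag = NULL) {
  r1_reverse <- if (strandedness == "reverse") locus_strand == "+" else locus_strand == "-"
  left_start <- fstart
  right_start <- fstart + frag_len - read_len
  # FLAGs: 0x1 paired, 0x2 proper, 0x10 reverse, 0x20 mate-reverse,
  # 0x40 first-in-pair, 0x80 second-in-pair
  if (r1_reverse) {
    f1 <- 0x1 + 0x2 + 0x10 + 0x40          # read1 reverse, rightmost
    f2 <- 0x1 + 0x2 + 0x20 + 0x80          # read2 forward, leftmost
    starts <- c(right_start, left_start)
    flags <- c(f1, f2)
    firsts <- c(TRUE, FALSE)
    revs <- c(TRUE, FALSE)
  } else {
    f1 <- 0x1 + 0x2 + 0x20 + 0x40          # read1 forward, leftmost
    f2 <- 0x1 + 0x2 + 0x10 + 0x80          # read2 reverse, rightmost
    starts <- c(left_start, right_start)
    flags <- c(f1, f2)
    firsts <- c(TRUE, FALSE)
    revs <- c(FALSE, TRUE)
  }
  tags <- if (is.null(tag)) {
    list(stats::setNames(character(0), character(0)),
         stats::setNames(character(0), character(0)))
  } else {
    list(stats::setNames(paste0("i:0"), tag), stats::setNames(paste0("i:0"), tag))
  }
  tibble::tibble(
    qname = qname, flag = as.integer(flags), chrom = chrom,
    start = as.integer(starts), end = as.integer(starts + read_len),
    mapq = 60L, cigar = paste0(read_len, "M"),
    paired = TRUE, proper_pair = TRUE, reverse_strand = revs,
    first_in_pair = firsts, secondary = FALSE, supplementary = FALSE,
    tags = tags
  )
}

#' Build gene/exon/LTR annotations around implanted elements
#'
#' For each truth row of [implant_elements], creates a gene spanning the
#' implant with a margin, two flanking exons (so the implant itself lies in
#' the intron), and an LTR catalog feature congruent with the implant —
#' enough structure to exercise hit annotation with known expected context.
#'
#' @param truth Implant truth tibble (`chrom`, `start`, `end`, `strand`).
#' @param gene_strands Strand of the gene created around each implant
#'   (recycled); sense/antisense expectation follows from the implant strand.
#' @param margin Distance from implant to gene boundary and exon width.
#' @return List with `genes` (gene + exon features) and `ltrs` (LTR
#'   features), both annotation tibbles.
#' @export
make_annotation <- function(truth, gene_strands = "+", margin = 500L) {
  gene_strands <- rep_len(gene_strands, nrow(truth))
  rows <- purrr::map(seq_len(nrow(truth)), function(i) {
    t <- truth[i, ]
    gid <- sprintf("GENE%03d", i)
    gene_start <- max(0L, t$start - margin)
    gene_end <- t$end + margin
    tibble::tibble(
      chrom = t$chrom,
      start = c(gene_start, gene_start, t$end + margin %/% 2),
      end = c(gene_end, t$start - margin %/% 2, gene_end),
      strand = gene_strands[i],
      kind = c("gene", "exon", "exon"),
      id = gid,
      source = "synthetic", score = ".", frame = ".",
      attributes = list(c(gene_id = gid, gene_name = paste0("SYN", i)),
                        c(gene_id = gid), c(gene_id = gid))
    )
  })
  genes <- dplyr::bind_rows(rows)
  ltrs <- tibble::tibble(
    chrom = truth$chrom, start = truth$start, end = truth$end,
    strand = truth$strand, kind = "LTR",
    id = sprintf("%d", seq_len(nrow(truth)) + 400L),
    source = "synthetic", score = ".", frame = ".",
    attributes = lapply(seq_len(nrow(truth)), function(i) character(0))
  )
  list(genes = genes, ltrs = ltrs)
}

#' Simulate a negative-binomial count matrix with known truth
#'
#' Draws `counts[i, j] ~ NB(mean = baseline_i * 2^log2fc(i, condition_j) *
#' factor_j, dispersion)` for a design crossing conditions with RNA
#' compartments, the structure of a total/cytoplasmic fractionation
#' experiment with transduced export factors.
#'
#' @param n_loci Number of loci.
#' @param conditions Character vector of condition labels; the first is the
#'   reference (e.g. `"EV"`).
#' @param compartments Character vector of compartment labels.
#' @param n_reps Replicates per (condition, compartment) cell.
#' @param baseline_mean Mean count of each locus in the reference condition
#'   (scalar or length `n_loci`).
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2);
#'   0 gives Poisson.
#' @param size_factors True per-sample depth factors (scalar or one per
#'   sample); defaults to 1.
#' @param log2fc Tibble with `locus_id` (or index), `condition`,
#'   `compartment`, `log2_fc` giving true effects relative to the reference
#'   condition; absent combinations default to 0.
#' @param seed Integer seed.
#' @return List with `counts` (tibble, `locus_id` + one column per sample),
#'   `sample_meta` (`sample_id`, `condition`, `compartment`), and `truth`
#'   (per-locus per-sample true means plus the simulation parameters).
#' @export
simulate_counts <- function(n_loci, conditions = c("EV", "Rev"),
                            compartments = "total", n_reps = 3,
                            baseline_mean = 500, dispersion = 0.05,
                            size_factors = 1, log2fc = NULL, seed = 42) {
  locus_ids <- sprintf("locus_%03d", seq_len(n_loci))
  design <- tidyr::expand_grid(condition = conditions, compartment = compartments,
                               rep = seq_len(n_reps))
  design$sample_id <- sprintf("%s_%s_r%d", design$condition, design$compartment,
                              design$rep)
  nsamp <- nrow(design)
  sf <- rep_len(size_factors, nsamp)
  baseline <- rep_len(baseline_mean, n_loci)
  lfc <- matrix(0, n_loci, nsamp, dimnames = list(locus_ids, design$sample_id))
  if (!is.null(log2fc)) {
    for (r in seq_len(nrow(log2fc))) {
      li <- log2fc$locus_id[r]
      li <- if (is.numeric(li)) li else match(li, locus_ids)
      cols <- design$condition == log2fc$condition[r] &
        design$compartment == log2fc$compartment[r]
      lfc[li, cols] <- log2fc$log2_fc[r]
    }
  }
  mu <- (baseline * 2^lfc) * rep(sf, each = n_loci)
  run_seeded(seed, {
    counts <- if (dispersion > 0) {
      matrix(stats::rnbinom(n_loci * nsamp, mu = mu, size = 1 / dispersion),
             n_loci, nsamp)
    } else {
      matrix(stats::rpois(n_loci * nsamp, lambda = mu), n_loci, nsamp)
    }
    dimnames(counts) <- dimnames(mu)
    list(
      counts = dplyr::bind_cols(tibble::tibble(locus_id = locus_ids),
                                tibble::as_tibble(counts)),
      sample_meta = tibble::tibble(sample_id = design$sample_id,
                                   condition = design$condition,
                                   compartment = design$compartment),
      truth = list(mu = mu, size_factors = stats::setNames(sf, design$sample_id),
                   dispersion = dispersion, log2fc = lfc,
                   baseline_mean = baseline)
    )
  })
}

#' Simulate a differential-expression p-value table with known truth
#'
#' Null genes draw p-values uniformly; true positives draw from
#' `Beta(beta_shape, 1)`, which concentrates near zero.
#'
#' @param n_genes Total genes.
#' @param n_de Number of true positives.
#' @param beta_shape Shape of the alternative p-value distribution; the
#'   default 0.005 gives the strong signal of a clearly differentially
#'   expressed gene (adjusted p-values around 1e-4 and below).
#' @param seed Integer seed.
#' @return Tibble `gene_id`, `p_value`, `is_de` (truth flag).
#' @export
simulate_de_table <- function(n_genes, n_de, beta_shape = 0.005, seed = 42) {
  stopifnot(n_de <= n_genes)
  run_seeded(seed, {
    p <- stats::runif(n_genes)
    de_idx <- sample.int(n_genes, n_de)
    p[de_idx] <- stats::rbeta(n_de, beta_shape, 1)
    tibble::tibble(
      gene_id = sprintf("ENSG%011d", seq_len(n_genes)),
      p_value = p,
      is_de = seq_len(n_genes) %in% de_idx
    )
  })
}
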