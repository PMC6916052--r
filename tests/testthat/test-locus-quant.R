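test_that("the unique-pair filter keeps clean proper pairs and drops tagged fragments", {
  lines <- c(
    sam_header(),
    sam_line("p1", 99, pos1 = 1001), sam_line("p1", 147, pos1 = 1201),
    sam_line("p2", 99, pos1 = 2001), sam_line("p2", 147, pos1 = 2201,
                                              tags = "ZS:i:40"),
    sam_line("u1", 0, pos1 = 3001)
  )
  aln <- read_alignments(write_sam_text(lines))
  kept <- filter_unique_pairs(aln)
  expect_equal(sort(unique(kept$qname)), "p1")
  expect_equal(nrow(kept), 2)  # both mates of p1 survive
  st <- filter_stats(kept)
  expect_equal(st$n_input, 5L)
  expect_equal(st$n_multihit, 2L)  # both mates of p2 removed together
  expect_equal(st$n_not_proper, 1L)
  expect_equal(st$n_kept, 2L)
})

test_that("secondary and supplementary records are excluded, orphans dropped", {
  lines <- c(
    sam_header(),
    sam_line("p1", 99, pos1 = 1001), sam_line("p1", 147, pos1 = 1201),
    sam_line("p1", 99 + 256, pos1 = 5001),   # secondary copy of p1 mate
    sam_line("p3", 99, pos1 = 4001)          # proper-pair flag, mate missing
  )
  aln <- read_alignments(write_sam_text(lines))
  kept <- filter_unique_pairs(aln)
  st <- filter_stats(kept)
  expect_equal(st$n_secondary, 1L)
  expect_equal(st$n_orphan, 1L)
  expect_equal(sort(unique(kept$qname)), "p1")
  expect_equal(st$n_input,
               st$n_not_proper + st$n_secondary + st$n_multihit +
                 st$n_orphan + st$n_kept)
})

test_that("filter equivalence with the literal command semantics on 10,000 records", {
  withr::with_seed(109, {
    n_pairs <- 5000
    qn <- sprintf("q%05d", seq_len(n_pairs))
    proper <- runif(n_pairs) < 0.8
    tagged1 <- runif(n_pairs) < 0.15
    tagged2 <- runif(n_pairs) < 0.15
    pos <- sample.int(90000, n_pairs)
    mk <- function(i, first) {
      flag <- 0x1 + (if (proper[i]) 0x2 else 0) + (if (first) 0x40 else 0x80)
      tg <- if (first && tagged1[i]) "ZS:i:30" else if (!first && tagged2[i]) "ZS:i:30" else character(0)
      sam_line(qn[i], flag, pos1 = pos[i] + (if (first) 0 else 200), tags = tg)
    }
    body <- unlist(lapply(seq_len(n_pairs), function(i) c(mk(i, TRUE), mk(i, FALSE))))
  })
  lines <- c(sam_header(), body)
  aln <- read_alignments(write_sam_text(lines))
  kept <- filter_unique_pairs(aln, filter_config("ZS"))

  oracle_lines <- oracle_filter_sam_text(lines, "ZS")
  oracle_qn_flag <- sort(paste(
    vapply(strsplit(oracle_lines, "\t"), `[[`, character(1), 1),
    vapply(strsplit(oracle_lines, "\t"), `[[`, character(1), 2)
  ))
  expect_equal(sort(paste(kept$qname, kept$flag)), oracle_qn_flag)
  expect_equal(nrow(kept), length(oracle_lines))
})

test_that("the multihit tag is configurable", {
  lines <- c(sam_header(),
             sam_line("p1", 99, pos1 = 1001, tags = "XS:i:20"),
             sam_line("p1", 147, pos1 = 1201))
  aln <- read_alignments(write_sam_text(lines))
  expect_equal(nrow(filter_unique_pairs(aln, filter_config("ZS"))), 2)
  expect_equal(nrow(filter_unique_pairs(aln, filter_config("XS"))), 0)
  expect_error(filter_config(""), "non-empty")
})

test_that("stranded fragment counting honors the dUTP orientation rule", {
  loci <- two_locus_annotation()
  # three fragments fully inside plus-strand locus provA; read1 on minus
  lines <- c(sam_header())
  for (i in 1:3) {
    p <- 2000 + 400 * i
    lines <- c(lines,
               sam_line(paste0("f", i), 163, pos1 = p),          # read2 fwd, left
               sam_line(paste0("f", i), 83, pos1 = p + 200))     # read1 rev, right
  }
  aln <- filter_unique_pairs(read_alignments(write_sam_text(lines)))
  cnt_rev <- count_fragments(aln, loci, "reverse")
  expect_equal(cnt_rev$count[cnt_rev$locus_id == "provA"], 3L)

  # the same fragments are wrong-orientation under "forward"
  cnt_fwd <- count_fragments(aln, loci, "forward")
  expect_equal(sum(cnt_fwd$count), 0L)
  expect_equal(assignment_stats(cnt_fwd)$n_wrong_strand, 3L)

  # and counted regardless under "unstranded"
  cnt_un <- count_fragments(aln, loci, "unstranded")
  expect_equal(cnt_un$count[cnt_un$locus_id == "provA"], 3L)
})

test_that("fragments spanning two loci are ambiguous and counted for neither", {
  loci <- dplyr::bind_rows(
    feature_row("chr1", 1000, 3000, "+", "locus", "L1"),
    feature_row("chr1", 2800, 5000, "+", "locus", "L2")
  )
  lines <- c(sam_header(),
             sam_line("amb", 163, pos1 = 2701),   # read2 fwd at 2700..2800
             sam_line("amb", 83, pos1 = 2801))    # read1 rev at 2800..2900
  aln <- filter_unique_pairs(read_alignments(write_sam_text(lines)))
  cnt <- count_fragments(aln, loci, "reverse")
  expect_equal(sum(cnt$count), 0L)
  expect_equal(assignment_stats(cnt)$n_ambiguous, 1L)
  expect_error(count_fragments(aln, loci[0, ]), "empty")
})

test_that("counts equal a brute-force per-fragment oracle on simulated data", {
  loci_spec <- tibble::tibble(
    locus_id = c("provA", "provB"), chrom = "chr1",
    start = c(1000L, 20000L), end = c(9000L, 28000L), strand = c("+", "-"),
    n_unique = c(120L, 75L), n_shared = c(40L, 25L)
  )
  sim <- simulate_alignments(loci_spec, seed = 113)
  kept <- filter_unique_pairs(sim$alignments)
  loci <- two_locus_annotation()
  cnt <- count_fragments(kept, loci, "reverse")
  expect_equal(cnt$count[match(loci_spec$locus_id, cnt$locus_id)],
               sim$truth$n_unique)

  # brute-force oracle: per-fragment interval and orientation check
  frags <- kept |>
    dplyr::summarise(chrom = chrom[1], start = min(start), end = max(end),
                     r1rev = any(reverse_strand[first_in_pair]), .by = qname)
  oracle <- sapply(seq_len(nrow(loci)), function(j) {
    l <- loci[j, ]
    sense <- ifelse(frags$r1rev, "+", "-")
    sum(frags$chrom == l$chrom & frags$start < l$end & frags$end > l$start &
          sense == l$strand)
  })
  # no fragment overlaps both loci here, so oracle counts are assignments
  expect_equal(cnt$count, as.integer(oracle))

  # conservation: assigned + ambiguous + wrong-strand + unassigned = fragments
  st <- assignment_stats(cnt)
  expect_equal(st$n_assigned + st$n_ambiguous + st$n_wrong_strand + st$n_unassigned,
               st$n_fragments)
  expect_equal(st$n_fragments, nrow(kept) / 2)
})

test_that("shared-segment fragments are removed before counting", {
  loci_spec <- tibble::tibble(
    locus_id = c("provA", "provB"), chrom = "chr1",
    start = c(1000L, 20000L), end = c(9000L, 28000L), strand = c("+", "+"),
    n_unique = c(0L, 100L), n_shared = c(50L, 0L)
  )
  sim <- simulate_alignments(loci_spec, seed = 127)
  kept <- filter_unique_pairs(sim$alignments)
  loci <- dplyr::bind_rows(
    feature_row("chr1", 1000, 9000, "+", "locus", "provA"),
    feature_row("chr1", 20000, 28000, "+", "locus", "provB")
  )
  cnt <- count_fragments(kept, loci, "reverse")
  expect_equal(cnt$count[cnt$locus_id == "provA"], 0L)
  expect_equal(cnt$count[cnt$locus_id == "provB"], 100L)
})

test_that("coverage bins apply the FPKM-style normalization formula", {
  # one fragment exactly covering one 50-nt bin
  lines <- c(sam_header(),
             sam_line("f1", 163, pos1 = 101, cigar = "25M"),
             sam_line("f1", 83, pos1 = 126, cigar = "25M"))
  aln <- filter_unique_pairs(read_alignments(write_sam_text(lines)))
  track <- coverage_track(aln, bin_width = 50, total_kept = 1e6,
                          chrom_sizes = c(chr1 = 200L))
  covered <- track[track$start == 100, ]
  expect_equal(covered$value, 1e9 / (50 * 1e6))  # 20.0
  expect_equal(sum(track$value > 0), 1)

  # zero fragments -> all-zero track
  empty <- filter_unique_pairs(read_alignments(write_sam_text(sam_header())))
  tz <- coverage_track(empty, bin_width = 50, total_kept = 10,
                       chrom_sizes = c(chr1 = 200L))
  expect_true(all(tz$value == 0))
  expect_error(coverage_track(empty, bin_width = 50), "total_kept")
})

test_that("coverage normalization is invariant to duplicating the library", {
  loci_spec <- tibble::tibble(locus_id = "L", chrom = "chr1", start = 1000L,
                              end = 6000L, strand = "+", n_unique = 80L,
                              n_shared = 0L)
  sim <- simulate_alignments(loci_spec, seed = 131)
  kept <- filter_unique_pairs(sim$alignments)
  t1 <- coverage_track(kept, bin_width = 50, chrom_sizes = c(chr1 = 7000L))
  doubled <- dplyr::bind_rows(kept, dplyr::mutate(kept, qname = paste0(qname, "_dup")))
  t2 <- coverage_track(doubled, bin_width = 50, chrom_sizes = c(chr1 = 7000L))
  expect_equal(t1$value, t2$value)

  path <- tempfile(fileext = ".bedgraph")
  write_bedgraph(t1, path)
  first <- readr::read_lines(path, n_max = 1)
  expect_match(first, "bedGraph")
})
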