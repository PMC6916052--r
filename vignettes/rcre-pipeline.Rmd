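---
title: "Finding and quantifying HERV-K Rec-responsive elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding and quantifying HERV-K Rec-responsive elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcrekit)
```

## The problem

The human genome carries ~90 HERV-K (HML-2) proviral loci and several hundred
solo LTRs. The U3 region of the HERV-K LTR contains the RcRE, a ~430-nt RNA
element which, bound by the retroviral export factor Rec or by HIV-1 Rev,
recruits the Crm-1 pathway and exports intron-containing transcripts from the
nucleus. Degenerate RcRE copies inside the introns of ordinary genes are
therefore potential cis-acting switches on host-gene export whenever Rev or
Rec is present.

Analysing this computationally involves four coupled sub-problems, each of
which this package implements and validates on synthetic data with known
ground truth:

* locating degenerate copies of a prototype element in genomic sequence;
* placing hits in genomic context (gene, orientation, intron/exon, LTR
  catalog) and collapsing identical sequences;
* quantifying the expression of near-identical, repetitive proviral loci
  from stranded paired-end alignments without cross-locus bleed-through;
* testing per-locus abundance shifts between conditions and between total
  and cytoplasmic RNA.

## Coordinates and formats

All intervals are 0-based half-open internally (the BED convention). GTF I/O
converts at the boundary (GTF is 1-based inclusive); display strings are
1-based inclusive with thousands separators (`chr3:101,700,268-101,700,695`).
A single internal convention avoids off-by-one drift between the scanner,
the annotator, and the counters; the coordinate round-trip is property-tested
through GTF and BED representations.

`merge_annotations` reproduces the merged-annotation construction used for
proviral-locus counting: features are concatenated, chromosomes are ordered
numerically after stripping a `chr` prefix (non-numeric names follow,
lexicographically), and features sort stably by start within a chromosome.

SAM text is the supported alignment dialect. FLAG bits 0x1, 0x2, 0x10, 0x40,
0x100 and 0x800 are decoded; optional tags are kept as opaque strings, and
only the presence of the configured secondary-score tag is ever interpreted.

## Element scanning

`scan_genome` is a seed-and-extend scanner: exact 12-mer seeds from the query
are matched on both strands, nearby seed projections are clustered into a
candidate window of query length ± 10 %, and the query is aligned globally
against each window (locally in the subject) under BLASTN-like scoring
(match +2, mismatch −3, gap open 5, gap extend 2; a length-L gap costs
5 + 2L). Percent identity is identical columns over total alignment columns
— gap columns count against identity, and `N` never matches anything,
including another `N`. Hits at or above the identity threshold (default 94)
are selected greedily by alignment score, ties broken by leftmost coordinate
then plus strand, so the result is deterministic.

Two design points deserve justification:

* **Seed length 12.** At the 94 % identity floor, roughly half of the
  ~420 query 12-mers survive unmutated in a true copy, so a real hit
  produces hundreds of seeds; a random 12-mer match occurs about once per
  17 Mb per seed, so background windows are rare and cheap to reject by
  alignment. Sensitivity at the threshold is therefore not seed-limited.
* **The oracle is ungapped.** `scan_genome_exhaustive` computes the ungapped
  percent identity of the query against the window at *every* offset on both
  strands and collapses qualifying runs to their best offset. For
  substitution-only divergence this is exact, and it shares no code with the
  seeded scanner — seeding, clustering, banding and greedy selection are all
  absent — so agreement is informative. Scanner behaviour on indel-containing
  copies is validated separately against implant-construction truth, where
  the true interval and realized identity are known by construction.

What synthetic testing does *not* show: performance or specificity on a
3-Gb genome, BLAST-style E-values, and sensitivity to the highly structured
repeat background of real DNA (a real LTR family is a forest of partially
overlapping, nested copies; the generator plants dispersed, non-overlapping
copies with at least one query length between them, which is the typical
spacing of solo LTRs but not the worst case).

## Annotation rules

A hit is assigned to a gene when at least half the hit length falls inside
the gene's full transcription-unit span; among several qualifying genes the
largest overlap wins and the ambiguity is reported. Orientation is sense when
hit and gene strands agree. Exonic/intronic status is resolved against the
union of the gene's annotated exons — transcript-level structure is
deliberately ignored, since intron placement of an element does not depend on
which isoform is considered. LTR-catalog membership demands 80 % reciprocal
overlap, enough to match partial LTRs while rejecting incidental containment
of a 400-nt element in a multi-kilobase annotation. `collapse_unique` groups
hits by exact sequence string; the distinct-gene-region count per group is
how "unique elements in annotated regions" is tallied when direct-repeat
LTRs carry letter-identical elements.

## Unique-mapping filtering and counting

Reads from near-identical proviral loci cannot be assigned by best-hit
alignment alone. The filter keeps a record only if it is a proper pair
(0x2), is not secondary (0x100) or supplementary (0x800), and carries no
secondary-score tag (default `ZS`, the HISAT2 convention; `XS` for
Bowtie2-style aligners). Filtering is fragment-consistent: if either mate is
tagged, both mates are removed, and a kept fragment always retains both
mates. The line-wise text filter this mirrors can orphan a mate; fragment
counting requires pairs, so pair consistency is enforced and the discrepancy
is confined to records the text filter would have half-kept.

`count_fragments` assigns a fragment (the union interval of its mates) to a
locus on ≥ 1 nt overlap, subject to the strandedness rule. The default is
`reverse` — in a dUTP library the first-in-pair read is antisense to the
transcript — so for a plus-strand locus the fragment qualifies when read 1
mapped to the minus strand. Fragments passing the strand rule for two or
more loci are discarded as ambiguous rather than fractionally assigned;
every fragment lands in exactly one of assigned / ambiguous / wrong-strand /
unassigned, and the partition is asserted in tests. Coverage tracks bin the
genome at 50 nt and report fragments × 10⁹ / (bin width × library size),
written as bedGraph.

## Normalization and the NB Wald test

Size factors are median-of-ratios: the per-locus reference is the geometric
mean across samples over loci with no zero count, and a sample's factor is
the median ratio to that reference. Factors are defined only up to a common
scale; the scaling-invariance property is therefore stated relatively (tests
compare factor ratios and normalized counts up to a global constant). On a
two-sample exact-doubling fixture the closed form is (1/√2, √2).

The per-locus test is a deliberately small NB Wald test, validated by
parameter recovery rather than by agreement with any larger DE framework:

* normalized group means `μ_t`, `μ_r`; effect
  `log2FC = log2((μ_t + 0.5)/(μ_r + 0.5))` (the 0.5 pseudo-count bounds the
  estimate when a group is empty);
* per-locus method-of-moments dispersion
  `α = (s² − μ)/μ²`, pooled within the two groups and floored at 1e-8;
* by default α is then shared across the loci of a contrast as the **mean**
  of the per-locus estimates. The mean, not the median, because the MoM
  estimator at n = 3 is noisy and right-skewed: its median sits below the
  true α, which understates standard errors and makes the null
  anti-conservative, while the mean is nearly unbiased and keeps the
  realized type-I error at its nominal level (asserted at 0.05 ± 0.02 over
  2,000 locus-replicates in the test suite). A `per-locus` mode is kept for
  heterogeneous-dispersion data at the cost of calibration at small n;
* `SE(log2FC)` by the delta method from `Var(μ̂_g) = (μ_g + α μ_g²)/n_g`,
  two-sided normal p-values, BH adjustment across the loci of the contrast.

At n = 3, mean 500 and α = 0.05 the sampling sd of the log2 fold estimate is
√(2(1/μ + α)/3)/ln 2 ≈ 0.27 — about ±20 % on the fold-change scale. A true
4.2-fold effect is therefore recovered without detectable bias and always at
extreme significance, but individual estimates scatter roughly between 3.2
and 5.5; single-seed fold changes should be read with that width in mind.
Contrasts are always condition-vs-control within one compartment, and
`compartment_report` flags loci whose cytoplasmic fold change exceeds the
total fold change — export enhancement rather than transcriptional induction.

Reporter measurements are normalized as `(p24/SEAP)` relative to the same
ratio for a designated reference export-factor/element pair, which is 1 by
construction; activities are invariant to rescaling all SEAP values by a
common constant.

## The synthetic-data generator

Every generator is a pure function of its parameters and an explicit seed
(no global RNG state leaks; the default demo seed is 42), and returns truth
records sufficient for downstream validation. The defaults encode the study
conditions the pipeline is meant for:

* 433-nt query elements; implant identities in the 94–98 % band; implant
  edits are substitutions by default (`indel_fraction = 0`, so realized
  identity equals the edit count exactly and the ungapped oracle applies),
  with 1–2-nt indels available to exercise the gapped path;
* dUTP-stranded proper pairs, 100-nt reads, 300-nt fragments; fragments from
  segments shared verbatim between loci carry the multihit tag, fragments
  from unique segments do not;
* NB counts with baseline mean 500, dispersion 0.05, and 3 replicates per
  condition/compartment cell — values typical of a moderately deep bulk
  experiment at a well-expressed locus — with true size factors and
  per-locus fold changes recorded;
* DE p-value tables with uniform nulls and Beta(0.005, 1) alternatives
  (adjusted p-values around 1e-4 and below, i.e. unambiguously
  differentially expressed genes).

Problem sizes used by the validation suite: 50–100-kb genomes with 3–6
implants (20 replicate genomes for the scanner/oracle comparison), 10,000
synthetic SAM records for filter equivalence, two-locus repetitive fixtures
for counting truth, 2,000 locus-replicates for null calibration, and 100
seeds for fold-change recovery.

What the generator does not emulate — and what passing tests therefore do
not show about real data: sequencing errors and quality strings, PCR
duplicates, alignment artefacts at repeat boundaries, partially homologous
(rather than verbatim-shared) locus segments, overdispersion heterogeneity
across loci, and identifier harmonization across external gene lists.

## Numerical and degenerate-input choices

Empty FASTA files, missing SAM headers, truncated records, negative or
reversed GTF coordinates and out-of-range p-values are errors with the
offending location named. An empty highlighter input yields an empty track
table, not an error. All-zero loci are omitted from test results. When no
locus is positive in every sample, `size_factors` stops and suggests a
pseudo-reference rather than silently switching estimators. Wald standard
errors are floored at 1e-12; dispersions at 1e-8. Greedy hit selection
breaks score ties by leftmost coordinate then plus strand, making scan
output deterministic for fixed input.

## Known limitations

* The scanner is desk-scale: exhaustively validated up to ~1 Mb genomes, not
  engineered for whole-genome throughput, and it reports raw identities, not
  E-values.
* The NB test has no dispersion shrinkage across mean ranges, no outlier
  handling, and no fold-change moderation; with 3 replicates its fold
  changes carry ±20 % sampling spread at dispersion 0.05.
* BAM, CRAM and bigwig are out of scope; SAM text and bedGraph are the
  supported dialects.
* Ambiguous fragments are discarded, never redistributed; loci shorter than
  a fragment cannot be simulated.
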