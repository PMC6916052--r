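test_that("size factors match the closed form on the doubling fixture", {
  cm <- tibble::tibble(locus_id = paste0("L", 1:5),
                       s1 = c(10L, 50L, 100L, 20L, 80L))
  cm$s2 <- cm$s1 * 2L
  sf <- size_factors(cm)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))

  # identical samples -> all 1
  cm$s2 <- cm$s1
  expect_equal(unname(size_factors(cm)), c(1, 1))

  # no all-positive locus -> informative error
  bad <- tibble::tibble(locus_id = c("a", "b"), s1 = c(0L, 5L), s2 = c(5L, 0L))
  expect_error(size_factors(bad), "pseudo-reference")
})

test_that("size factors recover simulated truth and match the DESeq2 estimator", {
  # 21 loci: an odd reference count keeps the arithmetic median identical to
  # DESeq2's log-space median, so the two estimators agree exactly
  sim <- simulate_counts(21, conditions = "EV", n_reps = 3,
                         baseline_mean = 400, dispersion = 0.02,
                         size_factors = c(0.5, 1, 2), seed = 137)
  sf <- size_factors(sim$counts)
  truth <- sim$truth$size_factors
  # recover up to a common scale (factors are relative)
  rel <- sf / exp(mean(log(sf)))
  rel_truth <- truth / exp(mean(log(truth)))
  expect_true(all(abs(rel / rel_truth - 1) < 0.1))

  m <- rcrekit:::counts_to_matrix(sim$counts)
  expect_equal(unname(sf), unname(DESeq2::estimateSizeFactorsForMatrix(m)))
})

test_that("scaling one sample's counts scales its relative factor and normalized counts", {
  # size factors are defined up to a common scale (the per-locus reference
  # moves when one sample is rescaled), so the invariance is relative:
  # the scaled sample's factor grows 3x against the others, and normalized
  # counts change only by a global constant
  sim <- simulate_counts(30, conditions = "EV", n_reps = 3,
                         baseline_mean = 300, dispersion = 0.05, seed = 139)
  cm <- sim$counts
  sf1 <- size_factors(cm)
  cm2 <- dplyr::mutate(cm, EV_total_r2 = EV_total_r2 * 3L)
  sf2 <- size_factors(cm2)
  expect_equal(sf2[["EV_total_r2"]] / sf2[["EV_total_r1"]],
               3 * sf1[["EV_total_r2"]] / sf1[["EV_total_r1"]])
  m1 <- sweep(rcrekit:::counts_to_matrix(cm), 2, sf1, "/")
  m2 <- sweep(rcrekit:::counts_to_matrix(cm2), 2, sf2, "/")
  ratio <- m2 / m1
  expect_equal(max(ratio) / min(ratio), 1, tolerance = 1e-10)
})

test_that("the NB Wald test is calibrated under the null", {
  sim <- simulate_counts(2000, conditions = c("EV", "Rev"), n_reps = 3,
                         baseline_mean = 500, dispersion = 0.05, seed = 149)
  res <- nb_wald_test(sim$counts, sim$sample_meta, c("Rev", "EV"),
                      compartment = "total")
  expect_equal(nrow(res), 2000)
  expect_lt(abs(mean(res$wald_p < 0.05) - 0.05), 0.02)
  # p-values approximately uniform on a 200-locus subset
  ks <- stats::ks.test(res$wald_p[1:200], "punif")
  expect_gt(ks$p.value, 0.01)
  expect_true(all(res$q >= res$wald_p))
})

test_that("a true 4.2-fold change is recovered without bias and with significance", {
  est <- vapply(1:30, function(s) {
    sim <- simulate_counts(20, conditions = c("EV", "Rev"), n_reps = 3,
                           baseline_mean = 500, dispersion = 0.05,
                           log2fc = tibble::tibble(locus_id = 1, condition = "Rev",
                                                   compartment = "total",
                                                   log2_fc = log2(4.2)),
                           seed = 1000 + s)
    res <- nb_wald_test(sim$counts, sim$sample_meta, c("Rev", "EV"),
                        compartment = "total")
    c(lfc = res$log2_fc[res$locus_id == "locus_001"],
      p = res$wald_p[res$locus_id == "locus_001"])
  }, c(lfc = 0, p = 0))
  # unbiased within 0.15 log2 units at n = 3
  expect_lt(abs(mean(est["lfc", ]) - log2(4.2)), 0.15)
  # the effect is always called significant
  expect_true(all(est["p", ] < 1e-4))
  # and the spread matches the NB sampling theory for these settings
  expect_lt(sd(est["lfc", ]), 0.4)
})

test_that("all-zero loci are omitted and replicate checks enforced", {
  sim <- simulate_counts(5, conditions = c("EV", "Rev"), n_reps = 3,
                         baseline_mean = 300, dispersion = 0.05, seed = 151)
  cm <- sim$counts
  cm[3, -1] <- as.list(rep(0L, ncol(cm) - 1))
  res <- nb_wald_test(cm, sim$sample_meta, c("Rev", "EV"), compartment = "total")
  expect_equal(nrow(res), 4)
  expect_false("locus_003" %in% res$locus_id)

  meta1 <- sim$sample_meta[c(1, 4), ]
  expect_error(nb_wald_test(cm, meta1, c("Rev", "EV"), compartment = "total"),
               "replicates")
})

test_that("tidy, glance and autoplot work on a test result", {
  sim <- simulate_counts(10, conditions = c("EV", "Rev"), n_reps = 3,
                         baseline_mean = 300, dispersion = 0.05, seed = 157)
  res <- nb_wald_test(sim$counts, sim$sample_meta, c("Rev", "EV"),
                      compartment = "total")
  td <- tidy(res)
  expect_false(inherits(td, "rcre_de"))
  expect_equal(nrow(td), 10)
  gl <- glance(res)
  expect_equal(gl$n_loci, 10L)
  expect_equal(gl$contrast, "Rev vs EV")
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("the compartment report flags export-enriched loci", {
  lfc <- tibble::tibble(
    locus_id = c(1, 1), condition = "Rev",
    compartment = c("cytoplasmic", "total"),
    log2_fc = c(2, 0)
  )
  sim <- simulate_counts(15, conditions = c("EV", "Rev"),
                         compartments = c("total", "cytoplasmic"), n_reps = 3,
                         baseline_mean = 500, dispersion = 0.03,
                         log2fc = lfc, seed = 163)
  tot <- nb_wald_test(sim$counts, sim$sample_meta, c("Rev", "EV"), "total")
  cyt <- nb_wald_test(sim$counts, sim$sample_meta, c("Rev", "EV"), "cytoplasmic")
  rep <- compartment_report(tot, cyt)
  expect_true(rep$export_enriched[rep$locus_id == "locus_001"])
  expect_gt(rep$fc_cytoplasmic[rep$locus_id == "locus_001"], 3)

  # identical inputs -> nothing flagged
  rep2 <- compartment_report(tot, tot)
  expect_false(any(rep2$export_enriched))

  expect_warning(compartment_report(tot[-1, ], cyt), "intersection")
})

test_that("a fractionation-control locus shows depleted cytoplasmic abundance", {
  # emulate a nucleus-retained transcript: near-zero cytoplasmic counts in
  # every condition
  lfc <- tidyr::expand_grid(locus_id = 2, condition = c("EV", "Rev"),
                            compartment = "cytoplasmic", log2_fc = -6)
  sim <- simulate_counts(10, conditions = c("EV", "Rev"),
                         compartments = c("total", "cytoplasmic"), n_reps = 3,
                         baseline_mean = 600, dispersion = 0.03,
                         log2fc = lfc, seed = 167)
  m <- rcrekit:::counts_to_matrix(sim$counts)
  cyt_cols <- sim$sample_meta$sample_id[sim$sample_meta$compartment == "cytoplasmic"]
  tot_cols <- sim$sample_meta$sample_id[sim$sample_meta$compartment == "total"]
  ratio <- mean(m["locus_002", cyt_cols]) / mean(m["locus_002", tot_cols])
  expect_lt(ratio, 0.05)
  # while the condition contrast within each compartment stays null
  cyt <- nb_wald_test(sim$counts, sim$sample_meta, c("Rev", "EV"), "cytoplasmic")
  expect_gt(cyt$wald_p[cyt$locus_id == "locus_002"], 0.001)
})

test_that("reporter activity is SEAP-normalized and reference-anchored", {
  meas <- tibble::tibble(
    pair = c("Rec/prRcRE", "Rev/CEBPZ", "Rec/CEBPZ"),
    p24 = c(6.4, 12.8, 6.4),
    seap = c(1000, 1000, 2000)
  )
  out <- reporter_relative_activity(meas, "Rec/prRcRE")
  expect_equal(out$activity, c(1, 2, 0.5))

  # rescaling all SEAP values by a common constant changes nothing
  out2 <- reporter_relative_activity(dplyr::mutate(meas, seap = seap * 7),
                                     "Rec/prRcRE")
  expect_equal(out2$activity, out$activity)

  expect_error(reporter_relative_activity(dplyr::mutate(meas, seap = c(0, 1, 1)),
                                          "Rec/prRcRE"), "SEAP")
  expect_error(reporter_relative_activity(meas, "Rev/prRcRE"), "not found")
})
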