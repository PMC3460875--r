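# Ct layout: a calibrator (0 h) and a treated condition (10 h), two tissues,
# n replicates; delta-Ct values are exact so fold changes have closed forms.
make_fc_data <- function(target_dct = 3, ref_dct = 1, n_rep = 3,
                         target_e = 2, ref_e = 2, extra_ref_dct = NULL,
                         extra_ref_e = 2) {
  genes <- c(t1 = NA, r1 = NA)
  rows <- tidyr::expand_grid(timepoint_h = c(0, 10), replicate = 1:n_rep)
  tgt <- rows |>
    dplyr::mutate(sample_id = sprintf("t%g_r%d", timepoint_h, replicate),
                  tissue = "root", treatment = "dehydration",
                  gene_id = "t1",
                  ct = 25 - ifelse(timepoint_h > 0, target_dct, 0))
  ref <- rows |>
    dplyr::mutate(sample_id = sprintf("t%g_r%d", timepoint_h, replicate),
                  tissue = "root", treatment = "dehydration",
                  gene_id = "r1",
                  ct = 20 - ifelse(timepoint_h > 0, ref_dct, 0))
  ref_genes <- tibble::tibble(gene_id = "r1", efficiency = ref_e)
  if (!is.null(extra_ref_dct)) {
    ref2 <- rows |>
      dplyr::mutate(sample_id = sprintf("t%g_r%d", timepoint_h, replicate),
                    tissue = "root", treatment = "dehydration",
                    gene_id = "r2",
                    ct = 21 - ifelse(timepoint_h > 0, extra_ref_dct, 0))
    ref <- dplyr::bind_rows(ref, ref2)
    ref_genes <- dplyr::bind_rows(
      ref_genes, tibble::tibble(gene_id = "r2", efficiency = extra_ref_e))
  }
  list(
    targets = ct_dataset(tgt, genes = tibble::tibble(gene_id = "t1",
                                                     efficiency = target_e)),
    refs = ct_dataset(ref, genes = ref_genes))
}

test_that("noiseless fold changes match their closed forms", {
  # E_t = E_ref = 2, dCt_t = 3, dCt_ref = 1 -> 2^3 / 2^1 = 4
  d <- make_fc_data(target_dct = 3, ref_dct = 1)
  fc <- fold_change(d$targets, d$refs, scheme = "r1")
  treated <- fc[fc$timepoint_h == 10, ]
  expect_equal(treated$fold_change, 4, tolerance = 1e-12)
  expect_equal(treated$se_log2, 0, tolerance = 1e-12)

  # efficiency-corrected: 1.9^3 / 2^1 = 3.4295 (1.9^3 = 6.859)
  d2 <- make_fc_data(target_dct = 3, ref_dct = 1, target_e = 1.9)
  fc2 <- fold_change(d2$targets, d2$refs, scheme = "r1")
  expect_equal(fc2$fold_change[fc2$timepoint_h == 10], 1.9^3 / 2,
               tolerance = 1e-12)
  expect_equal(fc2$fold_change[fc2$timepoint_h == 10], 3.4295,
               tolerance = 1e-4)
})

test_that("calibrator rows are exactly 1 and self-normalization is identity", {
  d <- make_fc_data()
  fc <- fold_change(d$targets, d$refs, scheme = "r1")
  expect_equal(fc$fold_change[fc$timepoint_h == 0], 1)

  # with replicate scatter the calibrator stays pinned at 1
  set.seed(21)
  jit <- d$targets$ct |> dplyr::mutate(ct = ct + stats::rnorm(dplyr::n(), 0, 0.3))
  fc_j <- fold_change(ct_dataset(jit, genes = d$targets$genes), d$refs, "r1")
  expect_equal(fc_j$fold_change[fc_j$timepoint_h == 0], 1)
  expect_gt(fc_j$se_log2[fc_j$timepoint_h == 10], 0)

  # a target normalized by itself is 1 everywhere
  self <- fold_change(d$refs, d$refs, scheme = "r1")
  self_r1 <- self[self$target == "r1", ]
  expect_equal(self_r1$fold_change, rep(1, nrow(self_r1)), tolerance = 1e-12)
})

test_that("stable reference at E = 2 reduces to the classic 2^-ddCt", {
  set.seed(31)
  rows <- tidyr::expand_grid(timepoint_h = c(0, 10), replicate = 1:3)
  tgt_ct <- 24 - ifelse(rows$timepoint_h > 0, 2.7, 0) +
    stats::rnorm(nrow(rows), 0, 0.2)
  tgt <- rows |>
    dplyr::mutate(sample_id = sprintf("s%g_%d", timepoint_h, replicate),
                  tissue = "root", treatment = "dehydration",
                  gene_id = "t1", ct = tgt_ct)
  ref <- rows |>
    dplyr::mutate(sample_id = sprintf("s%g_%d", timepoint_h, replicate),
                  tissue = "root", treatment = "dehydration",
                  gene_id = "r1", ct = 20)  # perfectly stable reference
  fc <- fold_change(ct_dataset(tgt), ct_dataset(ref), scheme = "r1")

  cal_mean <- mean(tgt_ct[rows$timepoint_h == 0])
  ddct <- (tgt_ct[rows$timepoint_h == 10] - cal_mean) - (20 - 20)
  expect_equal(fc$fold_change[fc$timepoint_h == 10],
               exp(mean(log(2^-ddct))), tolerance = 1e-12)
})

test_that("multi-reference normalization factorizes geometrically", {
  set.seed(41)
  d <- make_fc_data(target_dct = 2.2, ref_dct = 0.8, extra_ref_dct = 1.7,
                    ref_e = 1.87, extra_ref_e = 1.91, target_e = 1.88)
  # jitter all Cts so the factorization is tested away from the exact case
  d$targets$ct$ct <- d$targets$ct$ct + stats::rnorm(nrow(d$targets$ct), 0, 0.2)
  d$refs$ct$ct <- d$refs$ct$ct + stats::rnorm(nrow(d$refs$ct), 0, 0.2)

  fc_both <- fold_change(d$targets, d$refs, scheme = c("r1", "r2"))
  fc_1 <- fold_change(d$targets, d$refs, scheme = "r1")
  fc_2 <- fold_change(d$targets, d$refs, scheme = "r2")
  i <- fc_both$timepoint_h == 10
  expect_equal(fc_both$fold_change[i],
               sqrt(fc_1$fold_change[i] * fc_2$fold_change[i]),
               tolerance = 1e-9)

  expect_error(fold_change(d$targets, d$refs, scheme = "nope"), "absent")
})

test_that("detection disagreement flags mirror the published validation", {
  pub <- soybean_nac_fold_changes()
  flags <- reference_consistency(pub, detection_threshold = 2)

  # induced but hidden by the unstable reference: GmNAC19 in both tissues,
  # GmNAC43 and GmNAC92 in roots only; GmNAC85 never flagged
  expect_setequal(unique(flags$target[flags$tissue == "root"]),
                  c("GmNAC19", "GmNAC43", "GmNAC92"))
  expect_setequal(unique(flags$target[flags$tissue == "shoot"]), "GmNAC19")
  expect_false("GmNAC85" %in% flags$target)
  g19 <- flags[flags$target == "GmNAC19", ]
  expect_setequal(unique(g19$tissue), c("root", "shoot"))
  # every flagged cell has SUBI2 below and a stable scheme above threshold
  expect_true(all(grepl("SUBI2", flags$schemes_missing)))

  # agreement cases are not flagged
  agree <- tibble::tibble(
    target = "x", tissue = "root", treatment = "dehydration",
    timepoint_h = c(2, 2), scheme = c("a", "b"), fold_change = c(4, 4))
  expect_equal(nrow(reference_consistency(agree)), 0)
  # degenerate threshold: everything detected everywhere
  expect_equal(nrow(reference_consistency(pub, detection_threshold = 1e-9)), 0)

  one_scheme <- pub[pub$scheme == "60s", ]
  expect_error(reference_consistency(one_scheme), "at least 2")
})
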