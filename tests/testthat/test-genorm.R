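test_that("relative quantities anchor each gene at its minimum Ct", {
  ds <- make_ct_dataset(1, 3, function(g, s) c(20, 21, 23)[s])
  q <- relative_quantities(ds)
  expect_equal(unname(q[1, ]), c(1, 0.5, 0.125))

  # efficiency-corrected: E = 1.910 (published for the 60s amplicon)
  ds2 <- ct_dataset(make_long_ct(1, 2, function(g, s) c(20, 21)[s]),
                    genes = tibble::tibble(gene_id = "A", efficiency = 1.910))
  q2 <- relative_quantities(ds2)
  expect_equal(unname(q2[1, ]), c(1, 1 / 1.910), tolerance = 1e-12)

  # all Cts equal -> all quantities 1
  ds3 <- make_ct_dataset(2, 4, function(g, s) 22)
  expect_true(all(relative_quantities(ds3) == 1))

  # missing Ct is a hard error
  long <- make_long_ct(2, 3, function(g, s) 20)
  long$ct[1] <- NA
  expect_error(relative_quantities(ct_dataset(long)), "Missing Ct")
})

test_that("M is zero for proportional genes and matches the oracle otherwise", {
  # pairwise-proportional quantity vectors -> all M exactly 0
  ds <- make_ct_dataset(3, 4, function(g, s) 18 + g + s * 0.7)
  q <- relative_quantities(ds)
  expect_equal(unname(m_values(q)), c(0, 0, 0), tolerance = 1e-12)

  for (seed in 1:5) {
    ds <- random_ct_dataset(4, 6, seed = 100 + seed)
    q <- relative_quantities(ds)
    expect_equal(m_values(q), oracle_m(q), tolerance = 1e-12)
  }
})

test_that("M and V are invariant to per-sample and per-gene rescaling", {
  ds <- random_ct_dataset(5, 9, seed = 3)
  q <- relative_quantities(ds)
  m0 <- m_values(q)

  set.seed(4)
  sample_scale <- stats::runif(ncol(q), 0.2, 5)
  gene_scale <- stats::runif(nrow(q), 0.2, 5)
  q_scaled <- sweep(sweep(q, 2, sample_scale, `*`), 1, gene_scale, `*`)
  expect_equal(m_values(q_scaled), m0, tolerance = 1e-9)
})

test_that("with E = 2 the geNorm pair variation equals the delta-Ct pair SD", {
  for (seed in 1:10) {
    ds <- random_ct_dataset(6, 12, seed = 200 + seed)
    d <- deltact_stability(ds)
    q <- relative_quantities(ds)
    v <- refstab:::pairwise_v(q)
    expect_equal(v, d$pair_sd, tolerance = 1e-9)
    m <- m_values(q)
    expect_equal(unname(m[d$stability$gene_id]), d$stability$mean_sd,
                 tolerance = 1e-9)
  }
})

test_that("stepwise exclusion matches a definitional brute-force oracle", {
  for (seed in 1:10) {
    ds <- random_ct_dataset(5, 8, seed = 300 + seed)
    q <- relative_quantities(ds)
    gn <- genorm_ranking(q)
    or <- oracle_stepwise(q)
    expect_equal(gn$exclusion_order, or$exclusion)
    expect_equal(gn$final_pair, or$final_pair)
    excl_m <- gn$ranking$m[match(or$exclusion, gn$ranking$gene_id)]
    expect_equal(excl_m, unname(or$m_at_exclusion), tolerance = 1e-9)
    expect_equal(gn$ranking$m[1:2], unname(or$final_m[gn$final_pair]),
                 tolerance = 1e-9)
  }
})

test_that("an independently noisy gene is excluded first", {
  # genes A-C mutually proportional (Ct differs by constants); D noisy
  set.seed(9)
  noise <- stats::rnorm(8, 0, 1.5)
  long <- make_long_ct(4, 8, function(g, s) {
    if (g < 4) 19 + g + 0.3 * s else 22 + 0.3 * s + noise[s]
  })
  q <- relative_quantities(ct_dataset(long))
  gn <- genorm_ranking(q)
  expect_equal(gn$exclusion_order[1], "D")
  expect_true(all(gn$final_pair %in% c("A", "B", "C")))
  expect_error(genorm_ranking(q[1:2, ]), "at least 3 genes")
})

test_that("normalization factors and V(n/n+1) behave geometrically", {
  ds <- random_ct_dataset(5, 7, seed = 17)
  q <- relative_quantities(ds)
  gn <- genorm_ranking(q)

  expect_true(all(gn$v_ratios$v >= 0))
  expect_equal(gn$v_ratios$n, 2:4)

  # NF_n is the geometric mean over the top-n ranked genes, order-free
  top3 <- gn$ranking$gene_id[1:3]
  nf3 <- apply(q[top3, ], 2, function(x) exp(mean(log(x))))
  expect_equal(unname(gn$nf[, "3"]), unname(nf3), tolerance = 1e-12)
  nf3_perm <- apply(q[rev(top3), ], 2, function(x) exp(mean(log(x))))
  expect_equal(nf3, nf3_perm, tolerance = 1e-12)

  # V(2/3) from the definition
  v23 <- oracle_sd_pop(log2(gn$nf[, "2"] / gn$nf[, "3"]))
  expect_equal(gn$v_ratios$v[gn$v_ratios$n == 2], v23, tolerance = 1e-12)
})

test_that("tidiers and plots expose the ranking", {
  ds <- random_ct_dataset(4, 6, seed = 5)
  gn <- genorm_ranking(relative_quantities(ds))
  expect_equal(nrow(tidy(gn)), 4)
  expect_equal(glance(gn)$best_pair,
               paste(gn$final_pair, collapse = "/"))
  p <- autoplot(gn)
  expect_s3_class(p, "ggplot")
})
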