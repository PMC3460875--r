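# Small in-code fixtures shared across tests.

# long tibble for `n_genes` genes x `n_samples` samples; ct_fun(gene_idx,
# sample_idx) -> Ct
make_long_ct <- function(n_genes, n_samples, ct_fun,
                         gene_ids = LETTERS[seq_len(n_genes)]) {
  tidyr::expand_grid(s = seq_len(n_samples), g = seq_len(n_genes)) |>
    dplyr::mutate(
      sample_id = paste0("s", s),
      tissue = "root",
      treatment = "control",
      timepoint_h = 0,
      replicate = s,
      gene_id = gene_ids[g],
      ct = mapply(ct_fun, g, s)
    ) |>
    dplyr::select(-s, -g)
}

make_ct_dataset <- function(n_genes, n_samples, ct_fun, ...) {
  ct_dataset(make_long_ct(n_genes, n_samples, ct_fun), ...)
}

# random Ct matrix (genes x samples) as a ct_dataset, Cts ~ U[15, 30]
random_ct_dataset <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  m <- matrix(stats::runif(n_genes * n_samples, 15, 30), nrow = n_genes)
  make_ct_dataset(n_genes, n_samples, function(g, s) m[g, s])
}

# definitional oracles, independent of the package implementation ------------

oracle_sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

# mean of pairwise population SDs of delta-Ct, straight from the definition
oracle_deltact <- function(m) {
  g <- nrow(m)
  sapply(seq_len(g), function(i) {
    mean(sapply(setdiff(seq_len(g), i), function(j) {
      oracle_sd_pop(m[i, ] - m[j, ])
    }))
  })
}

# per-gene M from the definition: mean over partners of SD of log2 ratios
oracle_m <- function(q) {
  g <- nrow(q)
  out <- sapply(seq_len(g), function(i) {
    mean(sapply(setdiff(seq_len(g), i), function(j) {
      oracle_sd_pop(log2(q[i, ] / q[j, ]))
    }))
  })
  names(out) <- rownames(q)
  out
}

# full stepwise exclusion recomputed from scratch each round
oracle_stepwise <- function(q) {
  remaining <- rownames(q)
  exclusion <- character(0)
  m_at_exclusion <- numeric(0)
  while (length(remaining) > 2) {
    m <- oracle_m(q[remaining, , drop = FALSE])
    worst <- names(m)[m == max(m)]
    worst <- sort(worst)[length(worst)]
    exclusion <- c(exclusion, worst)
    m_at_exclusion <- c(m_at_exclusion, m[[worst]])
    remaining <- setdiff(remaining, worst)
  }
  list(exclusion = exclusion, m_at_exclusion = m_at_exclusion,
       final_pair = sort(remaining),
       final_m = oracle_m(q[remaining, , drop = FALSE]))
}
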