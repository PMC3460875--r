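#' Relative quantities from Ct values
#'
#' Converts Ct values to dimensionless relative quantities
#' \eqn{Q_{g,s} = E_g^{(minCt_g - Ct_{g,s})}}, anchoring each gene's highest
#' expression (minimum Ct within the subset) at 1. \eqn{E_g} is the gene's
#' fold-per-cycle amplification efficiency (2 = perfect doubling).
#'
#' @param ds A [ct_dataset()] with complete Ct values for the genes and
#'   samples present (drop incomplete samples first; missing Ct is an error).
#' @param efficiencies Optional named numeric vector of per-gene efficiencies
#'   overriding the dataset's gene table.
#' @param default_e Efficiency used for genes not covered by `efficiencies`
#'   or the gene table (default 2).
#' @return A genes x samples matrix of quantities with attribute
#'   `"efficiencies"`; every entry is in `(0, 1]` and each row's maximum is 1.
#' @export
relative_quantities <- function(ds, efficiencies = NULL, default_e = 2) {
  stopifnot(inherits(ds, "ct_dataset"))
  m <- ct_matrix(ds)
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Missing Ct for (%s, %s): drop incomplete samples before computing quantities.",
      rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  e <- setNames(ds$genes$efficiency, ds$genes$gene_id)
  if (!is.null(efficiencies)) {
    e[names(efficiencies)] <- efficiencies
  }
  e[is.na(e)] <- default_e
  check_efficiency(e)
  e <- e[rownames(m)]
  q <- e^(apply(m, 1, min) - m)
  attr(q, "efficiencies") <- e
  q
}

#' geNorm expression-stability measure M
#'
#' For each gene pair (g, k) the log2 expression ratios
#' \eqn{A_{gk,s} = \log_2(Q_{g,s}/Q_{k,s})} are formed across samples; their
#' population standard deviation \eqn{V_{gk}} measures how far the pair is
#' from the ideal of a constant ratio. A gene's stability M is the arithmetic
#' mean of its \eqn{V_{gk}} over all other candidates; lower M = more stable.
#'
#' @param q A genes x samples quantity matrix from [relative_quantities()]
#'   (at least 2 genes and 2 samples, all entries > 0).
#' @return Named numeric vector of per-gene M values (log2 cycles).
#' @export
m_values <- function(q) {
  v <- pairwise_v(q)
  rowSums(v) / (nrow(q) - 1)
}

pairwise_v <- function(q) {
  if (nrow(q) < 2 || ncol(q) < 2) {
    abort("Need at least 2 genes and 2 samples.")
  }
  if (any(!is.finite(q) | q <= 0)) {
    abort("Quantities must be finite and strictly positive.")
  }
  lq <- log2(q)
  g <- nrow(q)
  v <- matrix(0, g, g, dimnames = list(rownames(q), rownames(q)))
  for (i in seq_len(g - 1)) {
    for (j in seq(i + 1, g)) {
      v[i, j] <- v[j, i] <- sd_pop(lq[i, ] - lq[j, ])
    }
  }
  v
}

#' geNorm stepwise ranking with pairwise-variation ratios
#'
#' Repeatedly computes M on the remaining genes and excludes the gene with the
#' highest M (ties broken towards the lexicographically last gene_id) until two
#' genes remain; those two cannot be ranked further and are reported as an
#' unordered pair sharing one M value. Normalization factors
#' \eqn{NF_{n,s}} (geometric mean of the top-n genes' quantities in sample s)
#' and pairwise variations \eqn{V_{n/n+1}} (population SD over samples of
#' \eqn{\log_2(NF_n/NF_{n+1})}) are computed along the final ranking to judge
#' how many reference genes are needed.
#'
#' @param q A genes x samples quantity matrix from [relative_quantities()]
#'   with at least 3 genes.
#' @return An object of class `genorm_ranking` with
#'   * `rounds`: tibble `round`, `gene_id`, `m`, `excluded`;
#'   * `ranking`: tibble `gene_id`, `rank`, `m` (most stable first; ranks 1-2
#'     tie by construction);
#'   * `exclusion_order`: character, worst gene first;
#'   * `final_pair`: character of length 2 (unordered);
#'   * `v_ratios`: tibble `n`, `v` with \eqn{V_{n/n+1}} for n = 2..G-1;
#'   * `nf`: samples x (G-1) matrix of normalization factors, column `n`.
#' @examples
#' ds <- simulate_ct_dataset(sim_spec(n_genes = 6, seed = 7))$dataset
#' gn <- genorm_ranking(relative_quantities(ds))
#' gn$final_pair
#' @export
genorm_ranking <- function(q) {
  if (nrow(q) < 3) abort("Stepwise geNorm ranking needs at least 3 genes.")
  remaining <- rownames(q)
  rounds <- list()
  exclusion <- character(0)
  round_i <- 1L
  while (length(remaining) > 2) {
    m <- m_values(q[remaining, , drop = FALSE])
    worst <- names(m)[m == max(m)]
    worst <- sort(worst)[length(worst)]  # tie -> lexicographically last
    excl <- names(m) == worst
    rounds[[round_i]] <- tibble::tibble(
      round = round_i, gene_id = names(m), m = unname(m), excluded = excl)
    exclusion <- c(exclusion, worst)
    remaining <- setdiff(remaining, worst)
    round_i <- round_i + 1L
  }
  m_final <- m_values(q[remaining, , drop = FALSE])
  rounds[[round_i]] <- tibble::tibble(
    round = round_i, gene_id = names(m_final), m = unname(m_final),
    excluded = FALSE)
  rounds <- dplyr::bind_rows(rounds)

  final_pair <- sort(remaining)
  # most stable first: the tied final pair, then previously excluded genes in
  # reverse exclusion order
  ranked_genes <- c(final_pair, rev(exclusion))
  ranking <- tibble::tibble(
    gene_id = ranked_genes,
    rank = c(1L, 1L, seq(3L, length.out = length(exclusion))),
    m = c(unname(m_final[final_pair]),
          purrr::map_dbl(rev(exclusion), function(g) {
      r <- rounds[rounds$gene_id == g & rounds$excluded, ]
      r$m[nrow(r)]
    }))
  )

  nf_v <- genorm_nf_v(q, ranked_genes)

  structure(list(rounds = rounds, ranking = ranking,
                 exclusion_order = exclusion, final_pair = final_pair,
                 v_ratios = nf_v$v_ratios, nf = nf_v$nf),
            class = "genorm_ranking")
}

genorm_nf_v <- function(q, ranked_genes) {
  g <- length(ranked_genes)
  ns <- seq(2, g)
  nf <- sapply(ns, function(n) {
    apply(q[ranked_genes[seq_len(n)], , drop = FALSE], 2, geo_mean)
  })
  colnames(nf) <- as.character(ns)
  v <- purrr::map_dbl(seq_len(length(ns) - 1), function(i) {
    sd_pop(log2(nf[, i] / nf[, i + 1]))
  })
  list(nf = nf,
       v_ratios = tibble::tibble(n = head(ns, -1), v = v))
}

#' @export
print.genorm_ranking <- function(x, ...) {
  cat(sprintf("<genorm_ranking> %d genes, best pair: %s/%s (M = %.4f)\n",
              nrow(x$ranking), x$final_pair[1], x$final_pair[2],
              x$ranking$m[1]))
  if (nrow(x$v_ratios) > 0) {
    cat(sprintf("  V(2/3) = %.4f\n", x$v_ratios$v[1]))
  }
  invisible(x)
}

#' @rdname genorm_ranking
#' @param x A `genorm_ranking` object.
#' @param ... Unused.
#' @export
tidy.genorm_ranking <- function(x, ...) x$ranking

#' @rdname genorm_ranking
#' @export
glance.genorm_ranking <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$ranking),
    best_pair = paste(x$final_pair, collapse = "/"),
    best_m = x$ranking$m[1],
    v_2_3 = if (nrow(x$v_ratios) > 0) x$v_ratios$v[1] else NA_real_
  )
}

#' geNorm stability curve
#'
#' Average M of the remaining genes at each exclusion step, plotted most
#' stable (right) to least stable (left) in the style of the classic geNorm
#' charts.
#'
#' @param object A `genorm_ranking`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.genorm_ranking <- function(object, ...) {
  steps <- object$rounds |>
    dplyr::group_by(.data$round) |>
    dplyr::summarise(avg_m = mean(.data$m), .groups = "drop")
  labs <- c(rev(object$exclusion_order), paste(object$final_pair, collapse = "\n"))
  d <- tibble::tibble(
    step = seq_along(labs),
    label = factor(labs, levels = labs),
    avg_m = rev(steps$avg_m)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$avg_m, group = 1)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "<- least stable    (excluded gene at each step)    most stable ->",
                  y = "Average expression stability M",
                  title = "geNorm stepwise exclusion") +
    ggplot2::theme_minimal()
}
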