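#' Comparative delta-Ct stability ranking
#'
#' For every unordered pair of candidate reference genes (g, k), the per-sample
#' difference \eqn{\Delta Ct_s = Ct_{g,s} - Ct_{k,s}} is formed over the
#' samples in which both genes were measured; sample-to-sample variation of
#' \eqn{\Delta Ct} reflects instability of at least one of the two genes, while
#' template-amount (loading) differences cancel. Each pair is scored by the
#' population standard deviation (divisor N, spreadsheet STDEVP) of its
#' \eqn{\Delta Ct} values, and each gene by the mean of its pair SDs over all
#' other candidates. Lower mean SD = more stable; genes are ranked ascending.
#'
#' @param ds A [ct_dataset()], typically a condition subset from [subset_ct()].
#'   All samples present (control and treated, all timepoints, all replicates)
#'   enter as independent samples.
#' @param min_shared Minimum number of samples with non-missing Ct that every
#'   gene pair must share (default 3); fewer is a hard error naming the pair.
#' @return An object of class `deltact_stability` with elements
#'   * `pair_sd`: symmetric genes x genes matrix of pair SDs (cycles),
#'     zero diagonal;
#'   * `stability`: tibble `gene_id`, `mean_ct`, `sd_ct`, `mean_sd`, `rank`,
#'     `tied`, sorted ascending by `mean_sd`;
#'   * `n_shared`: matrix of per-pair sample counts.
#' @examples
#' ds <- simulate_ct_dataset(sim_spec(n_genes = 5, seed = 1))$dataset
#' deltact_stability(ds)
#' @export
deltact_stability <- function(ds, min_shared = 3) {
  stopifnot(inherits(ds, "ct_dataset"))
  m <- ct_matrix(ds)
  if (nrow(m) < 2) abort("Need at least 2 genes for delta-Ct analysis.")
  res <- pairwise_dct_sd(m, min_shared = min_shared)
  genes <- rownames(m)
  mean_sd <- rowSums(res$pair_sd) / (nrow(m) - 1)

  stability <- tibble::tibble(
    gene_id = genes,
    mean_ct = unname(rowMeans(m, na.rm = TRUE)),
    sd_ct = unname(apply(m, 1, sd_pop)),
    mean_sd = unname(mean_sd)
  ) |>
    dplyr::arrange(.data$mean_sd, .data$gene_id) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  tied = duplicated(.data$mean_sd) |
                    duplicated(.data$mean_sd, fromLast = TRUE))

  structure(list(pair_sd = res$pair_sd, stability = stability,
                 n_shared = res$n_shared),
            class = "deltact_stability")
}

pairwise_dct_sd <- function(m, min_shared = 3) {
  g <- nrow(m)
  pair_sd <- matrix(0, g, g, dimnames = list(rownames(m), rownames(m)))
  n_shared <- matrix(ncol(m), g, g, dimnames = dimnames(pair_sd))
  if (g >= 2) {
    for (i in seq_len(g - 1)) {
      for (j in seq(i + 1, g)) {
        d <- m[i, ] - m[j, ]
        ok <- !is.na(d)
        n_shared[i, j] <- n_shared[j, i] <- sum(ok)
        if (sum(ok) < min_shared) {
          abort(sprintf(
            "Gene pair (%s, %s) shares only %d samples with non-missing Ct (need >= %d).",
            rownames(m)[i], rownames(m)[j], sum(ok), min_shared))
        }
        pair_sd[i, j] <- pair_sd[j, i] <- sd_pop(d[ok])
      }
    }
  }
  list(pair_sd = pair_sd, n_shared = n_shared)
}

#' Wrap precomputed per-gene stability values as a delta-Ct result
#'
#' Published stability tables report only the per-gene mean of pair SDs.
#' This constructor turns such a column of per-gene statistics into a
#' `deltact_stability` object (without a pair-SD matrix) so that the
#' recommendation stage can run on printed values.
#'
#' @param stats A data frame with columns `gene_id` and `mean_sd` (cycles),
#'   or a named numeric vector of mean SDs.
#' @return A `deltact_stability` object with `pair_sd = NULL`.
#' @export
deltact_from_stats <- function(stats) {
  if (is.numeric(stats) && !is.null(names(stats))) {
    stats <- tibble::tibble(gene_id = names(stats), mean_sd = unname(stats))
  }
  stats <- tibble::as_tibble(stats)
  if (!all(c("gene_id", "mean_sd") %in% names(stats))) {
    abort("Need columns gene_id and mean_sd (or a named numeric vector).")
  }
  if (anyDuplicated(stats$gene_id)) abort("Duplicated gene_id.")
  stability <- stats |>
    dplyr::arrange(.data$mean_sd, .data$gene_id) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  tied = duplicated(.data$mean_sd) |
                    duplicated(.data$mean_sd, fromLast = TRUE))
  structure(list(pair_sd = NULL, stability = stability, n_shared = NULL),
            class = "deltact_stability")
}

#' @export
print.deltact_stability <- function(x, ...) {
  cat(sprintf("<deltact_stability> %d genes ranked by mean pair SD of delta-Ct\n",
              nrow(x$stability)))
  print(x$stability, n = 5)
  invisible(x)
}

#' @rdname deltact_stability
#' @param x A `deltact_stability` object.
#' @param ... Unused.
#' @export
tidy.deltact_stability <- function(x, ...) x$stability

#' @rdname deltact_stability
#' @export
glance.deltact_stability <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$stability),
    best_gene = x$stability$gene_id[1],
    best_mean_sd = x$stability$mean_sd[1],
    worst_gene = x$stability$gene_id[nrow(x$stability)],
    worst_mean_sd = x$stability$mean_sd[nrow(x$stability)]
  )
}

#' Bar chart of the delta-Ct stability ranking
#'
#' @param object A `deltact_stability` result.
#' @param ... Unused.
#' @return A ggplot: genes ordered most-stable first against their mean
#'   pair SD of delta-Ct (cycles).
#' @export
autoplot.deltact_stability <- function(object, ...) {
  d <- object$stability
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$gene_id, .data$mean_sd),
    y = .data$mean_sd)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL,
                  y = "Mean pair SD of ΔCt (cycles)",
                  title = "Delta-Ct stability ranking (lower = more stable)") +
    ggplot2::theme_minimal()
}
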