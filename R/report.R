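#' Recommend a reference-gene pair from a delta-Ct ranking
#'
#' The recommended pair is the top two genes of the delta-Ct ranking
#' (ascending mean pair SD). The geNorm trace, when supplied, is consulted
#' for concordance only: the note records whether both recommended genes sit
#' in the geNorm top 5.
#'
#' @param deltact A [deltact_stability()] result (possibly built from
#'   published per-gene statistics via [deltact_from_stats()]).
#' @param genorm Optional [genorm_ranking()] computed on the same condition
#'   subset.
#' @param condition,tissue Labels carried into the output (`"all"`/`"both"`
#'   for pooled analyses).
#' @return A one-row tibble of class `ref_recommendation`: `condition`,
#'   `tissue`, `gene1`, `gene2`, `stat1`, `stat2` (cycles, `stat1 <= stat2`),
#'   `method`, `genorm_top5_concordant`.
#' @export
recommend_pairs <- function(deltact, genorm = NULL,
                            condition = "all", tissue = "both") {
  stopifnot(inherits(deltact, "deltact_stability"))
  st <- deltact$stability
  if (nrow(st) < 2) abort("Need at least 2 genes to recommend a pair.")
  concord <- NA
  if (!is.null(genorm)) {
    stopifnot(inherits(genorm, "genorm_ranking"))
    top5 <- head(genorm$ranking$gene_id, 5)
    concord <- all(st$gene_id[1:2] %in% top5)
  }
  out <- tibble::tibble(
    condition = condition, tissue = tissue,
    gene1 = st$gene_id[1], gene2 = st$gene_id[2],
    stat1 = st$mean_sd[1], stat2 = st$mean_sd[2],
    method = "deltact", genorm_top5_concordant = concord
  )
  class(out) <- c("ref_recommendation", class(out))
  out
}

#' Condition-stratified stability report
#'
#' Runs the delta-Ct and geNorm engines on every requested condition cell of
#' a Ct dataset and collects the per-cell pair recommendations, plus a single
#' overall best gene (the delta-Ct winner of the pooled analysis).
#'
#' @param ds A [ct_dataset()].
#' @param conditions Data frame of cells to analyse with columns `condition`
#'   (a treatment label or `"all"`) and `tissue` (`"root"`, `"shoot"` or
#'   `"both"`). Default: every treatment present (plus `"all"`) crossed with
#'   each tissue present and `"both"`.
#' @param include_control Keep control samples inside each stress subset
#'   (default `TRUE`).
#' @param efficiencies Optional named per-gene efficiency vector for the
#'   geNorm quantities; default uses the dataset's gene table.
#' @return An object of class `stability_report`: list with
#'   `recommendations` (tibble, one row per cell), `deltact` and `genorm`
#'   (named lists of per-cell results), and `best_single_gene`.
#' @examples
#' sim <- simulate_ct_dataset(sim_spec(n_genes = 6, seed = 3))
#' rep <- run_all(sim$dataset,
#'                conditions = data.frame(condition = "all", tissue = "both"))
#' rep$recommendations
#' @export
run_all <- function(ds, conditions = NULL, include_control = TRUE,
                    efficiencies = NULL) {
  stopifnot(inherits(ds, "ct_dataset"))
  meta <- sample_meta(ds)
  if (is.null(conditions)) {
    trts <- setdiff(unique(meta$treatment), "control")
    if (length(trts) == 0) trts <- character(0)
    tissues <- unique(meta$tissue)
    conditions <- tidyr::expand_grid(
      condition = c(trts, "all"),
      tissue = c(tissues, if (length(tissues) > 1) "both"))
  }
  conditions <- tibble::as_tibble(conditions)

  cells <- purrr::pmap(conditions, function(condition, tissue, ...) {
    sub <- subset_ct(
      ds,
      tissue = if (tissue == "both") NULL else tissue,
      treatments = if (condition == "all") NULL else condition,
      include_control = include_control)
    dct <- deltact_stability(sub)
    gn <- if (nrow(sub$genes) >= 3 && !anyNA(ct_matrix(sub))) {
      genorm_ranking(relative_quantities(sub, efficiencies = efficiencies))
    } else {
      NULL
    }
    list(key = paste(condition, tissue, sep = "."),
         rec = recommend_pairs(dct, gn, condition = condition, tissue = tissue),
         deltact = dct, genorm = gn)
  })

  recs <- dplyr::bind_rows(purrr::map(cells, "rec"))
  pooled_key <- paste("all", if ("both" %in% conditions$tissue) "both"
                      else conditions$tissue[1], sep = ".")
  keys <- purrr::map_chr(cells, "key")
  pooled <- if (pooled_key %in% keys) {
    cells[[which(keys == pooled_key)[1]]]$deltact
  } else {
    cells[[1]]$deltact
  }

  structure(list(
    recommendations = recs,
    deltact = setNames(purrr::map(cells, "deltact"), keys),
    genorm = setNames(purrr::map(cells, "genorm"), keys),
    best_single_gene = pooled$stability$gene_id[1]
  ), class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %d condition cells; best single gene: %s\n",
              nrow(x$recommendations), x$best_single_gene))
  print(x$recommendations)
  invisible(x)
}

#' @rdname run_all
#' @param x A `stability_report`.
#' @param ... Unused.
#' @export
tidy.stability_report <- function(x, ...) x$recommendations

#' @rdname run_all
#' @export
glance.stability_report <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$recommendations),
    best_single_gene = x$best_single_gene,
    n_concordant = sum(x$recommendations$genorm_top5_concordant, na.rm = TRUE)
  )
}

#' Write the per-cell stability tables of a report to delimited text
#'
#' One file per condition cell (`<condition>.<tissue>.csv`, long layout
#' mirroring the published stability tables) plus `recommendations.csv`.
#'
#' @param report A `stability_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "stability_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(report$recommendations,
                   file.path(dir, "recommendations.csv"))
  purrr::iwalk(report$deltact, function(d, key) {
    readr::write_csv(d$stability, file.path(dir, paste0(key, ".deltact.csv")))
  })
  purrr::iwalk(report$genorm, function(g, key) {
    if (!is.null(g)) {
      readr::write_csv(g$rounds, file.path(dir, paste0(key, ".genorm.csv")))
    }
  })
  invisible(dir)
}
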