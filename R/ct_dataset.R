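#' Build a Ct dataset from a long table of cycle-threshold values
#'
#' A `ct_dataset` couples a long tibble of per-well Ct values (one row per
#' sample x gene) with a gene table carrying per-amplicon amplification
#' efficiencies. It is the common currency of the stability engines.
#'
#' @param ct A data frame with columns `sample_id`, `tissue`, `treatment`,
#'   `timepoint_h`, `replicate`, `gene_id`, `ct`. Missing Ct values are allowed
#'   (`NA`); non-missing values must lie in `[1, 45]` cycles.
#' @param genes Optional data frame with columns `gene_id`, `efficiency`
#'   (fold-per-cycle, in `(1, 2]`) and optionally `amplicon_length`. Genes
#'   present in `ct` but absent here are given efficiency `default_e`.
#' @param default_e Fold-per-cycle efficiency assumed for genes without an
#'   entry in `genes` (default 2, perfect doubling).
#' @return An object of class `ct_dataset`: a list with tibbles `ct` and
#'   `genes`.
#' @examples
#' ct <- tibble::tibble(
#'   sample_id = rep(c("s1", "s2"), each = 2),
#'   tissue = "root", treatment = "control", timepoint_h = 0,
#'   replicate = rep(1:2, each = 2),
#'   gene_id = rep(c("A", "B"), 2), ct = c(20, 22, 20.5, 22.5)
#' )
#' ds <- ct_dataset(ct)
#' ds
#' @export
ct_dataset <- function(ct, genes = NULL, default_e = 2) {
  required <- c("sample_id", "tissue", "treatment", "timepoint_h",
                "replicate", "gene_id", "ct")
  missing_cols <- setdiff(required, names(ct))
  if (length(missing_cols) > 0) {
    abort(paste0("`ct` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  ct <- tibble::as_tibble(ct)[required]
  ct$ct <- as.numeric(ct$ct)
  ct$timepoint_h <- as.numeric(ct$timepoint_h)
  ct$replicate <- as.integer(ct$replicate)

  bad_treat <- setdiff(unique(ct$treatment), TREATMENT_LEVELS)
  if (length(bad_treat) > 0) {
    abort(paste0("Unknown treatment label(s): ",
                 paste(bad_treat, collapse = ", "),
                 ". Allowed: ", paste(TREATMENT_LEVELS, collapse = ", ")))
  }
  bad_tissue <- setdiff(unique(ct$tissue), TISSUE_LEVELS)
  if (length(bad_tissue) > 0) {
    abort(paste0("Unknown tissue label(s): ",
                 paste(bad_tissue, collapse = ", "),
                 ". Allowed: ", paste(TISSUE_LEVELS, collapse = ", ")))
  }

  out_of_range <- !is.na(ct$ct) & (ct$ct < 1 | ct$ct > 45)
  if (any(out_of_range)) {
    i <- which(out_of_range)[1]
    abort(sprintf(
      "Ct value %.3f for (%s, %s) outside the valid range [1, 45] cycles.",
      ct$ct[i], ct$sample_id[i], ct$gene_id[i]))
  }

  dup <- ct |> dplyr::count(.data$sample_id, .data$gene_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("Duplicate Ct entries for (sample %s, gene %s).",
                  dup$sample_id[1], dup$gene_id[1]))
  }

  meta <- dplyr::distinct(ct, .data$sample_id, .data$tissue, .data$treatment,
                          .data$timepoint_h, .data$replicate)
  if (anyDuplicated(meta$sample_id)) {
    abort("A sample_id maps to more than one (tissue, treatment, timepoint, replicate).")
  }

  gene_ids <- unique(ct$gene_id)
  if (is.null(genes)) {
    genes <- tibble::tibble(gene_id = gene_ids, efficiency = default_e)
  } else {
    genes <- tibble::as_tibble(genes)
    if (!all(c("gene_id", "efficiency") %in% names(genes))) {
      abort("`genes` needs columns gene_id and efficiency.")
    }
    if (anyDuplicated(genes$gene_id)) abort("Duplicated gene_id in `genes`.")
    extra <- setdiff(gene_ids, genes$gene_id)
    if (length(extra) > 0) {
      genes <- dplyr::bind_rows(
        genes, tibble::tibble(gene_id = extra, efficiency = default_e))
    }
    genes <- genes[genes$gene_id %in% gene_ids, , drop = FALSE]
    # keep the order in which genes appear in the ct table
    genes <- genes[match(gene_ids, genes$gene_id), , drop = FALSE]
  }
  check_efficiency(genes$efficiency)

  structure(list(ct = ct, genes = genes), class = "ct_dataset")
}

check_efficiency <- function(e, upper = 2.2) {
  if (any(!is.finite(e) | e <= 1 | e > upper)) {
    abort(sprintf(
      "Amplification efficiencies must be fold-per-cycle values in (1, %.1f].",
      upper))
  }
  invisible(e)
}

#' @export
print.ct_dataset <- function(x, ...) {
  cat(sprintf("<ct_dataset> %d genes x %d samples (%d Ct values, %d missing)\n",
              nrow(x$genes), dplyr::n_distinct(x$ct$sample_id),
              nrow(x$ct), sum(is.na(x$ct$ct))))
  tis <- table(dplyr::distinct(x$ct, .data$sample_id, .data$tissue)$tissue)
  trt <- table(dplyr::distinct(x$ct, .data$sample_id, .data$treatment)$treatment)
  cat("  tissues:   ", paste(sprintf("%s (%d)", names(tis), tis), collapse = ", "), "\n")
  cat("  treatments:", paste(sprintf("%s (%d)", names(trt), trt), collapse = ", "), "\n")
  invisible(x)
}

#' Gene-by-sample Ct matrix of a dataset
#'
#' @param ds A [ct_dataset()].
#' @return A numeric matrix, genes in rows (in gene-table order), samples in
#'   columns (in order of first appearance).
#' @export
ct_matrix <- function(ds) {
  stopifnot(inherits(ds, "ct_dataset"))
  sample_ids <- unique(ds$ct$sample_id)
  m <- matrix(NA_real_, nrow = nrow(ds$genes), ncol = length(sample_ids),
              dimnames = list(ds$genes$gene_id, sample_ids))
  m[cbind(match(ds$ct$gene_id, rownames(m)),
          match(ds$ct$sample_id, colnames(m)))] <- ds$ct$ct
  m
}

#' Sample metadata of a dataset
#'
#' @param ds A [ct_dataset()].
#' @return A tibble with one row per sample: `sample_id`, `tissue`,
#'   `treatment`, `timepoint_h`, `replicate`.
#' @export
sample_meta <- function(ds) {
  stopifnot(inherits(ds, "ct_dataset"))
  dplyr::distinct(ds$ct, .data$sample_id, .data$tissue, .data$treatment,
                  .data$timepoint_h, .data$replicate)
}

#' Restrict a Ct dataset to a tissue and/or a set of treatments
#'
#' Conditions are analysed per tissue, per stress, or pooled. Control samples
#' (mock-treated, collected at the same durations) can be kept alongside the
#' selected stress treatments, which is the default.
#'
#' @param ds A [ct_dataset()].
#' @param tissue Optional tissue label (`"root"` or `"shoot"`); `NULL` keeps
#'   both tissues (combined roots & shoots analysis).
#' @param treatments Optional character vector of treatment labels; `NULL`
#'   keeps all.
#' @param include_control Keep `"control"` samples alongside the selected
#'   treatments (default `TRUE`).
#' @return A `ct_dataset` containing only the matching samples; the gene table
#'   is unchanged.
#' @export
subset_ct <- function(ds, tissue = NULL, treatments = NULL,
                      include_control = TRUE) {
  stopifnot(inherits(ds, "ct_dataset"))
  if (!is.null(tissue)) {
    bad <- setdiff(tissue, unique(ds$ct$tissue))
    if (length(bad) > 0) {
      abort(paste0("Tissue not present in dataset: ", paste(bad, collapse = ", ")))
    }
  }
  if (!is.null(treatments)) {
    bad <- setdiff(treatments, TREATMENT_LEVELS)
    if (length(bad) > 0) {
      abort(paste0("Unknown treatment label(s): ", paste(bad, collapse = ", "),
                   ". Allowed: ", paste(TREATMENT_LEVELS, collapse = ", ")))
    }
  }
  keep <- ds$ct
  if (!is.null(tissue)) keep <- dplyr::filter(keep, .data$tissue %in% .env$tissue)
  if (!is.null(treatments)) {
    wanted <- if (include_control) union(treatments, "control") else treatments
    keep <- dplyr::filter(keep, .data$treatment %in% wanted)
  }
  if (nrow(keep) == 0) {
    abort("Empty selection: no samples match the requested tissue/treatments.")
  }
  structure(list(ct = keep, genes = ds$genes), class = "ct_dataset")
}
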