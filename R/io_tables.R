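#' Read a Ct table from delimited text
#'
#' Reads comma- or tab-separated Ct tables (delimiter auto-detected from the
#' `.csv`/`.tsv` extension) in either of two layouts:
#'
#' * `"long"` (canonical): columns `sample_id, tissue, treatment, timepoint_h,
#'   replicate, gene_id, ct`, one row per well.
#' * `"wide"`: the metadata columns followed by one column per gene holding
#'   that gene's Ct.
#'
#' Missing wells are written as `NA`. Ct values must lie in `[1, 45]` cycles;
#' duplicate (sample, gene) pairs and unknown treatment labels are hard errors.
#'
#' @param path Path to a `.csv` or `.tsv` file (UTF-8, decimal point `.`).
#' @param layout `"long"` or `"wide"`.
#' @param genes Optional gene/efficiency table, see [ct_dataset()].
#' @param col_map Optional named character vector renaming file columns to the
#'   canonical names, e.g. `c(sample_id = "Sample", ct = "Cq")`.
#' @param default_e Efficiency for genes with no entry in `genes`.
#' @return A [ct_dataset()].
#' @export
read_ct_table <- function(path, layout = c("long", "wide"), genes = NULL,
                          col_map = NULL, default_e = 2) {
  layout <- match.arg(layout)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- read_delim_auto(path)
  if (!is.null(col_map)) {
    idx <- match(unname(col_map), names(raw))
    if (anyNA(idx)) {
      abort(paste0("col_map names columns absent from the file: ",
                   paste(col_map[is.na(idx)], collapse = ", ")))
    }
    names(raw)[idx] <- names(col_map)
  }
  meta_cols <- c("sample_id", "tissue", "treatment", "timepoint_h", "replicate")
  if (layout == "long") {
    long <- raw
  } else {
    missing_meta <- setdiff(meta_cols, names(raw))
    if (length(missing_meta) > 0) {
      abort(paste0("Wide table is missing metadata column(s): ",
                   paste(missing_meta, collapse = ", ")))
    }
    long <- tidyr::pivot_longer(raw, cols = -dplyr::all_of(meta_cols),
                                names_to = "gene_id", values_to = "ct")
  }
  ct_dataset(long, genes = genes, default_e = default_e)
}

#' Write a Ct dataset to delimited text (canonical long layout)
#'
#' @param ds A [ct_dataset()].
#' @param path Output `.csv` or `.tsv` path; the delimiter follows the
#'   extension.
#' @return `path`, invisibly. Round-trips bit-identically through
#'   [read_ct_table()].
#' @export
write_ct_table <- function(ds, path) {
  stopifnot(inherits(ds, "ct_dataset"))
  out <- ds$ct
  # full-precision decimal form so write -> read round-trips bitwise
  out$ct <- ifelse(is.na(out$ct), NA_character_, sprintf("%.17g", out$ct))
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::write_tsv(out, path)
  } else {
    readr::write_csv(out, path)
  }
  invisible(path)
}

#' Read a gene/efficiency table
#'
#' @param path Delimited text with columns `gene_id`, `efficiency` and
#'   optionally `amplicon_length`.
#' @param col_map Optional renaming map as in [read_ct_table()].
#' @return A tibble suitable for the `genes` argument of [ct_dataset()].
#' @export
read_gene_table <- function(path, col_map = NULL) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- read_delim_auto(path)
  if (!is.null(col_map)) {
    idx <- match(unname(col_map), names(raw))
    names(raw)[idx] <- names(col_map)
  }
  if (!all(c("gene_id", "efficiency") %in% names(raw))) {
    abort("Gene table needs columns gene_id and efficiency.")
  }
  check_efficiency(raw$efficiency)
  tibble::as_tibble(raw)
}

#' Import a supplementary raw-Ct spreadsheet with a user-supplied mapping
#'
#' Import path for supplementary per-sample Ct tables whose internal layout is
#' not standardised (sheet name, column headers, metadata encoding vary).
#' Spreadsheets (`.xls`/`.xlsx`) are read via the readxl package if installed;
#' `.csv`/`.tsv` are read directly. The caller supplies the mapping from file
#' columns to the canonical fields; nothing about the layout is hard-coded.
#'
#' @param path Spreadsheet or delimited-text file of per-sample Ct values.
#' @param col_map Named character vector mapping canonical names
#'   (`sample_id`, `tissue`, `treatment`, `timepoint_h`, `replicate`,
#'   `gene_id`, `ct`) to the file's column headers.
#' @param sheet Sheet name or index for spreadsheet input.
#' @param genes Optional gene/efficiency table.
#' @return A [ct_dataset()].
#' @export
read_supplementary_ct <- function(path, col_map, sheet = 1, genes = NULL) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      abort("Reading .xls/.xlsx needs the readxl package; export to .csv instead.")
    }
    raw <- readxl::read_excel(path, sheet = sheet)
  } else {
    raw <- read_delim_auto(path)
  }
  need <- c("sample_id", "tissue", "treatment", "timepoint_h", "replicate",
            "gene_id", "ct")
  if (!all(need %in% names(col_map))) {
    abort(paste0("col_map must map all of: ", paste(need, collapse = ", ")))
  }
  idx <- match(unname(col_map[need]), names(raw))
  if (anyNA(idx)) {
    abort(paste0("Mapped column(s) absent from the file: ",
                 paste(col_map[need][is.na(idx)], collapse = ", ")))
  }
  out <- raw[idx]
  names(out) <- need
  ct_dataset(out, genes = genes)
}

# Reads everything as character and lets the callers coerce: base R's
# strtod-backed as.numeric() is correctly rounded, so full-precision decimal
# Cts round-trip bitwise (vroom's fast float path is not exact to the ulp).
read_delim_auto <- function(path) {
  raw <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = "c"))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = "c"))
  }
  dplyr::mutate(raw, dplyr::across(
    dplyr::everything(),
    function(x) {
      y <- suppressWarnings(as.numeric(x))
      if (all(is.na(y) == is.na(x))) y else x
    }))
}
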