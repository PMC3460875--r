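#' Efficiency-corrected fold changes against a reference scheme
#'
#' Pfaffl-type relative quantification. For a target gene t and replicate r of
#' a condition, the efficiency-corrected ratio is
#' \deqn{ratio_r = \frac{E_t^{\,Ct_{t,cal} - Ct_{t,r}}}{NF_r}, \qquad
#'       NF_r = \left(\prod_{ref} E_{ref}^{\,Ct_{ref,cal} - Ct_{ref,r}}\right)^{1/|refs|}}
#' where \eqn{Ct_{\cdot,cal}} is the mean Ct over the calibrator replicates of
#' the same tissue. The condition's fold change is the geometric mean of the
#' replicate ratios and its `se_log2` is the sample SD of the per-replicate
#' log2 ratios divided by \eqn{\sqrt{n}}. Calibrator rows are exactly 1 (their
#' replicate ratios center on the calibrator mean by construction).
#'
#' @param targets A [ct_dataset()] holding the target genes.
#' @param refs A [ct_dataset()] holding the reference genes, with matching
#'   sample metadata (same tissue/treatment/timepoint/replicate cells).
#' @param scheme Character vector of one or more reference gene_ids.
#' @param calibrator Condition used as the 1x baseline, as a named list or
#'   one-row data frame of metadata values, e.g.
#'   `list(timepoint_h = 0)` (default: the 0 h samples of each tissue).
#' @param efficiencies Optional named vector of per-gene efficiencies
#'   overriding both datasets' gene tables.
#' @return A tibble of class `fold_change_tbl`: `target`, `tissue`,
#'   `treatment`, `timepoint_h`, `scheme`, `n_reps`, `fold_change`,
#'   `se_log2`, `calibrator`.
#' @export
fold_change <- function(targets, refs, scheme,
                        calibrator = list(timepoint_h = 0),
                        efficiencies = NULL) {
  stopifnot(inherits(targets, "ct_dataset"), inherits(refs, "ct_dataset"))
  missing_scheme <- setdiff(scheme, refs$genes$gene_id)
  if (length(missing_scheme) > 0) {
    abort(paste0("Reference gene(s) absent from `refs`: ",
                 paste(missing_scheme, collapse = ", ")))
  }
  eff <- c(setNames(targets$genes$efficiency, targets$genes$gene_id),
           setNames(refs$genes$efficiency, refs$genes$gene_id))
  if (!is.null(efficiencies)) eff[names(efficiencies)] <- efficiencies
  check_efficiency(eff)
  calib <- tibble::as_tibble(calibrator)

  all_ct <- dplyr::bind_rows(
    dplyr::mutate(targets$ct, .role = "target"),
    dplyr::mutate(dplyr::filter(refs$ct, .data$gene_id %in% scheme),
                  .role = "ref"))

  is_cal <- rep(TRUE, nrow(all_ct))
  for (col in names(calib)) {
    is_cal <- is_cal & all_ct[[col]] == calib[[col]][1]
  }
  if (!any(is_cal)) abort("Calibrator condition matches no samples.")

  # calibrator mean Ct per gene x tissue
  cal_means <- all_ct[is_cal, ] |>
    dplyr::group_by(.data$tissue, .data$gene_id) |>
    dplyr::summarise(ct_cal = mean(.data$ct), .groups = "drop")
  if (anyNA(cal_means$ct_cal)) abort("Missing calibrator Ct.")

  per_rep <- all_ct |>
    dplyr::left_join(cal_means, by = c("tissue", "gene_id")) |>
    dplyr::mutate(log2_q = log2(eff[.data$gene_id]) * (.data$ct_cal - .data$ct))
  if (anyNA(per_rep$ct_cal)) {
    abort("A gene lacks calibrator samples in some tissue.")
  }

  nf <- per_rep |>
    dplyr::filter(.data$.role == "ref") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(log2_nf = mean(.data$log2_q), n_refs = dplyr::n(),
                     .groups = "drop")
  if (any(nf$n_refs != length(scheme))) {
    abort("Some samples are missing Ct for part of the reference scheme.")
  }

  out <- per_rep |>
    dplyr::filter(.data$.role == "target") |>
    dplyr::inner_join(nf, by = "sample_id") |>
    dplyr::mutate(log2_ratio = .data$log2_q - .data$log2_nf) |>
    dplyr::group_by(target = .data$gene_id, .data$tissue, .data$treatment,
                    .data$timepoint_h) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      fold_change = 2^mean(.data$log2_ratio),
      se_log2 = ifelse(dplyr::n() > 1,
                       sd(.data$log2_ratio) / sqrt(dplyr::n()), 0),
      .groups = "drop")

  # identify calibrator rows and pin them to exactly 1
  cal_rows <- rep(TRUE, nrow(out))
  for (col in names(calib)) {
    if (col %in% names(out)) cal_rows <- cal_rows & out[[col]] == calib[[col]][1]
  }
  out$fold_change[cal_rows] <- 1

  out <- out |>
    dplyr::mutate(scheme = paste(sort(scheme), collapse = "+"),
                  calibrator = paste(names(calib), unlist(calib),
                                     sep = "=", collapse = ","),
                  .after = "timepoint_h")
  class(out) <- c("fold_change_tbl", class(out))
  out
}

#' Flag conditions where reference schemes disagree on detection
#'
#' A differentially expressed call at a fold threshold (default 2.0) should
#' not depend on the normalizer. A (target, tissue, condition) cell is flagged
#' when at least one scheme's fold change reaches the threshold while
#' another's does not — the signature of an unstable reference gene hiding a
#' real induction.
#'
#' @param tables A `fold_change_tbl` (or plain data frame with its columns)
#'   holding results for two or more schemes, e.g. `dplyr::bind_rows()` of
#'   several [fold_change()] calls; or a list of such tables.
#' @param detection_threshold Fold-change call threshold (default 2).
#' @return Tibble of flagged cells, sorted by target then tissue: `target`,
#'   `tissue`, `treatment`, `timepoint_h`, `n_schemes`, `min_fc`, `max_fc`,
#'   `schemes_detecting`, `schemes_missing`.
#' @export
reference_consistency <- function(tables, detection_threshold = 2) {
  if (is.list(tables) && !is.data.frame(tables)) {
    tables <- dplyr::bind_rows(tables)
  }
  tables <- tibble::as_tibble(tables)
  need <- c("target", "tissue", "treatment", "timepoint_h", "scheme",
            "fold_change")
  if (!all(need %in% names(tables))) {
    abort(paste0("Fold-change table needs columns: ",
                 paste(need, collapse = ", ")))
  }
  if (dplyr::n_distinct(tables$scheme) < 2) {
    abort("Need fold changes under at least 2 reference schemes.")
  }
  counts <- tables |>
    dplyr::count(.data$target, .data$tissue, .data$treatment,
                 .data$timepoint_h)
  n_schemes <- dplyr::n_distinct(tables$scheme)
  if (!any(counts$n == n_schemes)) {
    abort("Schemes do not overlap on any (target, tissue, condition) cell.")
  }

  tables |>
    dplyr::group_by(.data$target, .data$tissue, .data$treatment,
                    .data$timepoint_h) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(
      n_schemes = dplyr::n(),
      min_fc = min(.data$fold_change),
      max_fc = max(.data$fold_change),
      schemes_detecting = paste(
        .data$scheme[.data$fold_change >= detection_threshold], collapse = ","),
      schemes_missing = paste(
        .data$scheme[.data$fold_change < detection_threshold], collapse = ","),
      .groups = "drop") |>
    dplyr::filter(.data$min_fc < detection_threshold,
                  .data$max_fc >= detection_threshold) |>
    dplyr::arrange(.data$target, .data$tissue, .data$timepoint_h)
}

#' Fold-change bar chart per reference scheme
#'
#' @param object A `fold_change_tbl` (possibly several schemes bound together).
#' @param ... Unused.
#' @return A ggplot, faceted by target x tissue, log2 y-axis.
#' @export
autoplot.fold_change_tbl <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::mutate(condition = sprintf("%s %gh", .data$treatment,
                                      .data$timepoint_h))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$condition, y = .data$fold_change,
                                  fill = .data$scheme)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 2, linetype = 2, colour = "grey40") +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::facet_grid(target ~ tissue) +
    ggplot2::labs(x = NULL, y = "Fold change (log2 scale)",
                  fill = "Reference scheme") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
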