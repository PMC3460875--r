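#' Published candidate-gene panel with amplification efficiencies
#'
#' The 13-gene soybean candidate reference panel with per-amplicon
#' fold-per-cycle amplification efficiencies estimated from raw fluorescence
#' by window-of-linearity regression, as published for this assay.
#'
#' @return Tibble `gene_id`, `function_desc`, `amplicon_length`, `efficiency`.
#' @export
soybean_gene_panel <- function() {
  tibble::tribble(
    ~gene_id, ~function_desc,                          ~amplicon_length, ~efficiency,
    "60s",    "60s ribosomal protein L30",             125L, 1.910,
    "ABC",    "ATP-binding cassette transporter",      106L, 1.866,
    "Act11",  "Actin",                                 142L, 1.873,
    "Act27",  "Actin",                                 119L, 1.858,
    "CDPK",   "CDPK-related protein kinase",            97L, 1.885,
    "CYP2",   "Cyclophilin",                           154L, 1.855,
    "ELF1a",  "Eukaryotic elongation factor 1 alpha",  195L, 1.824,
    "ELF1b",  "Eukaryotic elongation factor 1 beta",   118L, 1.870,
    "Fbox",   "F-box protein family",                   93L, 1.883,
    "IDE",    "Insulin-degrading enzyme",              131L, 1.884,
    "SUBI2",  "Ubiquitin",                              84L, 1.862,
    "TUBa",   "Tubulin",                               159L, 1.861,
    "TUBb",   "Tubulin",                               161L, 1.844
  )
}

#' Published per-gene delta-Ct stability statistics
#'
#' The per-gene "average of STDEVP of delta-Ct" statistics published for the
#' 13-gene soybean panel, by condition. The all-stress columns also carry the
#' published mean Ct and Ct STDEVP. These printed values are inputs for the
#' recommendation stage (the raw per-sample Ct values behind them were only
#' released as a spreadsheet supplement).
#'
#' @param condition One of `"all"`, `"dehydration"`, `"salt"`, `"cold"`,
#'   `"ABA"`.
#' @param tissue One of `"root"`, `"shoot"`, `"both"`.
#' @return Tibble `gene_id`, `mean_sd` (cycles) plus, for `condition = "all"`,
#'   `mean_ct` and `sd_ct`.
#' @export
soybean_stability_published <- function(condition = c("all", "dehydration",
                                                      "salt", "cold", "ABA"),
                                        tissue = c("root", "shoot", "both")) {
  condition <- match.arg(condition)
  tissue <- match.arg(tissue)
  g <- c("60s", "ABC", "Act27", "Act11", "CDPK", "CYP2", "ELF1a", "ELF1b",
         "Fbox", "IDE", "SUBI2", "TUBa", "TUBb")
  tabs <- list(
    all = list(
      root = c(0.4274, 0.4580, 0.5325, 0.5772, 0.7810, 0.5148, 0.5210,
               0.4204, 0.4908, 0.5284, 0.9455, 0.8019, 0.5258),
      shoot = c(0.5112, 0.5851, 0.6736, 0.5761, 0.8356, 0.5897, 0.5905,
                0.5462, 0.5115, 0.5518, 1.1124, 1.1125, 0.7495),
      both = c(0.4492, 0.5238, 0.5837, 0.5682, 0.8015, 0.5987, 0.5541,
               0.5233, 0.4843, 0.5333, 1.0802, 0.9594, 0.6293)),
    dehydration = list(
      root = c(0.2902, 0.2145, 0.2179, 0.2159, 0.2437, 0.2807, 0.2362,
               0.2378, 0.2026, 0.2439, 0.5441, 0.2268, 0.2176),
      shoot = c(0.4857, 0.6269, 0.6418, 0.5537, 0.9915, 0.6573, 0.6186,
                0.5209, 0.4538, 0.5967, 1.2082, 1.0299, 0.8387),
      both = c(0.5346, 0.6452, 0.7222, 0.6363, 0.7685, 0.8326, 0.8439,
               0.6804, 0.4943, 0.5913, 1.1174, 0.8549, 0.7954)),
    salt = list(
      root = c(0.3015, 0.2896, 0.3128, 0.3823, 0.6666, 0.3622, 0.3238,
               0.2656, 0.3489, 0.2743, 0.5667, 0.2998, 0.3212),
      shoot = c(0.3537, 0.4840, 0.7563, 0.4164, 0.7199, 0.3792, 0.4713,
                0.3277, 0.3268, 0.4947, 0.6558, 0.5392, 0.7498),
      both = c(0.3579, 0.4180, 0.5739, 0.4384, 0.6857, 0.5192, 0.4462,
               0.4703, 0.3707, 0.4441, 0.6179, 0.4750, 0.5985)),
    cold = list(
      root = c(0.2196, 0.2441, 0.2424, 0.2726, 0.5454, 0.2449, 0.2968,
               0.2448, 0.2404, 0.2180, 0.2898, 0.2779, 0.2936),
      shoot = c(0.2579, 0.2647, 0.2564, 0.3457, 0.5116, 0.3092, 0.3152,
                0.2706, 0.2382, 0.2991, 0.3859, 0.3671, 0.3724),
      both = c(0.2778, 0.3557, 0.4209, 0.3707, 0.5909, 0.3632, 0.4136,
               0.3563, 0.3120, 0.3497, 0.8414, 0.3670, 0.3851)),
    ABA = list(
      root = c(0.3653, 0.4050, 0.5245, 0.4838, 0.5288, 0.4226, 0.4192,
               0.3987, 0.4435, 0.4787, 0.9597, 0.5854, 0.5330),
      shoot = c(0.3420, 0.3278, 0.5056, 0.3282, 0.3292, 0.3485, 0.3944,
                0.2959, 0.3221, 0.3714, 0.4756, 0.3893, 0.3625),
      both = c(0.3996, 0.4318, 0.5560, 0.4563, 0.4780, 0.4756, 0.4537,
               0.4073, 0.4320, 0.5126, 1.1887, 0.6987, 0.5416))
  )
  out <- tibble::tibble(gene_id = g, mean_sd = tabs[[condition]][[tissue]])
  if (condition == "all" && tissue != "both") {
    mean_ct <- list(
      root = c(21.31, 23.64, 21.64, 19.11, 25.79, 17.63, 18.41, 20.67,
               21.09, 21.66, 25.30, 20.12, 20.60),
      shoot = c(21.97, 24.38, 22.03, 19.70, 26.35, 17.68, 18.87, 21.86,
                21.55, 22.41, 26.65, 20.34, 21.16))
    sd_ct <- list(
      root = c(0.5507, 0.5522, 0.5793, 0.7787, 0.8712, 0.5748, 0.5853,
               0.5545, 0.5217, 0.7632, 1.1050, 0.6796, 0.6805),
      shoot = c(0.8184, 0.6079, 1.0963, 0.7892, 0.8752, 0.5359, 0.7598,
                0.7702, 0.6606, 0.6132, 0.8995, 1.0552, 1.0289))
    out$mean_ct <- mean_ct[[tissue]]
    out$sd_ct <- sd_ct[[tissue]]
  }
  out
}

#' Published fold changes of dehydration-inducible NAC genes
#'
#' Fold changes (and log-scale standard errors) of four dehydration-inducible
#' GmNAC transcription-factor genes in root and shoot tissue at 2 h and 10 h
#' of dehydration, each normalized three ways: against an unstable reference
#' (SUBI2) and against the two most stable references (60s, Fbox). Calibrator
#' is the 0 h sample of the same tissue. Used to validate that reference
#' choice changes detection calls at a 2-fold threshold.
#'
#' @return A `fold_change_tbl`-shaped tibble: `target`, `tissue`, `treatment`,
#'   `timepoint_h`, `scheme`, `fold_change`, `se`.
#' @export
soybean_nac_fold_changes <- function() {
  rows <- tibble::tribble(
    ~target,    ~tissue, ~timepoint_h, ~SUBI2, ~`60s`, ~Fbox, ~se_SUBI2, ~se_60s, ~se_Fbox,
    "GmNAC19",  "root",   0,  1.00,   1.00,   1.00, 0.14, 0.27, 0.22,
    "GmNAC19",  "root",   2,  1.26,   2.49,   2.58, 0.10, 0.27, 0.27,
    "GmNAC19",  "root",  10,  1.78,   2.32,   3.22, 0.18, 0.05, 0.14,
    "GmNAC19",  "shoot",  0,  1.00,   1.00,   1.00, 0.11, 0.04, 0.04,
    "GmNAC19",  "shoot",  2,  0.96,   3.13,   3.75, 0.15, 0.09, 0.06,
    "GmNAC19",  "shoot", 10,  1.12,  18.66,  13.93, 0.09, 0.05, 0.04,
    "GmNAC43",  "root",   0,  1.00,   1.00,   1.00, 0.24, 0.23, 0.19,
    "GmNAC43",  "root",   2,  1.50,   3.06,   3.18, 0.22, 0.23, 0.23,
    "GmNAC43",  "root",  10,  1.68,   3.06,   4.24, 0.11, 0.04, 0.14,
    "GmNAC43",  "shoot",  0,  1.00,   1.00,   1.00, 0.04, 0.05, 0.05,
    "GmNAC43",  "shoot",  2, 17.26,  25.42,  30.51, 0.16, 0.12, 0.08,
    "GmNAC43",  "shoot", 10, 25.69, 101.32,  75.61, 0.04, 0.09, 0.08,
    "GmNAC85",  "root",   0,  1.00,   1.00,   1.00, 0.24, 0.23, 0.18,
    "GmNAC85",  "root",   2,  3.06,   6.23,   6.46, 0.16, 0.18, 0.16,
    "GmNAC85",  "root",  10,  4.96,   9.02,  12.50, 0.24, 0.15, 0.24,
    "GmNAC85",  "shoot",  0,  1.00,   1.00,   1.00, 0.05, 0.02, 0.02,
    "GmNAC85",  "shoot",  2, 58.75,  86.51, 103.83, 0.16, 0.13, 0.07,
    "GmNAC85",  "shoot", 10, 139.24, 549.09, 409.76, 0.02, 0.08, 0.06,
    "GmNAC92",  "root",   0,  1.00,   1.00,   1.00, 0.29, 0.27, 0.22,
    "GmNAC92",  "root",   2,  1.22,   2.49,   2.58, 0.27, 0.27, 0.27,
    "GmNAC92",  "root",  10,  1.28,   2.32,   3.22, 0.12, 0.05, 0.14,
    "GmNAC92",  "shoot",  0,  1.00,   1.00,   1.00, 0.02, 0.04, 0.04,
    "GmNAC92",  "shoot",  2,  2.12,   3.13,   3.75, 0.13, 0.09, 0.06,
    "GmNAC92",  "shoot", 10,  4.73,  18.66,  13.93, 0.02, 0.05, 0.04
  )
  fc <- rows |>
    tidyr::pivot_longer(cols = c("SUBI2", "60s", "Fbox"),
                        names_to = "scheme", values_to = "fold_change")
  se <- rows |>
    tidyr::pivot_longer(cols = dplyr::starts_with("se_"),
                        names_to = "scheme", values_to = "se") |>
    dplyr::mutate(scheme = sub("^se_", "", .data$scheme))
  fc |>
    dplyr::select("target", "tissue", "timepoint_h", "scheme", "fold_change") |>
    dplyr::left_join(se |>
                       dplyr::select("target", "tissue", "timepoint_h",
                                     "scheme", "se"),
                     by = c("target", "tissue", "timepoint_h", "scheme")) |>
    dplyr::mutate(treatment = "dehydration", .after = "tissue")
}

#' Published recommended reference-gene pairs
#'
#' The recommended pair per condition cell (most stable gene first), as
#' published: each cell is the top two genes of the delta-Ct ranking for that
#' condition.
#'
#' @return Tibble `condition`, `tissue`, `gene1`, `gene2`.
#' @export
soybean_recommended_pairs <- function() {
  tibble::tribble(
    ~condition,    ~tissue, ~gene1,  ~gene2,
    "dehydration", "root",  "Fbox",  "ABC",
    "dehydration", "shoot", "Fbox",  "60s",
    "dehydration", "both",  "Fbox",  "60s",
    "salt",        "root",  "ELF1b", "IDE",
    "salt",        "shoot", "Fbox",  "ELF1b",
    "salt",        "both",  "60s",   "Fbox",
    "cold",        "root",  "IDE",   "60s",
    "cold",        "shoot", "Fbox",  "Act27",
    "cold",        "both",  "60s",   "Fbox",
    "ABA",         "root",  "60s",   "ELF1b",
    "ABA",         "shoot", "ELF1b", "Fbox",
    "ABA",         "both",  "60s",   "ELF1b",
    "all",         "root",  "ELF1b", "60s",
    "all",         "shoot", "60s",   "Fbox",
    "all",         "both",  "60s",   "Fbox"
  )
}
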