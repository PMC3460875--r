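#' Amplification curve container
#'
#' @param cycle Integer cycles, strictly increasing.
#' @param signal Raw fluorescence (arbitrary units, >= 0), same length.
#' @param well_id,amplicon_id Identifiers carried through the pipeline.
#' @return An object of class `amp_curve`. Fields `baseline`, `window`,
#'   `efficiency`, `r_squared`, `ct` and `corrected` are filled in by
#'   [correct_baseline()], [fit_efficiency()] and [amplicon_group()].
#' @export
amp_curve <- function(cycle, signal, well_id = "w1", amplicon_id = "a1") {
  cycle <- as.integer(cycle)
  if (length(cycle) != length(signal)) abort("cycle and signal lengths differ.")
  if (any(diff(cycle) <= 0)) abort("Cycles must be strictly increasing.")
  if (any(signal < 0)) abort("Fluorescence must be non-negative.")
  structure(list(well_id = well_id, amplicon_id = amplicon_id,
                 cycle = cycle, signal = as.numeric(signal),
                 baseline = NA_real_, corrected = NULL,
                 window = NULL, efficiency = NA_real_, r_squared = NA_real_,
                 flagged = FALSE, ct = NA_real_),
            class = "amp_curve")
}

#' @export
print.amp_curve <- function(x, ...) {
  cat(sprintf("<amp_curve> well %s (amplicon %s), %d cycles\n",
              x$well_id, x$amplicon_id, length(x$cycle)))
  if (!is.na(x$baseline)) cat(sprintf("  baseline   %.5g\n", x$baseline))
  if (!is.na(x$efficiency)) {
    cat(sprintf("  efficiency %.4f (R^2 %.5f, window %d-%d%s)\n",
                x$efficiency, x$r_squared, x$window[1], x$window[2],
                if (x$flagged) ", flagged low-quality" else ""))
  }
  if (!is.na(x$ct)) cat(sprintf("  Ct         %.3f\n", x$ct))
  invisible(x)
}

#' Read raw amplification curves from delimited text
#'
#' @param path `.csv`/`.tsv` file with columns `well_id`, `amplicon_id`,
#'   `cycle`, `fluorescence` (long format, one row per cycle per well).
#' @return A list of [amp_curve()] objects, one per well.
#' @export
read_amp_curves <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- read_delim_auto(path)
  need <- c("well_id", "amplicon_id", "cycle", "fluorescence")
  if (!all(need %in% names(raw))) {
    abort(paste0("Curve file needs columns: ", paste(need, collapse = ", ")))
  }
  raw |>
    dplyr::arrange(.data$well_id, .data$cycle) |>
    dplyr::group_by(.data$well_id, .data$amplicon_id) |>
    dplyr::group_map(function(d, key) {
      amp_curve(d$cycle, d$fluorescence,
                well_id = key$well_id, amplicon_id = key$amplicon_id)
    })
}

# Sliding log-linear fit over `len` consecutive observed cycles with strictly
# positive, non-constant signal. Returns the best window (max R^2, ties ->
# earliest), or with `first = TRUE` the earliest qualifying window regardless
# of R^2 (used to score baseline candidates: an additive background distorts
# log-linearity most in the low-signal early cycles, while late windows are
# insensitive to it).
find_window <- function(cycle, signal, len, first = FALSE) {
  n <- length(signal)
  best <- list(r2 = -Inf, start = NA_integer_, slope = NA_real_)
  if (n < len) return(best)
  for (s in seq_len(n - len + 1)) {
    idx <- seq(s, s + len - 1)
    y <- signal[idx]
    if (any(y <= 0)) next
    x <- cycle[idx]
    ly <- log10(y)
    mx <- mean(x); my <- mean(ly)
    sxx <- sum((x - mx)^2)
    sxy <- sum((x - mx) * (ly - my))
    syy <- sum((ly - my)^2)
    if (syy <= 0) next  # flat in log space: no exponential growth here
    r2 <- (sxy^2) / (sxx * syy)
    if (r2 > best$r2 + 1e-12) {
      best <- list(r2 = r2, start = s, slope = sxy / sxx)
    }
    if (first && is.finite(best$r2)) return(best)
  }
  best
}

#' Baseline-correct an amplification curve
#'
#' Subtracts a constant baseline fluorescence, chosen by maximising the
#' quality (R^2) of the log-linear fit in the earliest qualifying window of
#' the corrected signal: the low-signal early cycles are where an additive
#' background bends the log-linear plot, so they identify the constant (late,
#' high-signal windows are insensitive to it). Candidate constants are
#' searched on a grid over `[0, min(signal))` (the smallest raw signal bounds
#' any additive background from above) and the best grid cell is refined by
#' golden-section optimisation, so a noiseless exponential-plus-constant
#' recovers its baseline to high precision.
#'
#' @param curve An [amp_curve()] with at least 15 cycles.
#' @param window_len Window length used to assess log-linearity (default 5).
#' @param grid_n Number of grid candidates (default 201).
#' @return The curve with `baseline` set and `corrected` filled with
#'   `signal - baseline`.
#' @export
correct_baseline <- function(curve, window_len = 5, grid_n = 201) {
  stopifnot(inherits(curve, "amp_curve"))
  if (length(curve$cycle) < 15) abort("Need at least 15 cycles of data.")
  upper <- min(curve$signal)
  objective <- function(b) {
    w <- find_window(curve$cycle, curve$signal - b, window_len, first = TRUE)
    if (!is.finite(w$r2)) -Inf else w$r2
  }
  grid <- seq(0, upper * (1 - 1e-9), length.out = grid_n)
  scores <- vapply(grid, objective, numeric(1))
  if (all(!is.finite(scores))) {
    abort("Flat/failed reaction: no baseline leaves a positive exponential window.")
  }
  i <- which.max(scores)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(grid_n, i + 1)]
  b <- if (hi > lo) {
    opt <- optimize(objective, interval = c(lo, hi), maximum = TRUE,
                    tol = .Machine$double.eps^0.5)
    if (opt$objective >= scores[i]) opt$maximum else grid[i]
  } else {
    grid[i]
  }
  curve$baseline <- b
  curve$corrected <- curve$signal - b
  curve
}

#' Window-of-linearity efficiency estimation
#'
#' Slides a window of `window_len` consecutive cycles over the
#' baseline-corrected signal, regresses log10(signal) on cycle within each
#' window, and keeps the window with the highest R^2 (ties broken towards the
#' earliest window). The amplification efficiency is `10^slope`, the
#' fold-per-cycle amplification within the exponential phase (2 = perfect
#' doubling). Fits with R^2 below `r2_min` are retained but flagged
#' low-quality and excluded from amplicon-group averaging.
#'
#' @param curve A baseline-corrected [amp_curve()].
#' @param window_len Cycles per window, 4-7 (default 5).
#' @param r2_min Quality gate on the best window's R^2 (default 0.99).
#' @return The curve with `window`, `efficiency`, `r_squared` and `flagged`
#'   set.
#' @export
fit_efficiency <- function(curve, window_len = 5, r2_min = 0.99) {
  stopifnot(inherits(curve, "amp_curve"))
  if (is.null(curve$corrected)) {
    abort("Baseline-correct the curve first (correct_baseline).")
  }
  if (window_len < 4 || window_len > 7) abort("window_len must be 4-7 cycles.")
  w <- find_window(curve$cycle, curve$corrected, window_len)
  if (!is.finite(w$r2)) {
    abort("No positive-signal window: flat/failed reaction.")
  }
  idx <- seq(w$start, w$start + window_len - 1)
  curve$window <- c(curve$cycle[idx[1]], curve$cycle[idx[window_len]])
  curve$efficiency <- 10^w$slope
  curve$r_squared <- w$r2
  curve$flagged <- w$r2 < r2_min
  if (curve$flagged) {
    warn(sprintf("Well %s: best window R^2 = %.4f < %.2f; flagged low-quality.",
                 curve$well_id, w$r2, r2_min))
  }
  curve
}

#' Amplicon-group efficiency, threshold and Ct extraction
#'
#' Pools fitted curves sharing one amplicon: the group efficiency is the
#' arithmetic mean of the unflagged per-curve efficiencies, and the group
#' fluorescence threshold is the geometric mean over curves of the corrected
#' signal at each curve's window midpoint (placing the threshold inside every
#' exponential phase). Each curve's Ct is the fractional cycle at which its
#' corrected signal crosses the threshold, log-linearly interpolated between
#' the bracketing cycles; curves that never reach the threshold get `NA`.
#'
#' @param curves List of fitted [amp_curve()]s sharing an `amplicon_id`.
#' @param threshold Optional fluorescence threshold overriding the group rule.
#' @return A list with `amplicon_id`, `efficiency`, `threshold` and a tibble
#'   `cts` (`well_id`, `ct`, `flagged`).
#' @export
amplicon_group <- function(curves, threshold = NULL) {
  if (inherits(curves, "amp_curve")) curves <- list(curves)
  if (length(curves) == 0) abort("No curves supplied.")
  amp <- unique(vapply(curves, function(cv) cv$amplicon_id, character(1)))
  if (length(amp) != 1) abort("All curves must share one amplicon_id.")
  fitted <- vapply(curves, function(cv) !is.na(cv$efficiency), logical(1))
  if (!all(fitted)) abort("Fit all curves with fit_efficiency first.")
  ok <- !vapply(curves, function(cv) cv$flagged, logical(1))
  if (!any(ok)) abort("All curves in the amplicon group are flagged low-quality.")

  efficiency <- mean(vapply(curves[ok], function(cv) cv$efficiency, numeric(1)))
  if (is.null(threshold)) {
    mids <- vapply(curves[ok], function(cv) {
      mid <- (cv$window[1] + cv$window[2]) / 2
      # corrected signal at the (possibly half-integer) window midpoint,
      # log-interpolated between the two nearest cycles
      interp_signal(cv$cycle, cv$corrected, mid)
    }, numeric(1))
    threshold <- geo_mean(mids)
  }

  cts <- purrr::map_dfr(curves, function(cv) {
    tibble::tibble(well_id = cv$well_id,
                   ct = cross_threshold(cv$cycle, cv$corrected, threshold),
                   flagged = cv$flagged)
  })
  list(amplicon_id = amp, efficiency = efficiency, threshold = threshold,
       cts = cts)
}

interp_signal <- function(cycle, signal, at) {
  if (at <= cycle[1]) return(signal[1])
  n <- length(cycle)
  if (at >= cycle[n]) return(signal[n])
  i <- max(which(cycle <= at))
  if (cycle[i] == at) return(signal[i])
  f <- (at - cycle[i]) / (cycle[i + 1] - cycle[i])
  if (signal[i] > 0 && signal[i + 1] > 0) {
    10^((1 - f) * log10(signal[i]) + f * log10(signal[i + 1]))
  } else {
    (1 - f) * signal[i] + f * signal[i + 1]
  }
}

cross_threshold <- function(cycle, signal, threshold) {
  above <- signal >= threshold
  if (!any(above)) return(NA_real_)
  i <- which(above)[1]
  if (i == 1) return(NA_real_)  # already above threshold at the first cycle
  s0 <- signal[i - 1]; s1 <- signal[i]
  if (s1 == threshold) return(as.numeric(cycle[i]))
  if (s0 <= 0) return(as.numeric(cycle[i]))
  cycle[i - 1] + (cycle[i] - cycle[i - 1]) *
    (log10(threshold) - log10(s0)) / (log10(s1) - log10(s0))
}
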