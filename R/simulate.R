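#' Specification for a synthetic Ct experiment
#'
#' Describes the ground-truth world for [simulate_ct_dataset()]:
#' \deqn{Ct_{g,s} = \mu_g + shift_s + \beta_g(cond_s) + \varepsilon_{g,s}}
#' with per-sample loading shifts \eqn{shift_s \sim N(0, \delta^2)} (shared by
#' all genes of a sample, hence invisible to delta-Ct statistics), gene- and
#' condition-specific treatment effects \eqn{\beta} (0 = perfectly stable
#' gene) and replicate noise \eqn{\varepsilon \sim N(0, \sigma^2)}.
#'
#' Defaults emulate a seedling abiotic-stress screen: 13 candidate genes with
#' baseline Ct set to published root-tissue means (17.6-25.8 cycles), two
#' tissues (root, shoot), a mock-treated control series plus four stress
#' treatments (dehydration, salt, cold, ABA) sampled at 0, 2 and 10 h with
#' three biological replicates, loading-shift SD 0.5 cycles and replicate
#' noise SD 0.2 cycles.
#'
#' @param n_genes Number of candidate genes (default 13).
#' @param gene_ids Gene names (default the 13-gene candidate panel when
#'   `n_genes` is 13, otherwise `g01`, `g02`, ...).
#' @param mu Per-gene baseline Ct (cycles); recycled to `n_genes`.
#' @param tissues,treatments,timepoints,replicates Design factors, fully
#'   crossed.
#' @param delta SD (cycles) of the per-sample loading shift (default 0.5).
#' @param sigma SD (cycles) of replicate noise (default 0.2).
#' @param beta Treatment effects: a data frame with columns `gene_id`,
#'   `treatment`, optional `timepoint_h`, and `effect` (cycles). Rows without
#'   `timepoint_h` apply to every non-zero timepoint of that treatment.
#'   Default: none (all genes perfectly stable).
#' @param seed Integer seed; mandatory, no hidden global randomness.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(n_genes = 13, gene_ids = NULL, mu = NULL,
                     tissues = c("root", "shoot"),
                     treatments = c("control", "dehydration", "salt", "cold", "ABA"),
                     timepoints = c(0, 2, 10), replicates = 3,
                     delta = 0.5, sigma = 0.2, beta = NULL, seed) {
  if (missing(seed)) abort("`seed` is mandatory: simulations are reproducible by construction.")
  if (replicates < 1) abort("Need a positive replicate count.")
  if (delta < 0 || sigma < 0) abort("Noise SDs must be non-negative.")
  if (is.null(gene_ids)) {
    gene_ids <- if (n_genes == 13) {
      c("60s", "ABC", "Act11", "Act27", "CDPK", "CYP2", "ELF1a",
        "ELF1b", "Fbox", "IDE", "SUBI2", "TUBa", "TUBb")
    } else {
      sprintf("g%02d", seq_len(n_genes))
    }
  }
  stopifnot(length(gene_ids) == n_genes)
  if (is.null(mu)) {
    mu <- if (n_genes == 13) {
      # published root-tissue mean Cts for the default panel
      c(21.31, 23.64, 19.11, 21.64, 25.79, 17.63, 18.41,
        20.67, 21.09, 21.66, 25.30, 20.12, 20.60)
    } else {
      seq(18, 26, length.out = n_genes)
    }
  }
  mu <- rep_len(mu, n_genes)
  if (!is.null(beta)) {
    beta <- tibble::as_tibble(beta)
    if (!all(c("gene_id", "treatment", "effect") %in% names(beta))) {
      abort("`beta` needs columns gene_id, treatment, effect (timepoint_h optional).")
    }
    if (!"timepoint_h" %in% names(beta)) beta$timepoint_h <- NA_real_
  }
  structure(list(n_genes = n_genes, gene_ids = gene_ids, mu = mu,
                 tissues = tissues, treatments = treatments,
                 timepoints = timepoints, replicates = replicates,
                 delta = delta, sigma = sigma, beta = beta, seed = seed),
            class = "sim_spec")
}

#' Simulate a Ct dataset with known stability ground truth
#'
#' @param spec A [sim_spec()].
#' @return A list with
#'   * `dataset`: a [ct_dataset()] (efficiencies default to 2);
#'   * `truth`: tibble `gene_id`, `instability` (cycles), `rank` — the
#'     analytic expected instability \eqn{\sqrt{Var_{pop}(\beta_g) + \sigma^2}}
#'     where the variance is taken over the design cells, so 0-effect genes
#'     with equal noise tie;
#'   * `spec`: the input spec.
#' @examples
#' sim <- simulate_ct_dataset(sim_spec(seed = 42))
#' sim$truth
#' @export
simulate_ct_dataset <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  design <- tidyr::expand_grid(
    tissue = spec$tissues, treatment = spec$treatments,
    timepoint_h = spec$timepoints, replicate = seq_len(spec$replicates)
  ) |>
    dplyr::mutate(sample_id = sprintf("%s_%s_%gh_r%d", .data$tissue,
                                      .data$treatment, .data$timepoint_h,
                                      .data$replicate))

  beta_of <- beta_lookup(spec)
  # per-gene x design-cell effect matrix (genes x samples)
  b <- sapply(seq_len(nrow(design)), function(s) {
    beta_of(design$treatment[s], design$timepoint_h[s])
  })
  if (is.null(dim(b))) b <- matrix(b, nrow = spec$n_genes)

  withr_seed <- spec$seed
  old <- .Random.seed_exists()
  set.seed(withr_seed)
  shift <- stats::rnorm(nrow(design), 0, spec$delta)
  eps <- matrix(stats::rnorm(spec$n_genes * nrow(design), 0, spec$sigma),
                nrow = spec$n_genes)
  on.exit(restore_seed(old), add = TRUE)

  ctm <- spec$mu + b + rep(shift, each = spec$n_genes) + eps
  long <- tidyr::expand_grid(sample = seq_len(nrow(design)),
                             gene = seq_len(spec$n_genes)) |>
    dplyr::mutate(
      sample_id = design$sample_id[.data$sample],
      tissue = design$tissue[.data$sample],
      treatment = design$treatment[.data$sample],
      timepoint_h = design$timepoint_h[.data$sample],
      replicate = design$replicate[.data$sample],
      gene_id = spec$gene_ids[.data$gene],
      ct = ctm[cbind(.data$gene, .data$sample)]
    ) |>
    dplyr::select(-"sample", -"gene")

  truth <- tibble::tibble(
    gene_id = spec$gene_ids,
    instability = sqrt(apply(b, 1, function(x) mean((x - mean(x))^2)) +
                         spec$sigma^2)
  ) |>
    dplyr::mutate(rank = rank(.data$instability, ties.method = "min"))

  list(dataset = ct_dataset(long), truth = truth, spec = spec)
}

beta_lookup <- function(spec) {
  function(treatment, timepoint_h) {
    out <- numeric(spec$n_genes)
    if (is.null(spec$beta)) return(out)
    hit <- spec$beta$treatment == treatment &
      (is.na(spec$beta$timepoint_h) & timepoint_h > 0 |
         !is.na(spec$beta$timepoint_h) & spec$beta$timepoint_h == timepoint_h)
    if (any(hit)) {
      rows <- spec$beta[hit, ]
      idx <- match(rows$gene_id, spec$gene_ids)
      out[idx] <- out[idx] + rows$effect
    }
    out
  }
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate a single amplification curve with known truth
#'
#' Generates \deqn{signal_c = baseline + \min(n_0 E^c, plateau)(1 + \eta_c)}
#' with multiplicative noise \eqn{\eta_c \sim N(0, noise\_sd^2)}.
#'
#' @param e Fold-per-cycle amplification efficiency, in `(1, 2.2]`.
#' @param n0 Initial template signal (> 0).
#' @param baseline Constant background fluorescence (>= 0).
#' @param cycles Number of cycles (default 40).
#' @param plateau Saturation ceiling of the amplified signal (> baseline
#'   contribution is not included; the ceiling clamps `n0 * e^c`).
#' @param noise_sd Multiplicative noise SD as a fraction (default 0).
#' @param seed Integer seed; mandatory when `noise_sd > 0`.
#' @param well_id,amplicon_id Identifiers.
#' @return A list with `curve` (an [amp_curve()]) and `truth`
#'   (`e`, `baseline`, and `ct_at(threshold)`, the analytic fractional cycle
#'   at which the noise-free amplified signal reaches a threshold).
#' @export
simulate_amplification <- function(e, n0, baseline = 0, cycles = 40,
                                   plateau = Inf, noise_sd = 0, seed = NULL,
                                   well_id = "w1", amplicon_id = "a1") {
  check_efficiency(e)
  if (n0 <= 0) abort("n0 must be positive.")
  if (plateau <= baseline && is.finite(plateau)) {
    abort("plateau must exceed the baseline.")
  }
  cyc <- seq_len(cycles)
  amplified <- pmin(n0 * e^cyc, plateau)
  eta <- if (noise_sd > 0) {
    if (is.null(seed)) abort("`seed` is mandatory when noise_sd > 0.")
    old <- .Random.seed_exists()
    set.seed(seed)
    on.exit(restore_seed(old), add = TRUE)
    stats::rnorm(cycles, 0, noise_sd)
  } else {
    numeric(cycles)
  }
  signal <- baseline + amplified * (1 + eta)
  signal[signal < 0] <- 0
  truth <- list(e = e, baseline = baseline,
                ct_at = function(threshold) log(threshold / n0) / log(e))
  list(curve = amp_curve(cyc, signal, well_id = well_id,
                         amplicon_id = amplicon_id),
       truth = truth)
}
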