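---
title: "Choosing stable qPCR reference genes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing stable qPCR reference genes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

Quantitative RT-PCR expresses a target gene's abundance relative to one or
more reference ("housekeeping") genes, assumed to be equally expressed in
every sample. When a supposedly stable reference drifts with the treatment —
common under abiotic stresses such as dehydration, salt, cold or the hormone
ABA, which remodel large parts of the transcriptome — every normalized fold
change inherits that drift. A 2-to-3-fold induction can disappear entirely
behind an unstable normalizer. `refstab` implements the two standard
candidate-screening statistics, the curve preprocessing that produces the Ct
values they consume, and the efficiency-corrected quantification that the
chosen references feed into, so the whole chain from raw fluorescence to
validated fold change can be run and audited in one place.

## The delta-Ct stability statistic

For genes $g, k$ measured in the same sample $s$, the difference
$\Delta Ct_s = Ct_{g,s} - Ct_{k,s}$ cancels the sample's template amount and
loading. If both genes were ideal references, $\Delta Ct$ would be constant
across samples; its spread therefore measures the *joint* instability of the
pair. Each unordered pair is scored by the **population** standard deviation
(divisor $N$, the spreadsheet `STDEVP`) of its $\Delta Ct$ values, and each
gene by the mean of its pair SDs over all other candidates:

$$\mathrm{meanSD}_g = \frac{1}{G-1}\sum_{k \ne g}
  \mathrm{SD}_\mathrm{pop}\{\,Ct_{g,s}-Ct_{k,s}\,\}_s .$$

Lower is more stable; genes are ranked ascending. The population-SD
convention is deliberate: the published statistics this package reproduces
are labelled `STDEVP`, and we apply the same divisor everywhere (including
the geNorm V statistics below) so the two engines agree exactly in the
special case described next. Within a condition subset, all samples —
control and treated, every timepoint, every biological replicate, and both
tissues in the combined analyses — enter as independent samples; control
samples are retained in stress subsets by default (`include_control = TRUE`)
because the screening question is "is this gene stable between control and
stressed material", and the switch is exposed for users who want
treated-only spread. Missing wells are tolerated pairwise: each pair uses
its pairwise-complete samples and must share at least three.

## geNorm: M values, stepwise exclusion, V ratios

Ct values are first converted to relative quantities
$Q_{g,s} = E_g^{\,minCt_g - Ct_{g,s}}$, anchored at each gene's minimum Ct,
with $E_g$ the amplicon's fold-per-cycle amplification efficiency. The
pairwise variation $V_{gk}$ is the population SD over samples of
$\log_2(Q_{g,s}/Q_{k,s})$, and $M_g$ is the mean of $V_{gk}$ over partners.
The stepwise procedure recomputes M on the remaining panel, drops the
highest-M gene (ties broken towards the lexicographically last gene id, so
the result is deterministic), and stops when two genes remain — by
construction the ratio criterion cannot order the final pair, which is
reported unordered with a shared M. Normalization factors $NF_{n,s}$
(geometric means of the top-$n$ genes' quantities) yield
$V_{n/n+1} = \mathrm{SD}_\mathrm{pop}\,\log_2(NF_n/NF_{n+1})$, the usual
guide for how many references are enough.

Two modes are exposed: efficiency-corrected quantities when per-amplicon
$E$ values are supplied (the gene table), and the $E = 2$ fallback. The
$E = 2$ mode is pinned to the delta-Ct engine by an exact identity: since
$\log_2(Q_g/Q_k) = \text{const} - \Delta Ct$, every $V_{gk}$ equals the
delta-Ct pair SD and the full-panel M equals the delta-Ct mean SD. The test
suite asserts this elementwise at $10^{-9}$ on random matrices, which guards
both engines against independent drift.

The stepwise engine is validated against a brute-force oracle that
recomputes M from the definition at every round — no shared code, no
incremental updates — and must agree on exclusion order, final pair and all
M values.

## Curve preprocessing (window-of-linearity)

The Ct extraction the stability engines consume is delegated in practice to
baseline-corrected raw fluorescence. The package fixes the following
testable choices, since the published method's internals are configurable:

* **Constant baseline**, found by grid search over $[0, \min(\text{signal}))$
  with golden-section refinement. Candidates are scored by the $R^2$ of the
  log-linear fit in the *earliest* qualifying window of the corrected
  signal: an additive background bends the log plot exactly where the signal
  is comparable to it (the early cycles), while late high-signal windows are
  numerically insensitive to the constant, so scoring on the global best
  window would leave the baseline unidentifiable. On noiseless
  exponential-plus-constant curves the true constant is recovered to better
  than $10^{-6}$.
* **Efficiency** from the sliding window (default 5 cycles, configurable
  4–7) maximizing the $R^2$ of $\log_{10}(\text{signal})$ on cycle; ties go
  to the earliest window; $E = 10^{\text{slope}}$, reported in the
  fold-per-cycle convention ($E \in (1, 2]$ for real amplicons, 2 = perfect
  doubling). Fits with $R^2 < 0.99$ are kept but flagged and excluded from
  group averages.
* **Amplicon-based thresholds**: curves of one amplicon share a threshold —
  the geometric mean of each curve's corrected signal at its window
  midpoint — and the group efficiency is the arithmetic mean of unflagged
  per-curve efficiencies. Ct is the fractional crossing cycle, interpolated
  log-linearly between the bracketing cycles. Whether per-well or group-mean
  efficiency feeds downstream quantification was left open by the source
  method; the group mean is used, matching the per-amplicon efficiencies of
  the published gene table.

Monte-Carlo calibration with the package's own generator (200 curves,
$E = 1.85$, 2 % multiplicative noise) puts ~97.5 % of recovered efficiencies
within 0.05 of truth (median absolute error ≈ 0.011); the corresponding test
asserts the 0.05 band at the 90 % level to stay clear of binomial flake.

## Efficiency-corrected quantification

Fold changes use the Pfaffl-type ratio rather than $2^{-\Delta\Delta Ct}$,
because per-amplicon efficiencies are available and measurably below 2:

$$\mathrm{ratio}_r =
  \frac{E_t^{\,Ct_{t,cal} - Ct_{t,r}}}
       {\left(\prod_{ref} E_{ref}^{\,Ct_{ref,cal} - Ct_{ref,r}}\right)^{1/R}},$$

with the calibrator Ct the mean over the 0 h replicates of the same tissue.
The reported fold change is the geometric mean of the per-replicate ratios
(so multi-reference normalization factorizes exactly into the geometric mean
of single-reference results), and the uncertainty is the sample SD of the
per-replicate $\log_2$ ratios divided by $\sqrt{n}$ — reported on the log2
scale, since ratios are log-normal under Gaussian Ct noise. The published
validation table's standard-error estimator is unstated, so those printed
SEs are carried as data, not reproduced. Calibrator rows equal 1 by the
algebra (the ratios centre on their own mean) and are pinned to exactly 1 in
the output. The detection-consistency checker flags any (target, tissue,
condition) cell where one reference scheme calls an induction at the fold
threshold (default 2.0) and another does not — the operational signature of
a bad normalizer.

## The synthetic world

`simulate_ct_dataset()` draws
$Ct_{g,s} = \mu_g + \mathrm{shift}_s + \beta_g(\mathrm{cond}_s) +
\varepsilon_{g,s}$. The defaults state one fixed world and are not tuning
knobs:

| parameter | default | why |
|---|---|---|
| genes | 13, $\mu$ = published root mean Cts (17.6–25.8) | the candidate panel's observed abundance range |
| design | 2 tissues × (control + 4 stresses) × 0/2/10 h × 3 reps | the seedling stress experiment it emulates |
| loading shift $\delta$ | 0.5 cycles | typical between-sample pipetting/RT spread |
| replicate noise $\sigma$ | 0.2 cycles | routine SYBR technical+biological replicate scatter |
| effects $\beta$ | 0 | all genes stable unless the caller perturbs one |

Gaussian noise on the Ct scale is the standard qPCR assumption. Seeds are
mandatory arguments; nothing draws from an unseeded global stream, and the
caller's RNG state is restored on exit. The generator's analytic `truth`
ranks genes by $\sqrt{\mathrm{Var}_\mathrm{pop}(\beta_g) + \sigma^2}$ over
the design cells.

`simulate_amplification()` produces
$\text{baseline} + \min(n_0 E^c, \text{plateau})(1+\eta_c)$ with
multiplicative noise. Note what this world does *not* contain: additive
detector noise floors, inhibitor kinetics, primer-dimer signal, or
co-regulation between candidate genes. A green recovery test therefore
establishes that the estimators invert the stated model, not that they are
robust to every pathology of real plates — in particular, multiplicative
noise keeps early cycles as informative as late ones, which flatters the
earliest-window baseline score relative to curves with a real noise floor.
geNorm's known blind spot, ranking co-regulated genes as jointly "stable",
is likewise invisible here; it is the reason the recommendation stage ranks
by delta-Ct and uses geNorm only as concordance context.

## The recommendation rule

The recommended pair for a condition cell is the top two genes of the
delta-Ct ranking; the geNorm trace contributes a concordance note (are both
genes in its top 5?). This rule was fixed because it reproduces all 15
published per-condition pairs from the printed per-gene statistics — the
package's first acceptance criterion — and because the source analysis
states its conclusions were drawn primarily from the delta-Ct ranking. Any
geNorm-weighted consensus would be a different, unvalidated rule and is
deliberately not offered as a default. Ranking ties are broken
lexicographically by gene id and flagged in the output.

## Numerical and degenerate-input choices

* Population SD everywhere (`STDEVP`); duplicating every sample leaves all
  statistics unchanged, which the tests assert.
* Ct values outside $[1, 45]$ cycles, unknown treatment/tissue labels, and
  duplicate (sample, gene) wells are hard errors at ingest; missing wells
  are explicit `NA`.
* Quantities require complete Cts (drop incomplete samples first); the
  delta-Ct engine instead uses pairwise-complete samples with a floor of 3.
* Efficiencies are validated into $(1, 2.2]$ — slightly above 2 to admit
  estimation error on real amplicons.
* Flat reactions (no positive, non-constant log-window at any candidate
  baseline) error out rather than returning a fabricated efficiency.
* Byte-identical reproducibility: full-precision Cts on write, strtod
  parsing on read, fixed tie-breaks, mandatory seeds.

## Known limitations

* The per-sample raw Ct data behind the published stability tables were
  released only as a binary spreadsheet; the mapping-driven import
  (`read_supplementary_ct()`) is tested on synthetic data of the same shape,
  and the reproduction of the published statistics from raw Cts runs only
  when a text export of that table is supplied.
* The published validation table's standard errors cannot be recomputed
  (estimator and raw target Cts unavailable); they are carried as printed.
* Single-tissue, single-plate experiments only; no plate-layout or
  inter-run calibration handling.
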