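# refstab

Reference-gene stability ranking and efficiency-corrected quantification for
quantitative RT-PCR.

## The problem

qRT-PCR expresses a target gene's abundance relative to reference
("housekeeping") genes assumed to be stably expressed. Under abiotic
stresses — dehydration, high salinity, cold, or ABA treatment, which
reprogram much of a plant's transcriptome — that assumption routinely fails,
and an unstable reference silently distorts every normalized fold change: a
genuine 2–3-fold induction can fall below a 2-fold detection threshold
purely because the normalizer drifted. `refstab` is for anyone screening a
candidate reference panel before an expression study: it ranks candidates by
stability, recommends a reference pair per tissue × treatment condition, and
validates the choice by quantifying targets under good and bad references.

(A cautionary tale from the experiment this package's defaults emulate: the
18S rRNA gene had to be dropped from the candidate panel before any
statistics were run — its abundance is so high that templates must be
diluted ~1000-fold for it alone, and that dilution step injects variability
no stability statistic can repair. No computation fixes a candidate that
cannot be assayed on the same template as the targets.)

## What it computes

* **Delta-Ct stability** (`deltact_stability()`): for every gene pair,
  the population SD (`STDEVP`) of the per-sample Ct difference
  ΔCt = Ct_g − Ct_k; each gene is scored by its mean pair SD, ranked
  ascending (lower = more stable).
* **geNorm** (`relative_quantities()`, `m_values()`, `genorm_ranking()`):
  expression stability M (mean SD of log2 quantity ratios), stepwise
  exclusion of the worst gene down to an unordered best pair, normalization
  factors and pairwise variations V(n/n+1). With all efficiencies at 2 the
  pair variation V_gk equals the delta-Ct pair SD exactly — an identity the
  test suite asserts at 1e-9.
* **Curve preprocessing** (`correct_baseline()`, `fit_efficiency()`,
  `amplicon_group()`): constant-baseline correction, window-of-linearity
  efficiency estimation (E = 10^slope, fold-per-cycle), amplicon-shared
  fluorescence thresholds and fractional Ct extraction.
* **Efficiency-corrected fold changes** (`fold_change()`,
  `reference_consistency()`): Pfaffl-type ratios
  E_t^ΔCt(target) / geomean(E_ref^ΔCt(ref)) against a 0 h calibrator, and a
  checker that flags conditions where reference schemes disagree on
  detection at a fold threshold.
* **Synthetic data with ground truth** (`sim_spec()`,
  `simulate_ct_dataset()`, `simulate_amplification()`): Ct matrices with
  per-sample loading shifts, designed treatment effects and replicate
  noise; sigmoid-free exponential amplification curves with known
  efficiency, baseline and analytic Ct.
* **Reports** (`run_all()`, `recommend_pairs()`, `write_report()`): per
  tissue × treatment cell, both engines plus a recommended pair (top two by
  delta-Ct, geNorm as concordance note). `tidy()`/`glance()`/`autoplot()`
  methods cover the result objects.

The 13-gene soybean candidate panel, its published per-amplicon
efficiencies, the published per-condition stability statistics and the
published validation fold-change table ship as in-code tibbles
(`soybean_gene_panel()`, `soybean_stability_published()`,
`soybean_nac_fold_changes()`, `soybean_recommended_pairs()`).

## Worked example

Simulate the default stress experiment (13 genes, 2 tissues, control + 4
treatments at 0/2/10 h, 3 replicates) with two genes destabilized under
dehydration, then rank the dehydrated-root condition:

```r
library(refstab)

beta <- data.frame(gene_id = c("SUBI2", "TUBa"),
                   treatment = "dehydration", effect = c(2, 1))
sim  <- simulate_ct_dataset(sim_spec(beta = beta, seed = 2024))
dehy <- subset_ct(sim$dataset, tissue = "root", treatments = "dehydration")

dct <- deltact_stability(dehy)
dct
#> <deltact_stability> 13 genes ranked by mean pair SD of delta-Ct
#> # A tibble: 13 × 6
#>   gene_id mean_ct sd_ct mean_sd  rank tied
#>   <chr>     <dbl> <dbl>   <dbl> <int> <lgl>
#> 1 ELF1b      20.6 0.570   0.317     1 FALSE
#> 2 Act11      19.0 0.510   0.319     2 FALSE
#> 3 IDE        21.6 0.540   0.333     3 FALSE
#> 4 ELF1a      18.3 0.639   0.340     4 FALSE
#> 5 Act27      21.6 0.623   0.342     5 FALSE
#> # ℹ 8 more rows

gn <- genorm_ranking(relative_quantities(dehy))
gn
#> <genorm_ranking> 13 genes, best pair: Act11/IDE (M = 0.1482)
#>   V(2/3) = 0.0622

recommend_pairs(dct, gn, condition = "dehydration", tissue = "root")
#> # A tibble: 1 × 8
#>   condition   tissue gene1 gene2 stat1 stat2 method  genorm_top5_concordant
#> 1 dehydration root   ELF1b Act11 0.317 0.319 deltact TRUE
```

Reading the numbers: `mean_sd` is each gene's mean pairwise ΔCt spread in
cycles — ELF1b's 0.317 cycles is the smallest, so it pairs with Act11 as the
recommended references; the destabilized SUBI2 (2-cycle dehydration effect)
lands at the bottom of both rankings. `V(2/3) = 0.062` is far below the
customary 0.15 cut, so two references suffice here. The same recommendation
stage run on the *published* per-gene statistics for dehydrated roots
returns the published pair:

```r
recommend_pairs(
  deltact_from_stats(soybean_stability_published("dehydration", "root")),
  condition = "dehydration", tissue = "root")
#>   condition   tissue gene1 gene2 stat1 stat2 method
#> 1 dehydration root   Fbox  ABC   0.203 0.214 deltact
```

## Acceptance script

`scripts/acceptance.R` recomputes, with the installed package, the stability
statistic of the top-ranked gene for two published condition columns
(dehydration/roots and ABA roots-&-shoots combined): it feeds the 13 printed
per-gene delta-Ct statistics of each column through `deltact_from_stats()`
and `recommend_pairs()`, checks the recommended pair against the published
pair for that condition, and writes the top gene's statistic as JSON.

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
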