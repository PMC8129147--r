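# mrsuite

Two-sample Mendelian randomization (MR) for GWAS summary statistics, with
a simulation framework that makes every stage of the analysis testable
against known ground truth.

MR treats genetic variants as instrumental variables: if variant *j*
shifts a circulating biomarker (the exposure) by β<sub>Xj</sub> and the
same variant shifts disease risk by β<sub>Yj</sub>, then under the
instrumental-variable assumptions the Wald ratio
θ̂<sub>j</sub> = β̂<sub>Yj</sub>/β̂<sub>Xj</sub> estimates the causal
effect of the exposure on the outcome. `mrsuite` implements the full
workflow used in biomarker–disease MR studies:

* **Instrument selection** — genome-wide significance filtering
  (P < 5×10⁻⁸) and greedy LD clumping (r² < 0.01, lowest-P variant kept)
  from a supplied r² matrix.
* **Harmonization** — alignment of outcome effect alleles to the exposure
  coding, handling swapped alleles, strand flips, and palindromic A/T and
  C/G variants (oriented by allele frequency or dropped as ambiguous),
  with a per-variant audit log.
* **The estimator battery** — inverse-variance-weighted (IVW)
  meta-analysis of Wald ratios with an automatic fixed/random-effects
  switch on Cochran's Q (P < 0.05), weighted median, weighted mode,
  MR-Egger regression (intercept = directional pleiotropy under InSIDE),
  the contamination-mixture profile likelihood, and MR-PRESSO outlier
  simulation.
* **Mechanism clustering** — an EM-fitted mixture over variant-specific
  ratios with substantive, null, and junk components, BIC selection of the
  cluster count, and conservative reporting (assignment probability ≥ 0.8,
  at least 4 qualifying variants per reported cluster).
* **Inference across exposures** — Benjamini–Hochberg FDR within exposure
  families, a significant / suggestive / null classification, and analytic
  power for binary and continuous outcomes.
* **Synthetic data** — `sim_config()`/`simulate_pair()` generate
  two-sample summary statistics with configurable causal effect,
  pleiotropy scenario (balanced, directional, clustered mechanisms), LD
  blocks, and allele-coding pathologies, plus a truth table for every
  variant.

Everything is tidyverse-native: datasets and results are tibbles,
estimator outputs have `tidy()`/`glance()` methods, and
`plot_forest()` / `plot_cluster_scatter()` / `autoplot()` produce ggplot2
figures.

## Worked example

Simulate a two-sample pair with a true causal effect of 0.25 (log-OR per
exposure unit), 30% directionally pleiotropic instruments, and messy
allele coding; then run the core pipeline:

```r
library(mrsuite)

cfg <- sim_config(
  n_variants = 40, theta_true = 0.25, seed = 2025,
  pleiotropy_mode = "directional",
  pleiotropy_params = list(mean = 0.05, sd = 0.02, frac = 0.3),
  allele_pathologies = c(swapped = 0.2, flipped = 0.1, palindromic = 0.1),
  binary_outcome = TRUE
)
sim <- simulate_pair(cfg)

instruments <- select_instruments(sim$exposure, p_threshold = 5e-8, ld = sim$ld)
h <- harmonize(instruments, sim$outcome)
dplyr::count(harmonization_audit(h), action)
#> # A tibble: 6 × 2
#>   action                  n
#>   <chr>               <int>
#> 1 beta_flipped            5
#> 2 dropped                 1
#> 3 kept                   30
#> 4 palindrome_flipped      1
#> 5 palindrome_oriented     1
#> 6 strand_flipped          2
```

The audit shows harmonization at work: 5 swapped-allele variants had
their outcome betas sign-flipped, 2 were strand-corrected, 2 palindromic
variants were oriented by allele frequency, and 1 ambiguous palindrome
was dropped.

```r
r <- wald_ratios(h)
mr_ivw(r, model = "auto")
#> <mr_result> IVW: simulated_exposure -> simulated_outcome
#>   estimate 0.3717 (95% CI 0.29, 0.4533), p = 4.55e-19, 39 SNPs
#>   OR 1.45 (95% CI 1.336, 1.574)
#>   heterogeneity Q = 71.7 (p = 0.000764), random effects
```

IVW is biased upward (0.37 vs the true 0.25) because 30% of the
instruments carry a positive direct effect on the outcome, and the
heterogeneity this creates (Q = 71.7 on 38 df) has correctly switched the
model to random effects. The sensitivity estimators tell the same story:

```r
tidy(mr_weighted_median(r, n_boot = 500, seed = 1))[, c("method", "estimate", "se", "pval")]
#> # A tibble: 1 × 4
#>   method          estimate     se     pval
#>   <chr>              <dbl>  <dbl>    <dbl>
#> 1 weighted median    0.376 0.0481 5.35e-15

tidy(mr_egger(h))[, c("method", "estimate", "pval", "intercept", "intercept_pval")]
#> # A tibble: 1 × 5
#>   method   estimate     pval intercept intercept_pval
#>   <chr>       <dbl>    <dbl>     <dbl>          <dbl>
#> 1 MR-Egger    0.578 0.000259   -0.0228          0.140
```

With this many invalid instruments no single sensitivity estimator is a
silver bullet — which is exactly why the battery is run together and why
`run_study()` triggers it automatically whenever an exposure shows a
nominally significant association or significant heterogeneity.

Power at a typical design point (an outcome GWAS of 21,982 cases and
41,944 controls, instruments explaining 5% of exposure variance):

```r
mr_power_binary(n_total = 63926, case_fraction = 21982 / 63926,
                r2 = 0.05, or_alt = 1.10)
#> [1] 0.7257
```

For a full multi-exposure study, build a `run_config()` with exposure and
outcome tables (paths or in-memory datasets), then `run_study()` — it
selects, harmonizes, estimates, clusters flagged exposures, applies
per-family FDR, and writes results TSVs plus a reproducibility manifest.
A thin command-line wrapper with `simulate`, `select`, `harmonize`,
`estimate`, `cluster`, `run`, and `power` subcommands is installed at
`inst/cli/mrsuite.R`.

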