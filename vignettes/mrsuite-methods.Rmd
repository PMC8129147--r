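---
title: "Methods: two-sample Mendelian randomization in mrsuite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization in mrsuite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsuite)
```

## The model

Mendelian randomization (MR) uses genetic variants as instrumental
variables to estimate the causal effect $\theta$ of an exposure $X$ (here,
a circulating biomarker such as an immune-cell count or CRP level) on an
outcome $Y$ (a disease such as Alzheimer's, or an endophenotype such as
hippocampal volume). In the two-sample setting the per-variant association
estimates $(\hat\beta_{Xj}, \hat\sigma_{Xj})$ and
$(\hat\beta_{Yj}, \hat\sigma_{Yj})$ come from non-overlapping GWAS samples,
published as summary statistics. Under the instrumental-variable
assumptions each variant provides a Wald ratio
$\hat\theta_j = \hat\beta_{Yj} / \hat\beta_{Xj}$, and the package's job is
to pool these ratios, probe the assumptions, and control multiplicity
across many exposure–outcome pairs.

A variant $j$ is a *valid* instrument when its only path to $Y$ runs
through $X$. Horizontal pleiotropy — a direct effect $\alpha_j$ on the
outcome — biases the ratio by $\alpha_j / \beta_{Xj}$. The estimator
battery spans the standard ladder of progressively weaker assumptions:

* **IVW**: all instruments valid; weighted mean of ratios with weights
  $w_j = 1/\mathrm{se}(\hat\theta_j)^2$. With first-order delta SEs,
  $\mathrm{se}(\hat\theta_j) = \hat\sigma_{Yj}/|\hat\beta_{Xj}|$, this is
  exactly weighted least squares of $\hat\beta_Y$ on $\hat\beta_X$ through
  the origin — an identity the test suite checks against the normal
  equations at $10^{-10}$.
* **Weighted median**: consistent when instruments carrying $\ge$ 50% of
  the weight are valid.
* **Weighted mode**: consistent when the largest group of instruments
  sharing an asymptotic ratio is valid, even if a minority.
* **MR-Egger**: WLS with a free intercept after orienting
  $\hat\beta_X \ge 0$; the intercept estimates the average direct effect
  (directional pleiotropy) under the InSIDE assumption that instrument
  strength is independent of direct effects.
* **Contamination mixture**: each ratio is either normal about $\theta$
  (valid) or normal about 0 with variance inflated by $\psi^2$ (invalid);
  the profile likelihood over a $\theta$ grid takes, per variant, the
  larger of the two log-densities.
* **MR-PRESSO**: a leave-one-out residual-sum-of-squares test for global
  pleiotropy with per-variant outlier p-values from parametric simulation.

Heterogeneity among ratios is measured by Cochran's
$Q = \sum_j w_j (\hat\theta_j - \hat\theta_{IVW})^2$ on $J-1$ degrees of
freedom. The primary analysis switches automatically: fixed-effect IVW
when $Q$-derived $P \ge 0.05$, random effects otherwise.

## Design choices

Several points are genuinely open in the literature and were fixed as
follows.

**Delta-method order.** First-order ratio SEs are the default because they
make IVW coincide with origin-constrained WLS, giving an exact algebraic
oracle and matching the dominant convention in two-sample MR; second-order
SEs (adding $\hat\beta_Y^2\hat\sigma_X^2/\hat\beta_X^4$) are available via
`wald_ratios(se_order = "second")` and are never smaller, which the suite
checks as an inequality over random draws.

**Random-effects form.** The random-effects SE is the fixed SE inflated by
$\max(1, \sqrt{Q/(J-1)})$ — multiplicative overdispersion floored at the
fixed model — rather than an additive DerSimonian–Laird variance
component. The floor guarantees the random-effects SE never undercuts the
fixed one; the choice is recorded in each result's `effects_model` field.

**Egger small-sample treatment.** Egger slope and intercept p-values use
the $t$ distribution on $J-2$ degrees of freedom and the same
multiplicative overdispersion floor; IVW uses the normal, as its weights
are treated as known.

**Instrument gates.** Sensitivity estimators require at least 3 variants
(the "more than 2 SNPs" convention for markers eligible for sensitivity
analysis); MR-PRESSO requires 4 because its statistic is built from
leave-one-out fits. Below the gate the method reports not-applicable
rather than erroring the study.

**Palindromic variants.** A/T and C/G variants cannot be oriented by
allele labels. When both datasets report an effect-allele frequency and
both are outside $[0.5 - w, 0.5 + w]$ (default $w = 0.08$), orientation is
inferred by frequency agreement; otherwise the variant is dropped as
ambiguous. The window is a configuration knob
(`palindrome_eaf_window`) because published analyses rarely state their
rule; the default encodes common practice.

**LD pruning.** Instrument selection is greedy clumping on a supplied
r² matrix: repeatedly keep the lowest-P remaining variant (ties broken
lexicographically by rsID for determinism) and discard correlated
neighbours at $r^2 \ge 0.01$. No positional windows are used — the rule is
purely the r² threshold, so selection is reproducible from the matrix
alone without a genotype panel.

**Contamination-mixture scale.** $\psi$ defaults to $1.5 \times$ the SD of
the observed ratios; the 95% confidence set is the grid region within
$\chi^2_1(0.95)/2$ log-likelihood units of the maximum and is reported as
a union of intervals — multimodality is informative, not an error. The
reported p-value is a likelihood-ratio test of $\theta = 0$.

**Cluster model.** Mechanism clustering fits, by EM, a mixture over the
Wald ratios with $K$ substantive components
$N(\theta_k, \mathrm{se}(\hat\theta_j)^2)$ (shared mean, variant-specific
variance), a null component fixed at 0, and a junk component uniform over
the observed range extended by twice its width on each side, which keeps
the likelihood proper while absorbing estimates that fit nothing else.
This is a self-contained re-implementation of the published model class,
not a binding to the original package. $K$ is selected over $0..k_{max}$
(default 5) by BIC with $2K+1$ free parameters; each $K$ gets 20 restarts:
one from k-means centers, one seeded at the ratios most distant from zero
(substantive clusters sit away from the null by construction; a mean
initialized in the null mass cannot escape it because EM responsibilities
for a far-away cluster vanish), and the rest from k-means++-style random
spreads. Reporting is conservative: a variant joins a cluster only at
conditional probability $\ge 0.8$, and a cluster is reported only when at
least 4 variants qualify; everything else is relabeled null or junk by
responsibility. Both thresholds are arguments of
`apply_reporting_rule()`, and raising either can only shrink the reported
set.

**FDR families.** One Benjamini–Hochberg family per exposure tier ×
outcome by default (`fdr_family = "tier_outcome"`): primary exposures
against each outcome form their own families, and secondary exposures are
corrected separately. Published descriptions are ambiguous about pooling
outcomes, so the alternative (`"tier"`) is a configuration switch recorded
in the run manifest. Classification: *significant* when $q < 0.05$,
*suggestive* when $p < 0.05$ but $q \ge 0.05$, else *null*.

**Power.** The power calculation is the standard two-sided normal
approximation for a binary outcome: with $b = \log \mathrm{OR}$,
$x = |b|\sqrt{N R^2 \phi(1-\phi)}$ for case fraction $\phi$ and instrument
$R^2$, power $= \Phi(-z_{1-\alpha/2} + x) + \Phi(-z_{1-\alpha/2} - x)$. It
equals $\alpha$ exactly at $\mathrm{OR} = 1$ and is symmetric in
$\mathrm{OR} \leftrightarrow 1/\mathrm{OR}$. The continuous-outcome
analogue drops the case-fraction factor.

## What the generator emulates — and what it does not

`sim_config()` / `simulate_pair()` produce a two-sample pair with known
ground truth: true instrument effects $\beta_{Xj} \sim N(\mu_X,\sigma_X)$,
observed exposure effects with per-variant noise, outcome effects
$\theta \beta_{Xj} + \alpha_j + \varepsilon_j$, and per-variant p-values.
Pleiotropy scenarios cover none, balanced ($\alpha_j$ mean 0), directional
(nonzero mean, violating the assumptions IVW needs while preserving
InSIDE), and clustered (mechanism-specific $\theta_k$ replacing $\theta$).
LD blocks induce equicorrelated effect noise within blocks (pairwise
correlation $\sqrt{r^2}$) and populate the emitted r² matrix.
Allele-coding pathologies — swapped effect/other alleles, strand flips,
palindromic allele pairs, optionally with frequencies forced near 0.5 —
are applied to the outcome dataset only, so the exposure remains the
reference orientation and every harmonization action is auditable against
the truth table.

Default scales (exposure effects $N(0.1, 0.03)$, $\mathrm{se}_X = 0.005$,
$\mathrm{se}_Y = 0.02$, MAF uniform on $[0.05, 0.5]$) give strongly
significant instruments (median $|z| \approx 20$) against a much noisier
outcome, the typical geometry when a large biomarker GWAS is paired with a
disease GWAS. Directional pleiotropy defaults ($\alpha$ mean 0.05, SD
0.02, 30–40% invalid) put the invalid ratios roughly $0.5$ above the
truth — large enough to bias IVW visibly, small enough that median and
mode remain informative.

The generator is deliberately idealized: effect noise is exactly normal
with known SEs, allele frequencies are uniform rather than realistic
spectra, the two samples are fully independent (no overlap bias), and
no individual-level genotypes exist (LD is a stated matrix, not an
estimated one). Passing tests therefore demonstrate correctness of the
estimators and plumbing under the stated model, not robustness to
winner's curse, sample overlap, population stratification, or
misspecified SEs in real GWAS data.

## Numerical choices and degenerate inputs

* Simulated p-values are clamped at the smallest positive double so that
  vanishing noise cannot produce a literal zero, which the validator would
  reject.
* A single-instrument pair reports its Wald ratio with $Q$ undefined
  (`NA`) and the fixed model forced; zero-instrument exposures yield a
  warning and an `NA` row, never an abort — the full study must survive
  one-SNP exposures.
* Identical ratios give $Q = 0$ exactly and a zero kernel bandwidth in the
  weighted mode, which degenerates to the common value.
* EM convergence is declared when the log-likelihood gain drops below
  $10^{-6}$ (cap 500 iterations); the per-iteration trace is kept in the
  diagnostics and is asserted non-decreasing in the tests.
* Bootstrap and simulation SEs (`n_boot`, `n_sim`) are seeded through the
  pipeline's single stage-seed stream, so a study is byte-identical on
  re-run with the same configuration.
* Problem sizes in the shipped simulation studies (for example 500
  calibration replicates of 20 instruments, 200 robustness replicates of
  30, clustering on 28 variants) were chosen so the whole suite exercises
  every estimator at meaningful Monte-Carlo resolution while remaining
  comfortable to run repeatedly during development.

## Known limitations

No proxy-SNP lookup for instruments missing in the outcome; no Steiger
direction filtering; no multivariable MR; no correlated-instrument IVW
(instruments are pruned to near-independence upstream); the MR-PRESSO
distortion test is not implemented. Indels and multi-allelic records are
rejected at load rather than harmonized. These are scope decisions, not
oversights.
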