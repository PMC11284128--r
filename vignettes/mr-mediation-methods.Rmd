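---
title: "Methods: two-sample MR mediation along a causal chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR mediation along a causal chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chainMR)
```

## The model

chainMR implements two-sample Mendelian randomization (MR) from GWAS
summary statistics, organised around mediation along a causal chain

$$X \;\xrightarrow{\;\gamma\;}\; Z \;\xrightarrow{\;\delta\;}\; Y,
\qquad X \xrightarrow{\;\tau\;} Y \text{ (direct)},$$

where $X$ is an exposure (here, a microbial taxon's abundance), $Z$ a
candidate mediator (an inflammatory factor), and $Y$ a binary disease
outcome analysed on the log-odds scale. Genetic variants serve as
instrumental variables under the three core IV assumptions: association
with the exposure, independence from confounders, and no effect on the
outcome except through the exposure. The total causal effect decomposes as
$\beta_\mathrm{Total} = \tau + \gamma\delta$; the mediated share is
$\gamma\delta / (\tau + \gamma\delta)$.

The two-step estimator assembles the decomposition from three regressions
on summary statistics:

* $\hat\beta_\mathrm{Total}$ — univariable IVW of $Y$ on $X$'s instruments;
* $\hat\beta_{XZ}$ — univariable IVW of $Z$ on $X$'s instruments
  ($\hat\gamma$);
* $\hat\beta_{ZY}$ — the mediator's *direct* effect from multivariable MR
  with $X$ and $Z$ jointly instrumented ($\hat\delta$);

and reports $\hat\beta_{XZ}\hat\beta_{ZY}$ as the mediated effect and
$\hat\beta_{XZ}\hat\beta_{ZY}/\hat\beta_\mathrm{Total}$ as the proportion
mediated (displayed as a percentage with two decimals). A mediating effect
is only claimed when the mediated and total effects share direction;
`sign(0)` is treated as inconsistent with any nonzero sign, so a zero
mediated effect never supports a claim. No confidence interval is attached
to the proportion — a delta-method interval would require the covariance
of estimates from two non-overlapping samples, which summary data do not
identify, so none is invented.

## Instrument selection

The selection pipeline runs in a fixed order, and each step logs its
count so the non-increasing sequence can be audited:

1. **p-value threshold** — strictly below $1\times10^{-5}$ (locus-wide,
   the primary analysis) or $5\times10^{-8}$ (genome-wide, the strict
   rerun). The boundary value is excluded.
2. **LD clumping** — greedy: the best remaining SNP becomes the index and
   removes same-chromosome neighbours within $\pm$10,000 kb having
   $r^2 > 0.001$ with it. Ties on p are broken by (chromosome, position,
   id), so the result is invariant to input row order. Pairs absent from
   the LD table count as unlinked; no reference-panel computation and no
   proxy search is attempted.
3. **instrument strength** — the F statistic
   $F = R^2(n-1-k)\,/\,((1-R^2)k)$ with $F < 10$ flagging weak
   instruments. The acting filter is per-SNP ($k=1$); the set-level F is
   also reported. Because microbiome-scale GWAS rarely publish per-SNP
   $R^2$, the default is the z-score approximation
   $r^2 = z^2/(z^2+n-2)$, which needs neither allele frequency nor
   phenotype variance; $2p(1-p)\beta^2$ is available for standardized
   continuous traits.
4. **outcome-association filter** — SNP $j$ is removed iff
   $P_{\mathrm{outcome},j} < P_{\mathrm{exposure},j}$ (strict; ties
   kept). For a rare binary outcome this rule also guards the reverse
   analysis: shared instruments that are more significant in the disease
   GWAS than in the trait GWAS are excluded before any reverse estimate.
5. **harmonization** — outcome effects are aligned to the exposure's
   effect allele, flipping signs (and complementing frequencies) for
   swapped alleles, resolving strand complements, and dropping
   irreconcilable pairs. Palindromic SNPs (A/T, G/C) are dropped outright
   rather than resolved by frequency, trading a few instruments for zero
   strand ambiguity. Harmonization is idempotent.
6. **exclusion list** — a user-supplied set of variant ids (the stand-in
   for a confounder-database lookup) is removed last.

## Estimators

All estimators consume the harmonized per-SNP pairs
$(\hat\beta_{Xj}, \hat\beta_{Yj})$ with weights $w_j = 1/se_{Yj}^2$.

* **Wald ratio** ($k=1$): $\hat\beta_{Yj}/\hat\beta_{Xj}$ with the
  first-order SE $se_{Yj}/|\hat\beta_{Xj}|$ — adequate because F $\ge$ 10
  is enforced upstream.
* **IVW**: weighted regression through the origin. The fixed-effect SE is
  $(\sum_j w_j\hat\beta_{Xj}^2)^{-1/2}$; under multiplicative random
  effects it is inflated by $\max(1, \sqrt{Q/(k-1)})$. The default is
  fixed with an automatic switch to random effects when Cochran's Q
  rejects at 0.05 — heterogeneity switches the model, it does not veto the
  claim.
* **MR-Egger**: the same regression with an intercept after orienting all
  SNPs to non-negative exposure effects; the intercept estimates
  directional pleiotropy, and SEs carry the overdispersion factor
  $\max(1,\sqrt{RSS/(k-2)})$. Degrees-of-freedom quantiles are not used:
  1.96 is applied uniformly (below).
* **Weighted median**: ratio estimates sorted, weights normalized, and
  the estimate interpolated at cumulative weight $1/2$ using percentile
  positions $p_j = \sum_{i\le j} w_i - w_j/2$; consistent when valid
  instruments carry $\ge 50\%$ of the weight.
* **Simple and weighted mode**: the mode of a normal-kernel density over
  the ratio estimates, bandwidth $1.06\,s\,k^{-1/5}$ (normal reference on
  the ratio scale, $s$ the [weighted] SD) times a configurable factor;
  consistent when the largest group of instruments agreeing on an
  estimate is valid.

Median and mode SEs come from a seeded parametric bootstrap (default
1000 draws) resampling both $\hat\beta_X$ and $\hat\beta_Y$ from their
sampling distributions; identical seeds reproduce SEs bit-identically.
The bootstrap count and bandwidth rule are package defaults, not values
taken from any particular study.

Multivariable MR regresses $\hat\beta_Y$ on the $m$ exposure columns
without intercept (IVW), with an intercept after orienting on the first
exposure (Egger), or by weighted least-absolute-deviations (median
regression). For the LAD fit, small designs — including the $m=2$
exposure-plus-mediator design used throughout — are solved *exactly* by
enumerating the interpolating vertices (the LAD solution passes through
$m$ observations); iteratively reweighted least squares with an
$\varepsilon$-continuation schedule is the fallback for large designs.
Plain IRLS was observed to stall near vertex crossings on contaminated
designs, which motivated the exact solver. An exposure column that is
identically zero is excluded from the fit with a warning (its estimate is
`NA`), so the remaining columns nest the lower-dimensional model;
collinearity among non-degenerate columns is an error.

## Sensitivity suite and the decision gate

* **Cochran's Q** on the ratio estimates, $\chi^2_{k-1}$ under
  homogeneity.
* **Egger intercept test**, sharing the regression code path exactly.
* **MR-PRESSO**: the observed statistic is
  $\sum_j w_j(\hat\beta_{Yj} - \hat\theta_{(-j)}\hat\beta_{Xj})^2$ with
  leave-one-out IVW slopes; its null distribution is simulated
  parametrically (default 1000 draws, seeded), and the global p uses the
  add-one correction $(1 + \#\{\mathrm{sim} \ge \mathrm{obs}\})/(n+1)$,
  so it is never exactly zero. Per-SNP outlier p-values are
  Bonferroni-corrected at 0.05; flagged SNPs are removed and the analysis
  re-run (one round by default, iterable to a fixed point with a cap of
  5 — each round's flagged set is empty or strictly smaller, so the loop
  terminates). When outliers are removed, a distortion test compares the
  estimate shift against random subsets of the same size.
* **Leave-one-out** IVW, flagging any SNP whose omission flips the sign
  or the 0.05 significance of the estimate.

The gate calls a pair *positive* iff the IVW p-value is below 0.05, all
method estimates share a sign, and neither the Egger intercept nor the
(post-removal) PRESSO global test indicates pleiotropy at 0.05.
Diagnostics that cannot run (too few instruments) do not veto. Screens
classify IVW p-values after grouped Benjamini–Hochberg correction:
*significant* requires $P<0.05$ and $P_\mathrm{FDR}<0.1$, *potential*
$P<0.05$ with $P_\mathrm{FDR}\ge 0.1$. FDR families are configurable; the
convention used by the analysis scripts groups microbial exposures by
taxonomic rank within each outcome (a phylum-level family of nine
reproduces the published adjusted value $9 \times 2.71\times10^{-3} =
2.44\times10^{-2}$) and inflammatory factors across the factor-by-outcome
family.

Replication cohorts are pooled by fixed-effect inverse-variance
meta-analysis, with DerSimonian–Laird reported alongside when the Q test
is suggestive ($p<0.1$); $I^2 = \max(0, (Q-df)/Q)\times 100$. A claim is
retained iff the pooled p-value stays below 0.05.

## The synthetic generator

`simulate_chain()` draws, per SNP $j$ with MAF $p_j \sim
U(\mathrm{maf\_range})$: a true exposure effect $b_j \sim N(0,
\sigma_b^2)$; sampling SEs from the standardized-trait formula $se =
1/\sqrt{2p_j(1-p_j)N}$; and observed effects
$\hat\beta \sim N(\mathrm{true}, se^2)$ independently per GWAS (strict
two-sample designs — no sample overlap). True effects follow the chain:
mediator $\gamma b_j$, outcome $(\tau+\gamma\delta)b_j$. P-values are
exact two-sided normal tails (floored at $10^{-300}$ where the tail
underflows, as published GWAS files do).

Design choices a reader should know:

* **Binary outcomes are simulated directly on the log-odds scale**, not
  through individual-level case–control sampling: two-sample MR consumes
  only summary statistics, and for a *rare* outcome the realistic knob is
  the effective sample size $4/(1/\mathrm{cases} + 1/\mathrm{controls})$,
  which is what `n_outcome` should be set to (the analysis scripts use
  8000 for a biobank cohort with roughly 2000 cases).
* **Pleiotropy is planted on the exposure-increasing allele**: the
  invalid fraction receives $\mathrm{sign}(b_j)\,\alpha_j$ with
  $\alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2)$. "Directional" is only
  meaningful relative to an allele orientation, and MR-Egger orients to
  positive exposure effects; under raw allele coding a nonzero
  $\mu_\alpha$ would average out and be unrecoverable by construction.
* **Mediator-specific and outcome-specific SNPs** (`n_snps_mediator`,
  `n_snps_outcome`) carry effects on only that trait. The mediator's own
  instruments are what identify its direct effect in multivariable MR —
  with exposure-driven SNPs alone the design matrix has rank 1 and
  $\delta$ is unidentified. Outcome-specific SNPs give the disease GWAS
  instruments of its own, which is what makes reverse-MR analyses
  meaningful.
* **Outliers** add $\pm 10\,se_Y$ to the observed outcome effect of
  randomly chosen exposure SNPs. **Palindromic SNPs** are planted at a
  configurable fraction (default 10%) and are expected to be dropped
  downstream. **LD blocks** (optional) assign consecutive SNPs a common
  pairwise $r^2$ and nearby positions to exercise clumping; true effects
  within a block remain independent, so the LD table drives pruning only.
* Defaults mirror the study setting: exposure GWAS of ~18,000
  (microbiome-consortium scale), mediator ~22,000 (plasma-protein scale),
  per-SNP effect SD 0.05, MAF in (0.05, 0.5], chain coefficients
  $\gamma=0.3$, $\delta=-0.5$, $\tau=-0.2$ (so 42.9% of the total effect
  is mediated).

What the generator does **not** emulate: realistic LD beyond uniform
blocks, allele-frequency spectra, population stratification, sample
overlap between GWAS, compositional microbiome effects, or case–control
ascertainment. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated generative model, not performance
on real microbiome or proteomic data.

## Numerical choices

* 1.96 is used for all 95% bounds (not a re-derived quantile), so printed
  CI reproduction is bit-stable; p-values are two-sided normal
  throughout.
* Odds ratios display at 2 decimals; proportions mediated at 2 decimals
  of a percentage.
* Summary statistics serialize with 17 significant digits, making the
  write–read round trip bit-identical.
* Clumping ties break by (chromosome, position, id); greedy selection is
  order-invariant.
* The KDE mode guards degenerate spreads (numerical point masses return
  the weighted mean) and refines the 512-point grid maximum by local
  optimization.
* Monte-Carlo p-values use the add-one correction and are never 0; BH
  adjustment is delegated to `stats::p.adjust` within each family.
* Config fingerprints in report manifests use a 32-bit FNV-1a hash
  implemented in exact double arithmetic.

## Validation experiments and their problem sizes

The test suite validates the estimators at sizes chosen to separate the
property under test from known finite-sample phenomena, all run through
the package's own generator and selection pipeline:

* **IVW coverage** (nominal 95%): 30 valid instruments, exposure GWAS of
  $10^6$, outcome effective size $10^5$, 1000 replicates. The exposure
  sample is made large so that "no measurement error" (NOME) holds and
  coverage reflects the interval construction; at equal exposure and
  outcome precision the unmodelled $\hat\beta_X$ noise alone costs a
  visible ~1.5 points of coverage.
* **Egger intercept recovery** (planted $\mu_\alpha = 0.05$): 50
  instruments, 200 replicates, instruments passing the $10^{-5}$
  threshold. Selection matters: without it, SNPs with $|\hat\beta_X|$
  near zero get mis-oriented and systematically deflate the intercept — a
  boundary artefact the real pipeline never encounters because selected
  instruments satisfy $|z| > 4.4$.
* **MR-PRESSO detection**: one $10\,se$ outlier among 20 instruments,
  1000 null simulations, 100 replicates; detection is essentially
  certain, and the global test holds its 5% size on clean data.
* **Two-step mediation recovery**: the $\gamma=0.3, \delta=-0.5,
  \tau=-0.2$ chain. The mean-recovery check (200 replicates, three
  Monte-Carlo SDs) runs at GWAS sizes of $5\times10^5$ with per-SNP
  effect SD 0.1 — pQTL-scale instruments — because it is a consistency
  statement and requires weak-instrument attenuation to be negligible. At
  desk scale ($N = 5\times10^4$, effect SD 0.05) the same estimator shows
  the expected attenuation of a few points, and the suite separately
  checks that the *median* absolute bias of the proportion stays under
  5 points there.
* **Cochran's Q null**: 10 instruments, exposure GWAS of $10^8$ (so
  ratios are exactly normal around the truth), 2000 replicates,
  Kolmogorov–Smirnov agreement with $\chi^2_9$.

The analysis scripts under `analysis/` run a complete ten-taxon study at
honest desk scale (exposure $N$ = 18,340; outcome effective $N$ = 8,000)
where winner's curse and weak-instrument attenuation are visible in the
results — estimates shrink toward zero by roughly 15–20% and borderline
sensitivity flags occur — exactly as they would in a real screen of this
size. The scripts report recovered effects next to the generative truth
rather than hiding the gap.

## Known limitations

* Proportions mediated are reported without interval estimates (see
  above); inference on the proportion should be qualitative.
* The outcome-association filter ($P_Y < P_X$) couples instrument choice
  to outcome noise; with a very well-powered outcome GWAS it can discard
  genuine instruments. The selection log makes this visible.
* MR-PRESSO's distortion test conditions on the observed outlier count
  and is reported for completeness, not gating.
* Steiger directionality filtering, LD-proxy substitution, REML/
  Paule–Mandel heterogeneity estimators, and multi-mediator models are
  deliberately out of scope.
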