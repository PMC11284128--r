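# chainMR

Two-sample Mendelian randomization (MR) from GWAS summary statistics,
organised around mediation along a causal chain — built for study designs
that screen many exposures (e.g. gut-microbiome taxa) against a disease
outcome, probe candidate mediators (e.g. circulating inflammatory
factors), replicate across cohorts, and decompose how much of a causal
effect flows through the mediator.

## Who this is for

Epidemiologists and statistical geneticists running two-sample MR on
published summary statistics, who need the full pipeline — instrument
selection, harmonization, pleiotropy-robust estimation, sensitivity
gating, replication meta-analysis, multiple-testing control, and two-step
mediation — reproducible from seed to report, plus a synthetic GWAS
generator so every stage is testable without access to the original
cohort data.

## The model

For exposure $X$, mediator $Z$ and (binary, log-odds scale) outcome $Y$:

$$X \xrightarrow{\gamma} Z \xrightarrow{\delta} Y, \qquad
X \xrightarrow{\tau} Y,$$

so the total effect is $\beta_\mathrm{Total} = \tau + \gamma\delta$. The
two-step decomposition estimates $\beta_\mathrm{Total}$ and
$\beta_{XZ}=\gamma$ by univariable inverse-variance-weighted (IVW) MR and
$\beta_{ZY}=\delta$ as the mediator's direct effect from multivariable MR
(exposure and mediator jointly instrumented); the mediated effect is
$\beta_{XZ}\beta_{ZY}$ and the proportion mediated
$\beta_{XZ}\beta_{ZY}/\beta_\mathrm{Total}$.

Univariable estimators: Wald ratio, IVW (fixed / multiplicative random
effects with an automatic Q-based switch), MR-Egger, weighted median, and
simple/weighted mode. Sensitivity suite: Cochran's Q, the Egger intercept
test, MR-PRESSO (global test, outlier search with remove-and-rerun,
distortion test) and leave-one-out, combined into a positivity gate.
Replication cohorts pool by inverse-variance meta-analysis (fixed /
DerSimonian–Laird) with $I^2$; screens apply grouped Benjamini–Hochberg
FDR ("significant": $P<0.05$ and $P_\mathrm{FDR}<0.1$; "potential":
$P<0.05$ only). The methods vignette
(`vignettes/mr-mediation-methods.Rmd`) documents every formula, default
and numerical choice.

## Worked example

Simulate a causal chain with known truth ($\gamma = 0.3$,
$\delta = -0.5$, $\tau = -0.2$, hence total effect $-0.35$ and true
mediated proportion $42.9\%$), then run the full two-step analysis:

```r
library(chainMR)

cfg <- chain_sim_config(
  n_snps = 80, n_snps_mediator = 30,
  n_exposure = 50000, n_mediator = 50000, n_outcome = 50000,
  theta_xz = 0.3, theta_zy = -0.5, theta_direct = -0.2, seed = 42
)
sim <- simulate_chain(cfg)

h <- select_instruments(sim$exposure, sim$outcome)
print(h)
#> Harmonized set exposure -> outcome: k = 33 SNPs

print(ivw(h, model = "auto"))
#> MR estimate [ivw] k=33: beta=-0.3568 se=0.0197 p=5.75e-73 OR=0.70 (0.67-0.73) model=fixed

res <- run_two_step(sim$exposure, sim$mediator, sim$outcome, seed = 1)
print(res$mediation)
#> Mediation: total = -0.357, X->Z = 0.281, Z->Y = -0.386
#>   mediated effect = -0.109 (30.44% of total), direction consistent
```

Reading the output: 33 instruments survive the selection pipeline
(p-value threshold, clumping, F ≥ 10, outcome-association filter,
palindrome exclusion); IVW recovers the total effect $-0.357$ (truth
$-0.35$), an odds ratio of 0.70 per exposure SD; the decomposition
attributes 30% of it to the mediator in this single desk-scale
realization (truth 42.9% — the proportion is noisy at these sample
sizes; across 200 replicates at larger N its mean is within Monte-Carlo
error of the truth, see the test suite). The attached sensitivity report
showed no heterogeneity or pleiotropy (Q p = 0.454, Egger intercept
p = 0.160, PRESSO global p = 0.648).

## The analysis workflow

`analysis/` contains the study as numbered scripts over the package:

```sh
Rscript analysis/01_simulate_study.R      # 10-taxon synthetic study + replication cohort
Rscript analysis/02_forward_screen.R      # screen, sensitivity gate, grouped FDR
Rscript analysis/03_reverse_and_strict.R  # reverse MR + genome-wide threshold rerun
Rscript analysis/04_replication_meta.R    # per-cohort IVW + meta-analysis
Rscript analysis/05_mediation.R           # two-step mediation vs generative truth
```

Each stage prints what it found and writes its tables under `results/`
(with a seeded, config-fingerprinted manifest), so the whole study reruns
byte-identically.

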