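---
title: "Patient-specific ceRNA networks: model, parameters and design"
author: "psnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-specific ceRNA networks: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psnet)
```

## The model

A candidate ceRNA unit is a triplet (lncRNA $x$, miRNA $z$, mRNA $y$) in
which both $x$ and $y$ are annotated targets of the same miRNA $z$.
Candidates are assembled by joining an lncRNA–miRNA association list with an
mRNA–miRNA association list on the shared miRNA, restricted to genes present
in the cohort's expression matrices; when several association databases are
supplied per side, their intersection is used. Identifiers are opaque
case-sensitive strings after one normalization pass (whitespace trimmed, the
"miR" token lowercased so that `hsa-miR-424` and `hsa-mir-424` coincide).
Mature-arm suffixes (`-5p`/`-3p`) are *not* stripped by default, because arm
collapsing changes triplet counts; a flag enables it for users whose lists
mix precursor- and mature-level names.

The coupling of $x$ and $y$ net of their shared regulator is the first-order
partial correlation

$$\rho(x, y \mid z) =
  \frac{r_{xy} - r_{xz} r_{yz}}
       {\sqrt{1 - r_{xz}^2}\,\sqrt{1 - r_{yz}^2}},$$

with $r$ the Pearson correlation on the $\log_2(v + 1)$ expression scale.
The log transform is the default because Pearson correlation on raw RNA-seq
magnitudes is dominated by high-expression outliers; `transform = "none"`
disables it. Significance of a partial correlation uses the t statistic
$t = \rho\sqrt{(n-3)/(1-\rho^2)}$ with $n - 3$ degrees of freedom (one
conditioning variable).

A single sample cannot define a correlation network, so patient specificity
is obtained by perturbation: the *reference* network is estimated from the
$n$ normal samples; adding one tumor sample and re-estimating gives that
patient's *perturbed* network, and the differential partial correlation

$$\Delta\rho(x, y \mid z) = \lvert \rho_{n+1}(x,y\mid z) - \rho_n(x,y\mid z) \rvert$$

weights the edges of the patient-specific network. `psnet()` performs the
whole loop and returns a classed fit with `print`, `summary` and `plot`
methods; `patient_network()` projects one sample's network out of it.

## Edge filter and triplet selection

Per tumor sample, an edge is retained when $|\rho_{n+1}| > 0.7$ and its
p-value is below $0.05$ (`psnet_control(rho_abs = 0.7, p_max = 0.05)`).
Cohort-level selection then asks which triplets have mean differential
partial correlation different from zero, via a Z-test over the tumor
samples. Three design choices deserve explanation; each is a documented
default with an option for the alternative reading.

* **Filter-then-test order.** The edge filter runs per sample *before* the
  Z-test, and only passing samples contribute (at least
  `min_samples = 3` of them, else the triplet is dropped with reason
  `"insufficient passing samples"`). Whether non-passing samples should
  instead contribute their $\Delta\rho$ is genuinely open; pooling all
  samples is available with `use_edge_filter = FALSE`. Similarly the filter
  applies to $\rho_{n+1}$ only by default (`filter_reference = TRUE` also
  requires a strong reference edge).
* **Signed differentials.** The Z statistic is computed on the *signed*
  differences $\rho_{n+1} - \rho_n$, not on their absolute values, although
  $\Delta\rho$ (absolute) remains the network edge weight. The mean of an
  absolute value is strictly positive even for an unperturbed triplet, so a
  test of "mean $\Delta\rho \ne 0$" computed on absolute values rejects
  essentially always as the cohort grows; the signed mean is centred at
  zero under no perturbation and makes the selection a calibrated test.
  `signed = FALSE` restores the absolute-value variant for comparison, with
  a one-sided option (`alternative = "greater"`) since that statistic is
  positive by construction.
* **Shared-reference standard error.** All per-sample differences share the
  one estimated reference $\rho_n$, so they are positively correlated: the
  naive $\mathrm{sd}/\sqrt{m}$ understates the variance of their mean by a
  factor $\approx 1 + m/n$. The default standard error is
  $\mathrm{sd}\cdot\sqrt{1/m + 1/n}$, which restores nominal type-I error
  (about 4–5% empirically at $\alpha = 0.05$, versus roughly 13% for the
  naive form at $m = 50$, $n = 100$); `se = "iid"` gives the naive version.

Degenerate inputs — zero-variance genes, perfectly collinear conditioning —
exclude the affected triplet with a recorded reason and never abort a cohort
run. Partial correlations are clipped to $[-1, 1]$ and denominators below
$10^{-12}$ are treated as degenerate. Cohort iteration is sorted by sample
id, so runs are reproducible irrespective of input order.

## Prognostic screening

Each RNA of a selected triplet is dichotomized at its median over the tumor
cohort; the median rather than the mean avoids severely unbalanced
partitions under outliers, and values *equal* to the median are labeled
`low` (a deterministic tie rule). Three binary levels give 8 expression
patterns. Survival turned out to be driven by the lncRNA/mRNA pattern, so
patients are grouped by it: **Group 1** = opposite levels (one high, one
low), **Group 2** = similar levels; the miRNA level is carried but unused.
Within each group the two constituent sub-patterns (e.g. high/low vs
low/high in Group 1) form the binary covariate of a univariate Cox
proportional-hazards model with Efron tie handling; the reported p-value is
the two-sided Wald test. A triplet is called prognostic when at least one
group's p-value falls below `alpha` (default 0.01; 0.05 reproduces the
looser summary-table style of screening). The within-group sub-pattern
covariate is an interpretation — the original description reports one p per
triplet per group without naming the covariate — and is flagged as such; an
optional 8-level likelihood-ratio screen (`method = "patterns8"`) covers
the reading in which all expression patterns enter one categorical model.
Benjamini–Hochberg q-values are reported alongside raw p-values but do not
drive the default filter. Kaplan–Meier curves with censoring marks and the
two-group log-rank test (`km_logrank()`) support visualization; on untied
data the log-rank p agrees with the Cox score test.

Models with no events or a single-arm covariate are recorded as
non-estimable and skipped; Cox fits that fail to converge (monotone
likelihood under complete separation) keep their fit but carry the warning
in the result, and their near-1 Wald p-values simply never pass the filter.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the method assumes,
not RNA-seq in full. Each planted triplet follows a latent Gaussian model:
the miRNA latent is standard normal; lncRNA and mRNA load on it with
`loading = 0.5` and their residuals are correlated `rho_star` in normal
samples and `rho_star + delta` in tumor samples, so the *partial*
correlation given the miRNA is controlled exactly on the latent scale.
Latents map to non-negative expression via $v = 2^{\mu + \sigma w} - 1$
(defaults $\mu = 8$, $\sigma = 1.5$), which is affine on the
$\log_2(v + 1)$ analysis scale — the default transform therefore recovers
the latent correlation structure exactly, up to the small additive
measurement noise (`noise_sd = 0.05`). Decoy triplets are i.i.d. background
and default to 10 per planted triplet; association files list exactly the
planted plus decoy pairs, and a truth table records which is which.

Default cohort sizes are 100 normal and 50 tumor samples — a TCGA-scale
normal cohort and a tumor cohort large enough for the Z-test — with
`rho_star = 0.9` and `delta = -0.5`: the reference coupling must exceed the
0.7 edge filter to be observable at all, and the perturbation weakens it,
as expected when tumor dysregulation decouples a sponge pair. Survival
times are exponential with baseline hazard $\lambda = \log 2 / 1095$ per
day (three-year median) and log hazard ratio `beta` for the planted at-risk
sub-pattern; censoring is independent exponential with per-subject rate
$h_i\, r/(1-r)$, which achieves censoring probability exactly $r$ (default
0.6, heavy as in registry cohorts) for every subject.

What the generator does *not* emulate: count overdispersion
(negative-binomial noise), library-size effects and normalization, shared
miRNAs across triplets, and correlated gene backgrounds. Tests passing on
these cohorts therefore demonstrate correctness of the estimator and the
selection logic under the model's own assumptions, not robustness to every
artifact of real RNA-seq.

## Problem sizes and test design

The test-suite and acceptance script run at deliberately modest sizes
chosen to keep the whole suite in the minutes range while leaving
Monte-Carlo error well inside the asserted tolerances: oracle equivalence
on 1,000 random instances (agreement to $10^{-10}$; observed differences
are at machine precision), type-I checks on 10–20 replicate null cohorts of
500 triplets, sensitivity on replicates of the default 520-triplet cohort,
and hazard-ratio recovery over 50–100 replicates of $n = 500$ patients.
The permutation-style check of the partial-correlation p-value uses a
parametric Monte-Carlo null (100,000 simulated null datasets) rather than
permutation of the conditioning variable, because permuting $z$ tests joint
independence from $z$ — a different null that does not converge to the
t-based p-value.

## Limitations

* The method detects *changes* in conditional correlation when one sample
  is appended to a large reference cohort; per-sample effects scale as
  $1/n$, so single-patient edge weights are small numbers whose meaning is
  relative, not absolute.
* The edge filter effectively requires a strong reference coupling
  ($|\rho| > 0.7$); triplets whose coupling *appears* in tumors but is
  absent in normals are invisible to the default pipeline
  (`use_edge_filter = FALSE` relaxes this at the cost of specificity).
* Raw p-value thresholds (0.05, 0.01) mirror the original screening
  procedure; with tens of thousands of candidate triplets they imply a
  sizeable family-wise error, which is why q-values are reported alongside.
* The Cox screen is univariate by design: no adjustment for age, stage or
  other clinical covariates, no time-varying effects.
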