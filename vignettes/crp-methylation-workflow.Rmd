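---
title: "Methods: sibship-aware EWAS of DNA methylation and serum CRP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sibship-aware EWAS of DNA methylation and serum CRP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Chronic inflammation, indexed by serum C-reactive protein (CRP), is linked
to cardiovascular and metabolic disease, and DNA methylation (DNAm) in
peripheral blood leukocytes is a plausible molecular readout of that
process.  `crpewas` implements an epigenome-wide association study (EWAS)
pipeline for Infinium-style 27K methylation arrays in a sibship-based
cohort: samples arrive in families of siblings, so observations are not
exchangeable, and array intensities carry chip- and batch-level artefacts
that must be removed before association testing.

The pipeline has six analysis stages, each exposed as package functions
and driven end to end by the scripts under `analysis/`:

1. sample quality control on the 56 control-probe features of each chip;
2. site filtering: the Hartigan–Hartigan dip test for multimodal probes,
   sex-chromosome removal, and separation of cross-reactive and
   SNP-overlapping probes;
3. control-probe principal-component normalization of the methylated and
   unmethylated signals;
4. per-site linear mixed models of ln CRP on the beta-value with a sibship
   random intercept;
5. multiple-testing control (Bonferroni and Benjamini–Hochberg),
   genomic-inflation diagnostics, and methylome-PC adjustment;
6. internal replication by splitting sibships into two mutually unrelated
   subsets, and hypergeometric gene-set over-representation.

Because the cohort that motivated this design is not publicly deposited,
the package ships a synthetic-data generator that reproduces the study's
*statistical structure*, and every stage is validated against planted
truth.

# The association model

For probe $j$ with beta-value $m_{ij}$ in individual $i$ of sibship $s(i)$:

$$\ln \mathrm{CRP}_i \;=\; \alpha + \beta_j\, m_{ij} + \gamma^T x_i +
  u_{s(i)} + \varepsilon_i, \qquad
  u_s \sim N(0, \sigma_s^2),\;\; \varepsilon_i \sim N(0, \sigma_e^2).$$

CRP is log-transformed because its distribution is strongly right-skewed.
The covariates $x_i$ are age, sex, body-mass index and current smoking
(the sensitivity variant adds hypertension status; the PC-adjusted variant
adds the top three methylome principal components).  The model is fitted
per site by REML (`lme4::lmer`), and inference on $\beta_j$ is a Wald
z-test — the natural counterpart of reporting coefficient/SE pairs.  Two
design decisions deserve note:

* **Exposure scale.** The exposure is the beta-value on its natural 0–1
  scale, so $\beta_j$ is the change in ln CRP per unit change in
  methylation fraction; coefficients of magnitude 2–4 correspond to the
  strong end of observed blood-methylation associations.  No M-value
  transform is applied.
* **Boundary fallback.** When the sibship variance is estimated at zero,
  or the mixed model cannot be fitted at all (a cohort of singletons has
  one "sibship" per observation), the site is refitted by OLS and flagged
  via `converged = FALSE` / `method = "ols"`.  OLS inference uses the
  exact t-test; on singleton cohorts the two routes agree to numerical
  precision, which the test suite checks against an independent `lm()`
  oracle.
* **Joint adjustment.** Covariates enter the same model as the exposure
  (single-stage adjustment) rather than residualizing the outcome first;
  with correlated covariates the two differ, and the joint model is the
  one whose Wald test has the stated type-I behaviour.

Continuous covariates are centred and scaled inside the fitting routine.
This leaves $\beta_j$ and its SE untouched and keeps the mixed-model
optimizer well conditioned across the very different native scales of age,
BMI and beta-values.

# The dip test

Probes whose intensity distribution is multimodal (for instance through an
underlying SNP that switches methylation fully on or off) violate the
assumptions of intensity normalization and of a linear dose effect, and
are set aside before association testing.  Multimodality is measured by
the Hartigan–Hartigan dip statistic: the smallest sup-norm distance
between the empirical CDF and any unimodal CDF,

$$D(F_n) = \min_{G \text{ unimodal}} \; \sup_x |F_n(x) - G(x)|.$$

The implementation (in C++) writes the empirical CDF in count units and
characterizes, for every candidate mode placement, the feasibility of
threading a convex-then-concave chain through the tube
$[F_n(x_k) - d,\, F_n(x_k^-) + d]$; the minimal $d$ per placement
decomposes into a convex-side term, a concave-side term (both computable
from convex hulls of the CDF points), and a monotone-join term at the
mode, and the global minimum is located by exploiting the monotonicity of
the side terms along the ordered placements.  The result is exact: the
test suite pins it, on dozens of fixtures including ties and bimodal
mixtures, against an independent linear-programming minimization over
piecewise-linear unimodal CDFs.  Useful anchors: two equal point masses
give the maximal dip 0.25, and $n$ equally spaced points give the minimal
dip $1/(2n)$.

Significance is calibrated against the uniform distribution — the
conservative choice of unimodal null — by Monte Carlo: the p-value is the
add-one-smoothed exceedance fraction among `n_boot = 2000` uniform samples
of the same size, so the smallest attainable p is
$1/2001 \approx 5\times10^{-4}$, below the flagging cutoff
$p < 0.001$.  A probe is flagged when either its methylated or its
unmethylated channel rejects (the OR rule).  One null distribution is
simulated per sample size and shared across probes.  The dip test runs on
post-sample-QC, pre-normalization intensities; the asymptotic null tables
are not used.

# Control-probe normalization

Each chip carries 56 control features measuring assay steps (staining,
hybridization, extension, bisulfite conversion, ...).  Chip- and
batch-level artefacts move target and control probes together, so the
controls act as observable surrogates of the artefacts.  The pipeline:

1. standardizes each control feature across samples and extracts principal
   components of the samples × features matrix (`orthogonalize_controls`);
   the default number of components follows the Kaiser rule (eigenvalue
   above 1 on standardized features) and is configurable;
2. regresses, per probe and per channel, $\log(y+1)$ across samples on the
   component scores and reconstructs
   $\exp(\text{residual} + \text{intercept}) - 1$ floored at zero
   (`regress_out_controls`).  The log scale matches a multiplicative
   artefact model; a linear-scale option exists.  Re-adding the intercept
   keeps every probe on its native intensity scale so beta-values remain
   interpretable;
3. computes beta-values $\beta = M/(M+U+100)$, the platform-standard
   methylation fraction with a stabilizing offset (`compute_beta`).

The regression runs per probe across samples — the only orientation in
which per-sample control scores are valid predictors.  Normalization is
idempotent up to floating error, leaves residuals orthogonal to the
scores, and on synthetic data with planted chip effects removes well over
90% of the between-chip variance component (checked by the one-way ANOVA
decomposition in the acceptance suite).

# Multiple testing and inflation

The primary threshold is Bonferroni: $\alpha/m$ nominal (e.g.
$0.05/22{,}927 = 2.18\times10^{-6}$, or $1.67\times10^{-3}$ when
re-testing 30 sites).  FDR q-values use the Benjamini–Hochberg step-up
rule via `stats::p.adjust`; the tests validate it against an independent
step-up implementation and against worked numerical examples.

Inflation is summarized by $\lambda$: each p-value is converted to a 1-df
chi-square quantile and the median is divided by the null median 0.4549.
Unmeasured confounders with methylome-wide footprints (batch effects,
cell-type composition) inflate the whole p-value distribution; adjusting
for the top three principal components of the probe-standardized beta
matrix absorbs them.  On synthetic data with a planted global confounder
the unadjusted scan inflates to $\lambda > 1.2$ and the PC-adjusted scan
returns to $1 \pm 0.05$.  Two caveats are inherited by any such
adjustment: with widespread true signal the PCs can absorb signal too
(over-correction), and $\lambda$ estimated from a few thousand tests has
a sampling SD of a few percent.

# Internal replication

Sibships make a replication design available without an external cohort:
sampling one sibling per multi-member sibship (without replacement) twice
yields two disjoint subsets in which all individuals are mutually
unrelated; singletons are divided evenly at random.  With 294 multi-member
sibships and 198 singletons each subset has exactly 393 members.  An odd
singleton is dropped (logged) to keep the subsets the same size; sibships
of three or more contribute exactly two members, one per subset.  Within a
subset, ordinary least squares with the primary covariate set is the
correct model — there is no relatedness left.  A top-$k$ hit "replicates"
in a subset when its p-value clears $\alpha/k$; the verdict per site is
`both`, `one` or `neither`, with coefficient-sign concordance reported
alongside.

# Gene-set over-representation

Significant sites map to gene symbols through the manifest (probes without
annotation drop out; genes hit twice count once).  Each term of a
user-supplied annotation (two-column TSV or GMT) is tested with the
one-sided hypergeometric upper tail
$P(X \ge k)$ for drawing the query from the background universe.  The
background defaults to all genes on the tested manifest — the array, not
the genome, is what the study sampled.  Raw p-values are reported (as is
conventional for term tables), with BH q-values alongside.  The test suite
checks the tail probabilities against brute-force enumeration of all draws
on populations up to 20.

# The synthetic-data generator

`simulate_cohort()` emulates the structure the analysis assumes.  The
defaults are the study conditions wherever these are documented, and a
single considered choice elsewhere:

* **Sibships.** 492 sibships, sizes 1–10 with mean 1.96 and 198
  singletons (`study_sibship_sizes()`).  The size composition of the 294
  multi-member sibships is not published; a fixed composition matching the
  printed totals (966 individuals, maximum size 10) is used, and the
  size-probability vector is its empirical frequency.  The motivating
  study's sibship count is reported inconsistently (492 vs 493); the
  generator takes the count as a parameter, and the helper uses 492,
  which makes the mean size come out at the reported 1.96.
* **Phenotypes.** Female fraction 0.709; age 66.1 ± 7.6 (F) / 66.7 ± 7.6
  (M) years; BMI 32.1 ± 6.6 (F) / 29.0 ± 4.8 (M) kg/m²; hypertension
  83.5% (F) / 80.1% (M).  The smoker fraction is not reported; 0.15 is a
  realistic rate for an older African-American hypertensive cohort.
* **CRP.** Generated on the ln scale: sex-specific intercepts
  $\ln 0.38$ / $\ln 0.27$ reproduce the female/male median pattern in
  mg/L; age, BMI and smoking coefficients (0.005/yr, 0.03 per kg/m²,
  0.30) are modest positive effects; sibship intercept SD 0.40 and
  residual SD 0.90 put the marginal ln-scale spread at the published
  interquartile range.  Planted methylation effects enter mean-centred,
  $\beta_j (m_{ij} - \bar m_j)$, so they shift individuals, not the
  median.  The default 30 planted coefficients span −2.2 to −4.4 —
  the magnitude range of the strongest reported associations — and give
  per-site Wald statistics around $|z| \approx 6$ at $n = 966$, matching
  the reported p-value scale.
* **Intensities.** Per-probe mean methylation is Beta(1.2, 1.8); sample
  beta-values are Beta-distributed around it with precision 50 (SD ≈
  0.07).  Total intensity is log-normal around 4000 (a typical array
  intensity scale) with probe-level SD 0.40 and sample-level SD 0.25;
  $M = T\beta$, $U = T(1-\beta)$.  Chips hold 12 samples; a chip effect
  $N(0, 0.15)$ on the log scale is shared by target and control probes —
  the minimal structure that makes control-probe normalization
  identifiable.  Note the offset in $M/(M+U+100)$ shrinks observed
  beta-values by the factor $T/(T+100) \approx 0.98$, a platform property
  that bounds how exactly planted coefficients can be recovered.
* **Multimodal probes.** Drawn from an equal mixture of Beta components
  centred at 0.15 and 0.85 (precision 200), about six within-component
  SDs apart on the log-intensity scale — the fully-switched pattern of a
  genotype-driven probe.
* **Bad samples.** 49 samples displace 8 randomly chosen control features
  by ±6 model SDs on the log scale, emulating failed hybridizations; the
  4-SD rule recovers all of them with a small number of additional
  borderline exclusions (the two-sided 4-SD false-positive rate across
  56 × 966 control values).
* **Confounder.** A latent per-sample factor loads on 30% of probes
  (loading SD 0.02) and optionally on ln CRP.  Its CRP effect defaults to
  0 because no numeric magnitude is available for the inflation observed
  in the motivating cohort; the workflow scripts switch it on (effect
  0.25) to reproduce the inflated-then-controlled QQ pattern
  qualitatively, and the acceptance suite uses 0.5 for a strong,
  unambiguous inflation signal.

All randomness flows from a single seed in the configuration; the same
configuration reproduces a byte-identical dataset, and the generator
restores the caller's RNG state.

**What the generator does not emulate:** probe-level hybridization
chemistry and dye bias, genotype-driven methylation QTLs, cell-type
composition (the real driver of much EWAS confounding appears here only
as the abstract latent factor), and missing phenotype data.  Passing
tests therefore demonstrate the statistical machinery under the assumed
model, not robustness to everything real arrays do.

# Problem sizes and numerical choices

The workflow scripts run the full cohort (966 individuals) with the probe
dimension scaled to 3,000 sites, keeping the array's proportions of
sex-chromosome, cross-reactive and SNP-overlap probes; a complete run
takes a few minutes.  The test suite uses cohorts of roughly 80–900
sibships and 150–4,000 probes, chosen so each statistical property is
measured with useful precision: type-I error over 1,000 null sites judged
against the exact binomial envelope, coefficient recovery over 200
simulated cohorts (mean-estimate SE ≈ 0.03 against a ±0.15 bias bound),
and the confounder/PC-adjustment check at 4,000 probes — at a few hundred
probes the estimated PCs begin to remove a visible share of each probe's
own variation, a small-dimension artefact the full 27.5K-probe array does
not suffer.  Dip-test nulls use 1,000–2,000 bootstrap draws.  Other
numerical choices: zero-variance control features never trigger
exclusions; constant-control matrices yield an empty PCA and an identity
normalization; p-values of exactly 0 are clipped to the smallest positive
double before the chi-square conversion (with a warning); degenerate
(constant or collinear) exposures are skipped and logged, never fatal.

# Known limitations

* Wald inference per site has no small-sample df correction; at the
  design's n ≈ 900 this is negligible, but the package should not be used
  unmodified for very small cohorts.
* The OLS fallback reports `converged = FALSE` even though the fallback
  fit itself is exact; consumers should treat the flag as "mixed model
  not used", not as "result unreliable".
* The dip test's Monte-Carlo null is shared across probes of equal sample
  size; p-values are therefore correlated across probes through the null
  draw, which is immaterial for flagging but means the flagged count has
  slightly more spread than a binomial.
* Enrichment treats terms independently; no term-hierarchy pruning of the
  kind dedicated GO tools apply is attempted.
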