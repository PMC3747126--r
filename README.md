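# crpewas

Sibship-aware epigenome-wide association analysis (EWAS) of DNA
methylation and serum C-reactive protein (CRP).

## The problem

Serum CRP is a biomarker of chronic inflammation and a cardiovascular
risk factor.  Methylation of CpG sites in peripheral blood leukocytes,
measured on Infinium-style 27K arrays as beta-values
`M / (M + U + 100)`, may carry the epigenetic footprint of inflammation.
Testing ~23,000 autosomal sites for association with CRP in a
community-based cohort of hypertensive sibships poses four statistical
problems that this package solves as one pipeline:

* **Array quality control** — samples with aberrant control-probe
  intensities (any of the 56 control features more than 4 SD from its
  mean) are excluded, and probes whose intensity distribution is
  multimodal by the Hartigan–Hartigan dip test (p < 0.001 in either
  channel, against a uniform Monte-Carlo null) are set aside, along with
  sex-chromosome probes; cross-reactive and SNP-overlapping probes are
  flagged and reported separately.
* **Batch and chip effects** — the methylated and unmethylated signals
  are regressed, probe by probe on the log scale, onto orthogonal
  principal-component summaries of the control probes.
* **Relatedness** — for each site `j`, a linear mixed model with a
  sibship random intercept:

  `lnCRP_i = a + b_j * beta_ij + g' x_i + u_s(i) + e_i`,
  `u_s ~ N(0, s_s^2)`, `e_i ~ N(0, s_e^2)`

  with covariates age, sex, BMI and current smoking (hypertension in the
  sensitivity model, methylome PCs in the inflation-adjusted model), and
  a Wald test on `b_j`.  Bonferroni (`0.05/m`) defines epigenome-wide
  significance; Benjamini–Hochberg q-values and the genomic inflation
  factor lambda complete the correction stage.
* **Replication without a second cohort** — sampling one sibling per
  multi-member sibship twice yields two disjoint subsets of mutually
  unrelated individuals (393 each for 294 multi-member sibships plus 198
  singletons), in which top hits are re-tested by ordinary regression at
  the `alpha/k` threshold.

Gene-set over-representation of the genes carrying significant sites is
tested with the exact hypergeometric upper tail against the array's gene
universe.

Because the motivating cohort is not publicly deposited, the package
includes a first-class synthetic-data generator (`simulate_cohort()`)
that reproduces the study's structure — 492 sibships averaging 1.96
siblings, the published phenotype distributions, log-normal CRP with
sex-specific medians, planted negative methylation effects, planted
multimodal probes and planted low-quality samples — so the whole pipeline
is testable against known truth.

## Worked example

```r
library(crpewas)

cfg <- sim_config(n_sibships = 120, n_probes = 400, seed = 42)
ds  <- simulate_cohort(cfg)

qc   <- run_qc(ds$intensities, ds$controls, ds$manifest, seed = 7)
pca  <- orthogonalize_controls(ds$controls[, qc$kept_samples])
beta <- compute_beta(regress_out_controls(qc$intensities, pca))

cohort <- ds$cohort[ds$cohort$sample_id %in% qc$kept_samples, ]
ewas <- annotate_qvalues(run_ewas(beta, cohort, verbose = FALSE))
head(ewas[order(ewas$p_value), c("probe_id", "coefficient", "se", "p_value")])
genomic_inflation(ewas$p_value)$lambda
```

```
      probe_id coefficient       se      p_value
142 cg00000152   -5.822799 1.328263 0.0000116644
26  cg00000028   -5.268444 1.376110 0.0001289244
50  cg00000053    5.076596 1.422833 0.0003597853
103 cg00000111   -7.746207 2.201457 0.0005432874
1   cg00000001   -5.966684 1.823296 0.0010661185
368 cg00000386   -5.012792 1.545633 0.0011819618
[1] 1.422832
```

Negative coefficients mean lower methylation with higher CRP, in units of
lnCRP per unit beta-value; most of the top sites here are planted effects
recovered from the synthetic truth (`truth_report(ds)`).  The inflation
factor sits well above 1 because 30 of these 400 sites carry genuine
signal — the same widespread-association pattern that motivates the
methylome-PC-adjusted secondary analysis (`methylome_pca()` +
`model_spec(pc_scores = ...)`).  The full analysis — simulation at study scale,
QC, normalization, the primary and PC-adjusted scans, internal
replication of the top 30 sites, and enrichment — is scripted as
`analysis/01_simulate.R` … `analysis/07_enrich.R` (run them in order from
the repository root); summary tables land in `results/`.

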