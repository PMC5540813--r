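# asymmeta

Multi-site meta-analysis and pedigree heritability of brain volumetric
asymmetry.

## What this is for

Left–right volume differences of bilaterally paired brain structures
(nucleus accumbens, amygdala, caudate nucleus, globus pallidus,
hippocampus, putamen, thalamus) are small — mean asymmetry indices of a
percent or two — and effects of sex, age and handedness on them are smaller
still. Detecting them requires pooling dozens of imaging sites, but sites
cannot share subject-level data. `asymmeta` implements the federated
two-level protocol used for this problem: every site computes harmonized
summary statistics on its own subjects, and only the summaries are
combined by random-effects meta-analysis. It is aimed at consortium
analysts running the within-site stage, the pooling stage, or both, and at
methodologists who want the whole protocol reproducible on synthetic data.

## The statistics at its core

The asymmetry index of a structure with left/right volumes *L*, *R* is

    AI = (L − R) / (L + R)  ∈ [−1, 1],

positive when the left side is larger. Per site, `site_summary()` applies
an adaptive outlier rule (±2.5, 3 or 3.5 SD depending on sample size),
residualises AIs on age and ICV, and produces Welch sex/handedness
contrasts, ANCOVA per-year age coefficients, and one-sample lateralization
tests per sex. `meta_analyze()` filters datasets (≥ 15 per group; ≥ 5-year
age IQR for age effects), reconstructs standard errors from CI + Welch df,
and pools by DerSimonian–Laird:

    w_i = 1/se_i²,  Q = Σ w_i (y_i − ȳ_w)²,
    τ² = max(0, (Q − (k−1)) / (Σw − Σw²/Σw)),
    pooled = Σ y_i/(se_i²+τ²) / Σ 1/(se_i²+τ²)

with Cochran's Q, Higgins' I² = max(0, (Q−(k−1))/Q)·100, and Rosenberg's
weighted fail-safe N at α = 0.007. `ai_heterogeneity()` partitions pooled
AI variance into between-dataset and between-software-version η² shares.
`fit_univariate_vc()` / `fit_bivariate_vc()` estimate heritability
h² = σ²_g/(σ²_g+σ²_e) and the left–right genetic correlation ρ_g on
extended pedigrees via the eigenrotated multivariate-normal likelihood
(covariance σ²_g·2Φ + σ²_e·I, boundary LRTs with the ½χ²₀+½χ²₁ mixture).
`generate_multisite()` and `generate_pedigrees()` provide a fully seeded
synthetic world at consortium-scale effect sizes so everything is testable
without data access.

## Worked example

```r
library(asymmeta)
cfg  <- sim_config(seed = 11)                 # 52-site synthetic consortium
tabs <- generate_multisite(cfg)               # ~19,000 subjects
res  <- run_pipeline(run_config(tabs, seed = 11))
res$meta$sex[, c("structure","pooled","se","p","Q","I2","k","failsafe_n")]
```

```
    structure    pooled       se        p    Q    I2  k failsafe_n
1   accumbens  0.001281 0.001096 2.43e-01 38.5  0.00 52          0
2    amygdala  0.000617 0.000734 4.01e-01 48.0  0.00 51          0
3     caudate -0.000163 0.000357 6.48e-01 54.2  5.86 52          0
4    pallidum  0.003497 0.000726 1.43e-06 37.3  0.00 52        115
5 hippocampus  0.000633 0.000503 2.08e-01 74.0 31.05 52          0
6     putamen -0.002543 0.000396 1.36e-10 33.2  0.00 52        243
7    thalamus -0.001081 0.000447 1.56e-02 55.4  7.91 52          0
```

Reading this: the pooled male−female difference in residualised putamen AI
is −0.0025 (males shifted rightward relative to females), significant far
beyond the Bonferroni threshold of 0.007, with no between-site
heterogeneity (I² = 0) and 243 average-weight null sites needed to undo
it; the globus pallidus shows the opposite, leftward-in-males shift
(+0.0035). These are exactly the two sex effects the synthetic world
carries, at their configured magnitudes (−0.002 and +0.004); the remaining
structures' effects are an order of magnitude smaller and stay
non-significant. `res$heterogeneity` reproduces the configured
between-dataset variance shares (η² lowest for putamen and hippocampus),
and `res$heritability` appears when a pedigree and phenotypes are passed to
`run_config()`.

A thin CLI wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","asymmeta.R",package="asymmeta"))') \
    simulate --seed 7 --n-sites 4 --out-dir sim/
```

with subcommands `simulate`, `site-stats`, `meta`, `variance`,
`heritability`, `run-all`.

## Acceptance script

`scripts/acceptance.R` recomputes, from scratch against the installed
package: Higgins' I² for the amygdala and putamen sex meta-analyses from
their printed Cochran's Q and dataset counts, and Monte-Carlo recovery of
the putamen AI heritability (h² = 0.27) and of the left–right putamen
genetic correlation (ρ_g = 0.899, ρ_e = 0.58) on simulated 71-family
extended pedigrees (20 replicate fits each). Run it from the repository
root:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The JSON maps each target id to the recomputed value and the problem size
used.
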