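---
title: "Methods: multi-site asymmetry meta-analysis and pedigree heritability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-site asymmetry meta-analysis and pedigree heritability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asymmeta)
```

## The problem

Volumetric asymmetries of bilaterally paired brain structures — nucleus
accumbens, amygdala, caudate nucleus, globus pallidus, hippocampus, putamen
and thalamus — are subtle (mean asymmetry indices on the order of 1–2 % of
bilateral volume) and their association with sex, age and handedness cannot
be established in single samples of typical size. The design this package
implements is a *federated two-level analysis*: many imaging sites each
compute summary statistics on their own subjects with one shared protocol,
and only those summaries are pooled by random-effects meta-analysis. No
subject-level data cross the site boundary; `run_pipeline()` enforces the
same boundary internally by processing every site independently.

The asymmetry index of a structure with left and right volumes $L$ and $R$
is

$$AI = \frac{L - R}{L + R} \in [-1, 1],$$

positive when the left structure is larger. It is dimensionless, so sites
with different scanners and head-size distributions become comparable after
covariate adjustment.

## Within-site stage

For each site and structure, `site_summary()`:

1. computes AIs for subjects with both volumes present ($L + R > 0$);
2. excludes outliers with an adaptive SD rule: values further than
   $k \cdot SD$ from the mean are dropped, where $k$ depends on the site's
   sample size ($N < 150 \Rightarrow k = 2.5$;
   $150 \le N \le 1000 \Rightarrow k = 3$; $N > 1000 \Rightarrow k = 3.5$).
   The rule is applied jointly to the left volume, the right volume and the
   AI; a subject is dropped for that structure if any of the three flags it.
   The mean and SD are computed once (a single, non-iterative pass), since
   an iterated rule would change the stated threshold semantics;
3. residualises AIs on age and ICV (and sex for handedness contrasts) by
   OLS, then runs Welch two-sample tests (Satterthwaite degrees of freedom)
   for the male−female and left−right-hander contrasts;
4. estimates the per-year age coefficient by ANCOVA (`AI ~ age + sex +
   ICV`);
5. runs one-sample $t$-tests of mean AI against zero, separately per sex,
   on the *raw* (non-residualised) AIs. Whether population-level
   lateralization should use adjusted AIs is genuinely open; raw AIs are
   used because the quantity of interest is the population mean itself, and
   this choice is flagged here.

Sign conventions are fixed: sex contrasts are male minus female, handedness
contrasts left- minus right-handers. All tests are two-sided. Subjects with
a missing structure are dropped per structure, not listwise.

The ordering — exclusion on raw volumes and AIs first, residualisation
second — is fixed and deliberate: the outlier rule is a data-quality screen
on the measured quantities, not on model residuals, so it must not depend
on which covariates a later contrast happens to use.

## Site-to-meta boundary

Sex and handedness effects travel as mean difference + 95 % CI + Welch
degrees of freedom; the pooling stage reconstructs the standard error as
$se = (\text{upper} - \text{lower}) / (2\, t_{0.975,\,df})$
(`se_from_ci()`). Age coefficients travel with their own SEs. This
reconstruction is exact for $t$-based intervals and is tested as a
round-trip.

## Meta-analysis stage

Datasets enter a contrast's meta-analysis only if every group involved has
at least 15 observations; the age analysis additionally requires the site's
age interquartile range to span at least 5 years, because a per-year linear
coefficient estimated on a nearly age-homogeneous sample is noise.
Boundaries are inclusive (15 and 5.0 qualify).

`random_effects_pool()` implements DerSimonian–Laird pooling: fixed-effect
weights $w_i = 1/se_i^2$, Cochran's $Q = \sum_i w_i (y_i - \bar y_w)^2$,
moment estimator
$\tau^2 = \max\!\big(0, (Q - (k-1)) / (\textstyle\sum w - \sum w^2 / \sum w)\big)$,
random-effects weights $w_i^* = 1/(se_i^2 + \tau^2)$. Design choices made
here, where several defensible conventions exist:

* **$\tau^2$ estimator** — DerSimonian–Laird, the classical random-effects
  default; it reproduces $I^2 = 0$ exactly wherever $Q$ falls below its
  degrees of freedom, which matters for consistency with printed
  heterogeneity columns.
* **$I^2$** — computed from $Q$ and $k$ as
  $\max(0, (Q - (k-1))/Q) \times 100$, not from $\tau^2$ over a typical
  within-study variance; the two differ in general and only the $Q$-based
  form yields the printed zeros.
* **Pooled $p$-value** — normal approximation on $z = \hat\mu/se$, not a
  $t$ on $k - 1$ df. With $k \ge 35$ datasets the two are nearly
  indistinguishable; $z$ is the default and documented.
* **Fail-safe N** — Rosenberg's weighted formulation: the smallest integer
  number of hypothetical null studies, each carrying the *mean observed
  fixed-effect weight* and effect zero, whose addition lifts the pooled
  fixed-effect two-sided $p$ to the chosen $\alpha$ (0.007 by default). A
  closed-form bound is used and then verified by direct evaluation at the
  boundary, so the result equals a brute-force incremental search by
  construction; the brute-force definition is normative and is what the
  tests assert against.
* **Significance threshold** — $\alpha = 0.05/7$ for the seven structures,
  conventionally reported as 0.007; the fail-safe default uses 0.007
  itself, matching how the threshold is stated where fail-safe counts are
  reported.

The post-hoc `weighted_meta_regression()` regresses per-site age
coefficients on per-site median ages, weighting by $\sqrt{n}$, to detect
age effects that change across the lifespan.

## Variance partitioning

`ai_heterogeneity()` quantifies how much of the pooled AI variance is
attributable to "dataset" and to "segmentation-software version" as one-way
$\eta^2 = SS_{between}/SS_{total}$ per factor, main effects only: each site
runs exactly one software version, so the two factors are confounded and no
interaction (or joint Type-II decomposition) is estimable. The pooled
vector is the post-exclusion, *non-residualised* AI. The reported
$\sigma^2_{within}$ is the within-group ANOVA mean square
$SS_{within}/(N-k)$ — i.e. average AI variability after removing dataset
mean differences; "total variance minus between-dataset SS" divided by
$N-1$ would be a slightly different quantity, and the mean-square reading
is documented here as the package's convention.

## Heritability stage

The polygenic model takes phenotypes multivariate normal with covariance
$\sigma^2_g K + \sigma^2_e I$, where $K = 2\Phi$ is the additive
relationship matrix built by the recursive tabular method
(`kinship_from_pedigree()`). Since $K$ is block-diagonal by family, each
family block is eigendecomposed once; rotating data onto the eigenbasis
turns the likelihood into a product of independent normals, and the fit is
a 1-D profile optimisation over $h^2 = \sigma^2_g/(\sigma^2_g+\sigma^2_e)$
with fixed effects profiled out by GLS and the scale variance in closed
form. Choices:

* **ML, not REML** — the exact scheme of classical variance-component
  software is not uniquely specified; ML is simpler, and with $n \approx
  1200$ and 4 fixed-effect parameters the REML bias correction is
  negligible relative to the Monte-Carlo error the acceptance checks
  tolerate.
* **Boundary tests** — $h^2 = 0$ and $\rho_g = 1$ sit on the edge of the
  parameter space, so likelihood-ratio $p$-values use the 50:50
  $\chi^2_0{:}\chi^2_1$ mixture, reported as
  $p = \tfrac12 P(\chi^2_1 \ge LR)$ (equal to 0.5 when the estimate is at
  the boundary) — the convention of standard pedigree-analysis software.
* **Flat likelihoods** — with no family structure ($K = I$) the model is
  unidentified; near-ties in the profile likelihood resolve to the smallest
  $h^2$, so uninformative data land on the null boundary instead of an
  arbitrary interior point.
* **Bivariate fits** — covariance $G \otimes K + E \otimes I$ with $2
  \times 2$ genetic and environmental matrices. After the same rotation the
  likelihood factorises into per-individual $2 \times 2$ normals, vectorised
  in closed form. Correlations are parameterised through $\tanh$ and
  variances through $\exp$, so every iterate is automatically positive
  definite (nothing needs to be projected back to the PSD cone); the
  boundary $\rho_g = 1$ is handled by a constrained refit rather than by the
  unconstrained parameterisation. Optimisation is Nelder–Mead from
  univariate-fit starting values; the standard error of $\rho_g$ comes from
  the numerical Hessian with a $\tanh$ delta-method correction.
* **Transformations** — phenotypes are standardised internally for
  conditioning and estimates returned on the original scale; no
  inverse-normal transform is applied by default because none is stated in
  the protocol being emulated.

`cross_ai_correlations()` runs the 21 pairwise bivariate fits across the
seven AIs and reports uncorrected $p$-values, matching how exploratory
cross-trait screens are reported.

## The synthetic world

No consortium subject-level data are distributable, so
`generate_multisite()` and `generate_pedigrees()` generate data with the
statistical structure the analysis assumes. The generator's defaults *are*
the stated world and are not tuned:

* per-structure mean AIs and within-dataset variances, sex effects and age
  effects are the consortium-scale reference values in
  `reference_effects()`;
* site offsets are Normal with SD
  $\sqrt{\sigma^2_{within}\,\eta^2_{ds}/(1-\eta^2_{ds})}$ so the
  between-dataset variance share matches the reference $\eta^2$ column —
  the offsets' magnitudes themselves are nowhere printed, so this
  calibration *from* the printed shares is the one free choice, made once;
* version offsets are fixed per label with one version per site (a 75/25
  split across two labels, mirroring the predominance of a single
  segmentation version), sized analogously from $\eta^2_{version}$;
* sex is effect-coded ($\pm\gamma/2$) and age centred at the site's
  mid-range, so the male−female difference equals $\gamma$ and the
  per-site mean AI stays at $\mu$ + offsets, which keeps the generator's
  convergence contract exact;
* handedness is Bernoulli(0.1 left) independent of AI, matching the null
  handedness findings being emulated;
* ICV is log-normal around $1.5 \times 10^6$ mm³; each structure's total
  bilateral volume is linear in ICV (60 % ICV-tied) with 8 % residual
  spread — a realistic covariate structure for residualisation tests, not a
  claim about anatomy; the split $L = T(1+AI)/2$, $R = T(1-AI)/2$ makes AI
  recovery exact to machine precision;
* AI noise is Gaussian: only means and variances of the AI distributions
  are available, and a Gaussian is the maximum-entropy choice under those
  constraints;
* pedigrees use a fixed template (founder couple → 3 married children → 3
  grandchildren each: 17 individuals; 71 families ≈ 1200 individuals,
  emulating a large family study of ~1170 subjects in 71 extended
  pedigrees) rather than random mating graphs, for reproducibility and
  hand-checkable kinship; genetic values are drawn through the Cholesky
  factor of each family's $2\Phi$, giving covariance exactly
  $h^2\sigma^2 \cdot 2\Phi$ (bivariate: $G \otimes 2\Phi$). The bivariate
  volume simulation for the genetic-correlation check uses trait
  heritabilities equal to the putamen AI value (0.27), keeping the whole
  check inside the same stated world; the printed table does not give the
  left/right volume heritabilities themselves.

What a green test on this world does **not** establish: robustness to
non-Gaussian AI noise, site-specific variance differences, informative
missingness, scanner drift within site, or real segmentation error — none
of which the generator emulates (only optional per-structure missingness
via absent volumes is representable in the schema).

## Numerical and degenerate-input conventions

* Outlier pass with zero variance keeps everything; missing values are
  never flagged as outliers (missingness is handled per structure).
* `welch_test()` refuses two zero-variance groups; `residualize()` names
  the collinear columns on rank deficiency.
* `higgins_i2()` returns 0 at $Q = 0$; `rosenberg_failsafe()` returns 0
  when the pooled $p$ is already non-significant.
* Variance-component optimisation reports boundary estimates
  (`boundary = TRUE`) rather than hiding them; eigenvalues of kinship
  blocks are clipped at 0 against $-10^{-8}$-scale round-off.
* All simulation is seeded; identical config + seed is bit-identical, and
  the full pipeline is reproducible end to end.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 11)            # 52-site default world
tabs <- generate_multisite(cfg)
res <- run_pipeline(run_config(tabs, seed = 11))
res$meta$sex[res$meta$sex$structure %in% c("pallidum", "putamen"), ]
```

On this seed the putamen male−female pooled difference is −0.0025
(SE 4.0e-4, $p < 10^{-9}$, $I^2 = 0$) and the globus pallidus +0.0035
(SE 7.3e-4, $p < 10^{-5}$) — the two sex effects the world was configured
to carry, with rightward putamen shift in males and leftward pallidus
shift, and fail-safe counts in the hundreds. See the README for the full
printed output.

## Known limitations

* Handedness contrasts need sites with ≥ 15 left-handers; small simulated
  worlds often have none, and the pipeline then stops with the filter
  named rather than silently pooling nothing.
* The bivariate optimiser is derivative-free; pathological starting values
  could in principle converge locally, though the univariate-informed
  starts have not shown this in testing.
* Heritability SEs come from profile curvature / numerical Hessians;
  near boundaries they are approximations and flagged as such.
* The meta stage assumes effects and SEs are finite and positive; sites
  whose contrasts are inestimable (degenerate groups) are dropped with
  their fields set to NA at the site stage.
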