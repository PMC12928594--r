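# momentdiff

Effect sizes for two-group differences in **skewness**, **kurtosis**, and
**correlation** — with sampling variances, so they can be meta-analyzed.

Group comparisons in biology and medicine (males vs females, treated vs
control, two strains) usually stop at the mean, sometimes at the variance.
But groups can also differ in the *shape* of a trait's distribution and in
how tightly two traits covary, and those differences carry biological signal:
asymmetric trait distributions bias heritability estimates, tail weight
reflects the prevalence of extreme phenotypes, and sex-specific trait
correlations can indicate sex-specific risk structure. `momentdiff` is for
meta-analysts and quantitative biologists who want to quantify these
differences with proper uncertainty, pool them across strata or studies, and
evaluate how the estimators behave before trusting them.

The three statistics, with group 1 minus group 2 throughout:

- **Δsk** = *sk*₁ − *sk*₂, the difference in small-sample-corrected sample
  skewness *sk* = (m₃/m₂^{3/2})·√(n(n−1))/(n−2), with analytic sampling
  variance s² = s²₁ + s²₂ − 2ρ s₁s₂ where s²ᵢ = 6nᵢ(nᵢ−1)/[(nᵢ−2)(nᵢ+1)(nᵢ+3)];
- **Δku** = *ku*₁ − *ku*₂, the difference in small-sample-corrected *excess*
  kurtosis (G2; 0 for a normal population), per-group variance
  24n(n−1)²/[(n−3)(n−2)(n+3)(n+5)];
- **ΔZr** = *Zr*₁ − *Zr*₂, the difference in Fisher-transformed within-group
  correlations *Zr* = atanh(r), per-group variance 1/(n−3).

Because the analytic variances assume normality, each contrast can instead
carry a pooled per-group **delete-1 jackknife** variance (and a
bias-corrected jackknife point estimate); the defaults pair analytic points
with jackknife variances for Δsk/Δku and analytic variances for ΔZr, the
combinations that perform best in Monte-Carlo evaluation. Companion lnRR
(log response ratio) and lnVR (log variance ratio) cover mean and
variability contrasts so one dataset yields a full distributional profile.

The package also ships the infrastructure around the statistics: a
moment-parameterized **Pearson-system sampler** (all types I–VII), a seeded
**simulation engine** for bias / relative variance bias / coverage over
scenario grids, a **random-effects meta-analysis layer** (REML via metafor
with crossed random factors; effective-sample-size weighting for Δku, whose
sampling variance is unreliable), a long-format ingestion + per-stratum
pipeline, and a synthetic multi-center fixture generator with known truths.

## Worked example

Six center × strain strata of a synthetic mouse phenotyping dataset, 500
males and 500 females each, where females truly have the stronger fat-mass /
heart-weight correlation (r = 0.6 vs 0.4):

```r
library(momentdiff)

fx <- generate_fixture(fixture_config(), seed = 42)
st <- read_study_table(fx$table, group_col = "sex",
                       trait_cols = c("fat_mass", "heart_weight"),
                       stratum_cols = c("center", "strain"))
eff <- effect_table(st, types = "dzr", group_order = c("male", "female"))
head(eff[, 1:6], 3)
#>   effect_kind                 trait estimate sampling_variance  n1  n2
#> 1    delta_zr fat_mass+heart_weight   -0.293           0.00402 500 500
#> 2    delta_zr fat_mass+heart_weight   -0.207           0.00402 500 500
#> 3    delta_zr fat_mass+heart_weight   -0.310           0.00402 500 500

random_effects_meta(eff, random_factors = c("center", "strain"))
#> Random-effects meta-analysis of delta_zr (k = 6, inverse_variance weighting)
#>   pooled = -0.2658 (SE 0.0259), 95% CI -0.3165 to -0.2150
#>   heterogeneity: center: tau2 7.585e-12 (I2 0.0%); strain: tau2 2.804e-14 (I2 0.0%);
#>   effect_id: tau2 9.268e-15 (I2 0.0%); I2 total 0.0%
```

One ΔZr per stratum (male − female; negative means the correlation is weaker
in males), each with variance 2/(n−3) ≈ 0.004. The pooled estimate −0.266
(CI −0.316 to −0.215) recovers the configured truth atanh(0.4) − atanh(0.6) =
−0.269, and I² ≈ 0 because the fixture's strata share one true effect.

A single shape contrast from raw data:

```r
set.seed(1)
g_m <- group_sample(sample_pearson(500, moment_target(10, 4, 0.8, 3.2)), label = "male")
g_f <- group_sample(sample_pearson(500, moment_target(10, 4, 0.3, 3.2)), label = "female")
delta_skewness(g_m, g_f)
#> delta_sk = 0.6371 (95% CI 0.4084 to 0.8659), sampling variance 0.013621
#>   male (n = 500) vs female (n = 500); point: analytic, variance: jackknife
```

The interval comfortably covers the true skewness difference of 0.5. Effects
computed only from *reported* summaries work too:
`effect_from_summaries("delta_zr", r1 = 0.5, r2 = 0.3, n1 = 103, n2 = 53)`.

A thin command-line wrapper over the same pipelines is installed at
`inst/cli/momentdiff` (subcommands `effect`, `meta`, `simulate`, `fixture`).
See `vignettes/momentdiff-methods.Rmd` for the estimators, the simulation
design, and the numerical choices.

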