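---
title: "Statistical methods and design of wgbsqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods and design of wgbsqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette documents the generative model behind the synthetic cohorts,
the statistical method implemented by each module, the numerical choices that
affect results, and the design decisions and problem sizes the package is
built around. Code chunks are illustrative and not evaluated when the
vignette is built.

# 1. The generative model

`sim_config()` bundles every knob of the generator; its defaults *are* the
study conditions used throughout the tests and the acceptance script, chosen
to reproduce the statistical texture of a deep WGBS brain cohort:

* **Cohort**: 165 donors, 500 SNPs in AR(1) LD blocks of 10
  (`ld_rho = 0.9`), 5 000 CpG and 500 CpH sites on a single 500 kb synthetic
  chromosome.
* **Baseline methylation** is a three-class mixture — 78% of CpGs highly
  methylated (> 0.8), 14% intermediate, 8% low (< 0.2) — giving the bimodal
  marginal distribution characteristic of somatic CpG methylation. CpH sites
  are generated near zero.
* **Coverage** is zero-truncated Poisson with mean 17.3 reads per site;
  methylated counts are Binomial(coverage, true fraction).
* **cis-meQTL effects**: 20% of SNPs carry an effect; each affected SNP
  perturbs all CpGs inside a window of mean width 14.5 kb by a per-allele
  shift with mean absolute size 0.026 (2.6 percentage points of
  methylation). CpH effects are sparse (10% of in-window sites respond) but
  large (mean 0.27/allele), mimicking the few strong CpH-meQTLs reported in
  neurons. Injected pairs are recorded in `truth$pair_effects`, so recovery
  can be scored exactly.
* **Covariate structure**: batch (10% of non-genetic variance), neuronal
  fraction (per-site slopes, SD 0.02), age (10% of sites with a trend, 94%
  gaining methylation with age, per-decade slope SD 0.005), sex, diagnosis,
  and three ancestry MDS coordinates. Sample-by-region co-methylation noise
  (SD 0.015 over 20 kb blocks) makes neighboring sites covary the way real
  methylomes do, rather than site-by-site.

## Realism and limits

The generator is a *statistical* mimic, not a biological one. Its known
limits:

* A single chromosome, uniform site spacing distribution, and no CpG
  islands/shores; smoothing behavior at island boundaries is therefore not
  exercised.
* Effects are purely additive on the fraction scale and clipped to [0, 1];
  real meQTLs can be dominant or interact with cell type.
* LD is block-diagonal AR(1); there is no long-range LD, so index-SNP
  pruning is easier than in real data.
* At toy scale (tens of samples, a few hundred sites) the leading
  methylation principal components absorb a large share of the *injected
  genetic* signal, not just technical structure — with 500 SNPs on 500 kb
  nearly every site sits in some effect window. Adjusting a scan for
  methylation PCs at these sizes therefore costs real power, which is why
  the worked examples and the acceptance script adjust for the *known
  simulated* covariates (`~ batch + neuronal_fraction + age + sex`) instead
  of estimated PCs. `variance_components()` is still useful at toy scale to
  see which known factors each PC tracks.
* Coverage is independent of methylation state; real WGBS shows mild
  coverage biases in CpG-dense regions.

# 2. Methylome smoothing

`smooth_methylome()` implements a BSmooth-style coverage-weighted local
linear smoother. For each site, a window is grown symmetrically to the
nearest-neighbor minimax half-width that captures at least 70 sites, floored
at half of `min_width = 2000` bp. Within the window, the raw fractions are
fit by weighted least squares on position with weights
`tricube(d/h) * coverage`, where the tricube denominator is `h * 1.0001` so
the boundary sites retain a strictly positive weight. Numerical properties
relied on by the tests:

* A constant methylome is an exact fixed point of the smoother.
* On smooth truth (e.g. a sigmoid) at 17× coverage the smoother reduces mean
  squared error versus raw fractions by ~25-fold (the acceptance script
  reports this as `smoothing_mse_ratio`).

# 3. cis-meQTL scanning

`meqtl_scan()` tests every SNP–site pair within `window` bp. Covariates are
removed once from both the smoothed methylation matrix and each dosage vector
by projecting out `Q` from the QR decomposition of `[1, C]`
(Frisch–Waugh–Lovell), after which the per-pair slope, SE, and t follow from
vectorized cross-products with residual degrees of freedom `n − k − 1`.
P-values are two-sided t and floored at `.Machine$double.xmin` to keep
`log(p)` finite. `fdr_pvalue_cutoff()` converts a Benjamini–Hochberg step-up
at level `q` into an equivalent p-value threshold against the *total* number
of tests `m_total` (which may exceed the number of returned pairs when a
scan is chunked), so downstream files need only a single cutoff.
`index_snp_scan()` picks the most significant SNP per site and labels
cis/trans; `interaction_scan()` adds a SNP × modifier product term and tests
its coefficient.

Calibration at null: with `meqtl_fraction = 0`, 200 samples and 5 000 sites,
the fraction of p < 0.05 is 0.048–0.058 across seeds (tests assert this with
LD-block-clustered standard errors, since pairs sharing an LD block are
correlated), and a BH cutoff at q = 0.01 yields zero discoveries.

# 4. gDMRs

`cluster_sites()` groups significant same-SNP sites into runs broken at
position gaps > `maxgap = 1000` bp; `find_gdmrs()` additionally breaks runs
at sign changes of the t-statistic and keeps runs with at least
`min_sites = 2` sites. The strict (|t| ≥ 5) regions are provably nested
inside the liberal (|t| ≥ 3.5) regions, a property the tests verify on
hundreds of random instances against an exhaustive run-enumeration oracle.
`classify_region()`/`overlap_regions()` use inclusive interval arithmetic
(abutting regions overlap).

# 5. Sharing, mediation, moderated t

* `storey_pi0()` estimates π0 by the λ-grid estimator with a natural-spline
  smoother evaluated at max λ (the `"fixed"` method uses a single λ);
  estimates are clamped to [0, 1] and π1 = 1 − π0. `pi1_sharing()` matches
  discovery pairs into a replication scan by (snp_id, site_idx) key and
  reports π1 of the matched p-values.
* `mediation_fit()` regresses expression on dosage with and without
  methylation; the proportion mediated is `1 − β_adjusted / β_marginal`.
  Fits with `|β_marginal|` below `beta_floor = 1e-6`, or attenuation outside
  sensible bounds, are flagged `unstable` rather than silently reported —
  exact orthogonality or sign flips otherwise produce wild ratios.
* `fit_site_models()` + `ebayes_moderate()` implement limma-style moderated
  t: the prior `(d0, s0²)` is recovered by moment matching on `log s²`
  using digamma/trigamma identities, with `trigamma_inverse()` solved by
  Newton iteration. When the observed spread of `log s²` is at or below the
  sampling-only expectation, the prior degenerates to a point mass
  (`d0 = Inf`, `s0² = exp(mean(log s²))`) and moderated t equals ordinary t
  scaled to the common variance. Moment recovery of `(d0 = 4, s0² = 0.01)`
  at 1 000 sites is accurate to a few percent on average.

# 6. Heritability and stratified LD-score regression

`compute_grm()` builds the GRM from standardized dosages (monomorphic SNPs
skipped). `reml_h2()` profiles the restricted likelihood on the spectral
decomposition of the covariate-projected GRM and optimizes h² on [0, 1];
the boundary test uses the 50:50 χ²₀/χ²₁ mixture. Two numerical facts shape
both code and tests:

* A standardized-dosage GRM annihilates the constant vector (`A %*% 1 = 0`),
  so dense solves at h² = 1 are singular — the spectral profile handles the
  boundary, but brute-force oracles must stay on [0, 0.99].
* With a rank-deficient GRM (fewer SNPs than samples) and a noiseless
  genetic trait, the restricted likelihood diverges at the boundary; the
  estimator correctly returns h² → 1 with a significant boundary test.

`ld_scores()` computes annotation-stratified LD scores
`ℓ_{j,c} = Σ r²_adj` over a position window, with the small-sample
adjustment `r²_adj = r² − (1 − r²)/(n − 2)`. `stratified_regression()` fits
χ² on `[1, N·ℓ]` by WLS with weights `1/(2 max(ℓ_full, 1)²)` and reports
per-annotation τ, heritability shares, and enrichment with block-jackknife
standard errors.

Identifiability note: if SNPs are mutually uncorrelated, every LD score is
≈ 1 and the ℓ columns are collinear with the intercept — τ is then
unidentifiable. Meaningful simulations (and the tests and acceptance script)
therefore use LD blocks of *varying* size (1–20 SNPs) so the LD scores have
spread. Jackknife note: with 50 blocks and t(49) quantiles, CIs for the
causal-annotation τ and for enrichment achieve ~93–94% empirical coverage
at the simulated sizes, while the baseline-annotation τ interval is
anticonservative (~86–88%) because its weighted estimator is heavy-tailed;
the tests assert coverage only where the jackknife is adequate. Enrichment
of the all-SNP annotation is identically 1 by construction, a useful
invariant the tests check to machine precision. The ratio estimator of
enrichment also carries a small-m Jensen bias under χ²(1) noise, so
mean-enrichment assertions use a 25% band rather than Monte-Carlo-SE bands.

# 7. Pipeline and determinism

`run_pipeline()` consumes a validated config (see
`validate_pipeline_config()`; YAML via `read_pipeline_config()`) and writes
genotypes (VCF), per-sample Bismark-style coverage files, covariates, the
significant-pair table, gDMR BED files at t-cutoffs 5 and 3.5, a resolved
config, `counts.json`, and `manifest.tsv` with MD5 checksums of every other
file. All randomness derives from the single config seed, so two runs with
the same config produce byte-identical data files (the resolved config
differs only if `out_dir` differs). Stages can be disabled individually.

# 8. Problem sizes and runtime

The package targets desk scale: the default cohort
(165 × 500 SNPs × 5 500 sites) simulates, smooths, and scans
(~215 000 pairs) in well under a minute on one core; the full test suite —
about 5 500 assertions including brute-force oracle comparisons for the
regression, GRM, LD-score, gDMR, ANOVA, and REML cores — runs in ~1.5
minutes; `scripts/acceptance.R` in ~1 minute. Memory stays below a few
hundred MB throughout. Scaling to genome scale would require chunked scans
(supported via `m_total` in `fdr_pvalue_cutoff()`) and out-of-core
methylation storage, which are out of scope.

# 9. Design decisions

* **Tibble-native surface.** Every analysis returns a tibble (plus class
  attributes); `generics::tidy()`/`glance()` and `ggplot2::autoplot()`
  methods cover the main result types. Vectors entering tibble columns are
  explicitly unnamed — named scalars from `coef(...)["x"]`-style indexing
  otherwise leak element names into columns.
* **Oracles over fixtures.** Tests compare the vectorized implementations to
  deliberately naive re-implementations (explicit normal equations, double
  loops, exhaustive run enumeration, dense-solve REML) on random instances,
  rather than to stored numbers, so they check the mathematics, not a
  snapshot.
* **Honest Monte-Carlo tolerances.** Stochastic assertions use standard
  errors measured from the actual sampling design — including LD-block
  clustering for correlated test fractions — with bands fixed in advance of
  the final test runs.
* **Fail loudly.** Degenerate inputs (constant modifiers, collinear
  annotations, all-monomorphic genotype sets, rank-deficient designs) raise
  errors or set explicit flags (`skip`, `unstable`) instead of returning
  plausible-looking numbers.
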