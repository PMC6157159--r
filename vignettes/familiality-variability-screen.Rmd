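---
title: "Screening for treatment-responsive CpG sites by familiality and variability outliers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for treatment-responsive CpG sites by familiality and variability outliers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the indirect design

Longitudinal drug-methylation studies would ideally test each CpG site by
the within-individual difference between pre- and post-treatment beta
values. When the two phases are measured in separate batches with no shared
samples or untreated controls, that direct contrast is confounded: any
per-site shift could be batch. `famvar` implements an indirect screen for
sites whose methylation acquires a *genetic* response to treatment. The
reasoning: if treatment changes the activity of transcription factors whose
binding sites harbor SNPs, then after treatment the affected CpG sites gain
a genetic component of variance. A genetic component leaves two fingerprints
that can be measured *within* a phase, and are therefore immune to a
between-phase location shift:

* **familiality** — resemblance of relatives. We use the Spearman
  correlation between full siblings (`scor`), each pair ordered by birth so
  the two vectors are consistently defined. Twice the sibling correlation is
  an upper bound on the narrow-sense heritability
  (`heritability_upper_bound()`).
* **variability** — the per-site standard deviation of beta values. A
  segregating allele with an effect on methylation inflates the trait
  variance.

The screen ranks all sites within each of the four distributions (SD and
scor, pre and post), takes the upper 0.1% tail of each (450 sites of a
450,000-site array), intersects the two **post**-treatment outlier sets, and
removes any site that was already an outlier of **either** pre-treatment
distribution. Surviving sites — post-concordant, pre-unremarkable — are the
candidate treatment-responsive CpG sites. If the candidate set is empty, the
screen escalates to 0.5% and then 1% thresholds, recording which level
produced results. Candidates are then followed up with a cis-window meQTL
scan: SNPs with MAF > 1% within 1 Mb of the CpG, tested under a mixed model
that accounts for pedigree relatedness.

Two deliberate asymmetries are worth noting. Outliers are upper-tail only —
the screen looks for the *most* familial and variable sites, and a loss of
genetic control is not part of the model. And the pre-exclusion uses the
same rank cut as the post-selection, so "was not an outlier before" is
judged at the threshold that defines "is an outlier now".

## Statistics: definitions and conventions

**SD.** Sample standard deviation with the `n - 1` denominator over a
phase's non-missing values, computed on the full phase sample including
relatives, with no family adjustment. Every site is estimated on the same
sample and downstream use only ranks the estimates, so the (real)
non-independence among relatives distorts no comparison between sites.

**scor.** Spearman correlation over ordered sibling pairs, average ranks on
ties, pairwise-complete; a site reports `NA` below `min_pairs` complete
pairs (default 10 — below that a rank correlation is too unstable to rank
against 450,000 competitors). All distinct full-sib pairs enter (a sibship
of size *k* contributes *k(k-1)/2* pairs); `one_pair_per_sibship = TRUE`
restricts to the two earliest-born as a sensitivity analysis, since pair
counts reported for family studies rarely state the rule. Beta values are
analyzed directly rather than M-values: both statistics are either
rank-based or used only through ranks, and a monotone transform changes
neither the scor nor the relative ordering questions the screen asks (it
does change SD, which is why the generator is explicit about the beta
scale — see below).

**Ranking.** `rank_descending()` breaks ties lexicographically by site id
and ranks missing values after everything else, so ranks are always a
permutation of `1..N` and the entire screen is byte-reproducible. The
selected set size is exactly `round(fraction * N)`.

**Turnover.** For each statistic, `|post outliers \ pre outliers| / |post
outliers|` — the fraction of the post-treatment outlier set that is new.
Near-total scor turnover with modest SD turnover is the signature pattern of
a phase-specific familiality change measured with noisy per-site
correlations.

## The mixed model and its spectral acceleration

For a candidate site, methylation `y` across the `n` analysis samples is
modeled as

y ~ N(Xb + g s, sigma_g^2 R + sigma_e^2 I)

where `s` is the SNP dosage (0/1/2, missing values mean-imputed), `R` is a
relatedness matrix — by default twice the pedigree kinship matrix Phi, any
externally estimated PSD matrix is accepted — and `sigma_g^2 R` absorbs the
polygenic covariance among relatives. Phi is computed by the recursive
tabular method: founders unrelated, `phi(i,i) = 0.5 (1 + phi(fa_i, mo_i))`,
`phi(i,j) = 0.5 (phi(fa_i, j) + phi(mo_i, j))` processing parents before
children; the matrix is block-diagonal across pedigrees and `2 Phi` is
positive semi-definite by construction.

Writing `delta = sigma_e^2 / sigma_g^2` and eigendecomposing `R = U S U'`
**once per site**, the rotated data `U'y`, `U'X` have diagonal covariance
`sigma_g^2 (S + delta I)`: for any `delta`, the GLS estimates of `b` and
`sigma_g^2` are closed-form and one likelihood evaluation costs O(np).
`delta` is profiled on a 100-point log-spaced grid spanning `1e-5..1e5` and
the winning bracket is refined by one-dimensional optimization. The grid
bounds encode the two degenerate limits — `delta -> 0` is a pure genetic
model, the cap stands in for `sigma_g^2 -> 0` (at the cap the GLS weights
are uniform to ~3e-5 relative and the fit coincides with OLS) — while
keeping the ratio finite. Maximum likelihood is the default; REML is a flag.
Each SNP is then tested by appending its rotated dosage to the covariates
and re-solving the weighted least-squares problem **at the null fit's
`delta`** — the standard acceleration that makes scanning hundreds of SNPs
per site a sequence of O(np) solves; `refit_per_snp = TRUE` re-optimizes
`delta` per SNP for comparison. The Wald statistic uses the `n - p` residual
variance, so with `R = I` it reduces exactly to the classical t-statistic;
p-values are reported from the standard normal reference, raw (no
multiplicity adjustment, matching how single-region scans are usually
reported; a within-window Bonferroni is a trivial post-hoc step on the
output table). No covariates are included by default; a covariate matrix
(age, sex) is an argument.

The per-site null fit restricts to complete cases of `y`; the MAF filter is
strict (`> 0.01`) and computed from non-missing dosages on the scan sample;
the cis window is the closed interval `|pos_SNP - pos_CpG| <= 1e6`. Lead
SNPs are the minimum-p SNP per site, ties broken by smaller position then
id, which makes scan output invariant to SNP input order.

## What the generator emulates

`sim_config()` / `generate_study()` produce a complete study whose structure
mirrors a two-phase family methylation panel:

* **Pedigrees.** Nuclear families: two founders plus a sibship of size drawn
  from `sibship_size_distribution`. The default
  `P(1,2,3) = (0.46, 0.36, 0.18)` over 182 families gives 0.90 expected
  sibling pairs per family — about 164 pairs, the scale of a ~180-pedigree
  family study. Real pedigrees of such studies are extended (about 5.5
  members each, which no nuclear-family sibship distribution can reproduce
  simultaneously with the pair count); we match the *pair count*, the
  quantity both the familiality statistic and the kinship model actually
  consume.
* **Genotypes.** Gene dropping: founder alleles Bernoulli(MAF) under HWE,
  offspring inherit one uniformly chosen allele per parent. Realized sibling
  dosage correlation is then `2 phi = 0.5` by construction. Each meQTL-class
  site gets a causal SNP within ±50 kb of the CpG plus `snps_per_window - 1`
  independent neighbors across its ±1 Mb window. No LD model: neighbors are
  independent, so "localization" means the causal SNP itself wins, a
  stricter requirement than in real LD blocks (where the lead may be a
  proxy) but also an easier one (no correlated competitors).
* **Methylation.** Latent liability per individual and site:
  `z = mu_j + beta_phase,j * dosage + a + c + batch * 1[post] + e`, with
  polygenic `a` drawn per pedigree from N(0, `sigma_a2 * 2 Phi`), sibship-
  shared `c ~ N(0, sigma_c2)` (founders draw independently — they come from
  different households), residual `e ~ N(0, sigma_e2)`, mapped through the
  logistic link to a beta value in (0, 1). The link is bounded and strictly
  monotone, so rank statistics computed on beta values equal those on the
  latent scale exactly, and no boundary atoms arise (the alternative,
  truncation, piles mass at 0/1 and breaks rank equivalence). `a` and `c`
  are drawn once and shared by both phases — an individual's genotype and
  household do not change with treatment — while `e` is phase-specific.
* **Attrition and batch.** The post-treatment sample keeps whole pedigrees
  at random until `post_retention` (default 0.53) of individuals remain, so
  retained families contribute intact sibling pairs, and adds `batch_shift`
  (default 0.3 latent units) to every site — a pure location confound, which
  is exactly the artifact the indirect design is built to survive: it moves
  post-treatment means but neither within-phase SD ranks nor rank
  correlations.

### Parameter defaults and why

All variance parameters are on the latent (logit) scale.

| parameter | default | rationale |
|---|---|---|
| `sigma_a2, sigma_c2, sigma_e2` | 0.020, 0.006, 0.174 | total 0.2: null-site sibling latent correlation 0.08 → familiality `2*scor ≈ 0.16`, a modest typical methylation heritability; null beta-SD ≈ 0.1 at intermediate methylation, well below planted-site SDs (~0.25) as on a real array |
| `responsive_ve` | 0.85 | fraction of post-treatment latent variance explained by the causal SNP. Deliberately a *strong* meQTL: a lead SNP reaching p below 1e-200 at a few hundred samples implies the variant explains most of the site's variance. The allele effect is derived per site as `beta = sqrt(ve/(1-ve) * V0 / (2p(1-p)))`, so the fraction is exact whatever the MAF |
| `constitutive_ve` | 0.35 | ordinary cis-meQTL strength, present in both phases |
| `causal_maf_range` | (0.2, 0.5) | a bounded beta value cannot be spread by a rare allele: with MAF 0.05 the minor-homozygote class is ~0.25% of samples and the beta-scale SD barely moves however large the latent effect. A variant explaining most variance of a bounded trait is necessarily common |
| `snp_maf_range` | (0.05, 0.5) | non-causal window SNPs span the usual common-variant range; the scan's MAF filter (1%) never bites by construction |
| `mu_sd_null` / `mu_sd_meqtl` | 2.0 / 0.3 | per-site baseline logit means. Wide for null sites (the array-wide beta distribution is bimodal, most sites near 0 or 1 where the SD is compressed); narrow for meQTL sites, which sit at intermediate methylation — both the mechanism (an active, SNP-sensitive regulatory site) and the selection of the screen favour mid-range sites |
| `batch_shift` | 0.3 | a visible (~7% of a mid-range beta value) location confound |
| `post_retention` | 0.53 | 530-from-995-scale attrition |
| `site_class_fractions` | 0.99 / 0.006 / 0.004 | a handful of planted sites in a null background; 20 responsive sites per 5,000 |

Effect sizes for the treatment response are genuinely free parameters — no
empirical estimate exists to pin them — so the defaults were chosen, once,
for detectability at the simulated sample sizes and are documented here
rather than tuned per experiment.

### What the generator does *not* emulate

Probe-level measurement error, cell-type composition, realistic LD,
position-dependent mean structure along the genome, extended pedigrees, and
non-batch technical artifacts. Consequently, passing tests show that the
screen and scan behave correctly *given their own model of the data*; they
do not show robustness to cellular heterogeneity or probe artifacts, which a
real analysis would have to address upstream.

## Numerical and degenerate-input choices

* Kinship Cholesky factors add `1e-10` to the diagonal (founder blocks are
  singular in `2 Phi` only for inbred configurations, which the generator
  never produces but the recursion supports).
* The eigendecomposition refuses relatedness matrices with eigenvalues below
  `-1e-6` relative; small negative eigenvalues from floating-point are
  clamped to zero.
* Zero-variance traits, missing values in `y`, asymmetric `R`, monomorphic
  SNPs (after imputation) and empty cis windows are rejected or skipped with
  named errors/warnings rather than propagated.
* `threshold_count()` floors at one site; `outlier_turnover()` refuses an
  empty post set rather than return 0/0.
* Every stage of the generator derives its RNG stream from `cfg$seed`
  (stage-offset seeds below 2^31), so a configuration is one dataset:
  reruns are byte-identical, including written TSVs.

## Validation strategy and problem sizes

The test suite pins each component to an independent oracle rather than to
itself: Spearman against an explicit average-rank Pearson computation (1,000
random vectors, agreement to 1e-12); the spectral log-likelihood against a
dense multivariate-normal evaluation (n ≤ 60, 1e-6); the kinship recursion
against a 100,000-replicate gene-dropping identity-by-descent Monte Carlo on
a three-generation pedigree (±0.01); the null distribution of the SNP test
against uniformity over 2,000 pedigree-simulated replicates at n = 200
(rejection rate at 5% within [0.035, 0.065]); the simulated sibling Spearman
against the bivariate-normal closed form `(6/pi) asin(rho/2)` at 2,000 pairs
(±0.03); and the end-to-end screen against planted truth at an
array-scaled-down size — 5,000 sites, 150 pedigrees, 20 responsive sites,
0.5% threshold, ten seeds — chosen so the whole suite and the acceptance
script each run in about a minute. `scripts/acceptance.R` recomputes the
same quantities from scratch under a caller-supplied seed.

## Known limitations

* The familiality statistic needs sibling pairs in *both* phases;
  whole-pedigree attrition preserves pairs but halves their number at the
  default retention, and scor sampling noise at ~200 pairs is the binding
  constraint on recall — sites whose true post scor sits within one standard
  error of the selection cutoff are found only most of the time.
* The screen is a ranking device, not a test: no error rate is attached to
  "outlier", and the 0.1% / 0.5% / 1% ladder is a design choice inherited
  from the analysis the package operationalizes.
* `common` sample mode (both phases restricted to shared individuals)
  trades power for sample consistency exactly as described; with
  whole-pedigree dropout the shared sample *is* the post sample, so the mode
  matters mainly for data ingested from files.
* The Wald test at the null `delta` is slightly liberal at small n (normal
  vs t reference); the calibration suite bounds the effect at n = 200.
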