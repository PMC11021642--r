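---
title: "Methods: twin-design EWAS, cell-composition adjustment, causal inference and region calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin-design EWAS, cell-composition adjustment, causal inference and region calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mzewas)
```

# The design

`mzewas` implements an epigenome-wide association workflow for a continuous
trait measured in trait-discordant monozygotic (MZ) twin pairs, with RRBS
(reduced representation bisulfite sequencing) count data as input.  The MZ
design matches genetic background perfectly within a pair, so within-pair
contrasts remove genetic confounding; discordance in the trait (here,
handgrip strength in kg, with a minimum intra-pair difference of 0.1 kg)
guarantees informative contrasts.  The pipeline is:

1. **QC** — coverage capping, low-signal site removal, beta-to-M transform;
2. **cell composition** — reference-free surrogate components;
3. **EWAS** — per-CpG generalized estimating equations (GEE) clustered on
   pair, with BH-FDR control;
4. **causal inference** — ICE FALCON on the FDR-significant CpGs, in both
   directions;
5. **region calling** — autocorrelation-adjusted Stouffer–Liptak (SLK)
   combination of the per-CpG p-value track;
6. **annotation** — nearest gene from a local gene-model file, and Spearman
   correlation of methylation with expression where expression is supplied.

Because raw twin RRBS cohorts of this kind are not generally deposited, the
package carries a first-class cohort simulator whose ground truth drives the
test suite, plus the published summary tables of a handgrip-strength twin
EWAS as worked-example inputs for desk-scale arithmetic checks.

# Preprocessing

Coverage at a CpG-by-individual cell is capped at the empirical quantile
(default 0.90, type-7 interpolation rounded half-to-even to an integer cap)
of all observed coverages; methylated counts at capped cells are rescaled
proportionally.  Capping rather than exclusion follows the usual practice of
limiting overdispersed RRBS coverage (the alternative reading — excluding
such cells — is available by filtering beforehand; we state the choice here
because published QC descriptions rarely distinguish the two).

A cell is *missing* iff its coverage is zero; no other missingness rule is
imposed.  Sites are removed when the mean beta over non-missing individuals
is **below** 0.01 (a site at exactly 0.01 is kept) or when **more than** 10
observations are missing (exactly 10 is kept); "observations" means
individuals, not pairs.  M-values are `log2(beta/(1-beta))` with beta clamped
to `[eps, 1-eps]`, `eps = 1e-6`, giving M = ±19.93 at the boundaries — the
standard variance-stabilised regression scale.  A triangular-kernel smoother
(`smooth_beta()`, bandwidth 80 bp) is available as an optional, deliberately
simple stand-in for heavier local-likelihood smoothing; it is not part of the
default pipeline.

# Cell composition

Whole-blood methylation is a mixture over cell types.  Without reference
profiles, `refactor_components()` recovers mixture surrogates by
feature-selected PCA: standardize each site, reconstruct at rank *k* by
truncated SVD, rank sites by reconstruction distance, keep the *t* best
(default 500; ties broken by genomic order), and take the first *d* (default
5) principal-component scores of the individuals over that panel.  Defaults
k = 5, t = 500, d = 5: only "five components" is conventionally reported by
studies; k and t follow the method's customary defaults and are exposed for
scaled-down simulations.  Component signs are fixed by forcing the
largest-absolute-loading entry positive, otherwise the SVD sign ambiguity
breaks bit-reproducibility of every downstream regression.

# GEE with exchangeable within-pair correlation

Each CpG is modelled marginally: M ~ trait + sex + age + PC1..PCd, Gaussian
family, identity link, exchangeable working correlation within pairs.  The
fitter alternates a GLS coefficient update with a moment estimate of the
working correlation from standardized residuals, converging when the largest
coefficient change is below 1e-8 (at most 100 iterations; non-convergence is
flagged, never raised).  Because the exchangeable inverse has closed form,
all cluster algebra reduces to per-cluster row sums and the update is fully
vectorised.  Inference uses the robust sandwich covariance over clusters,
Wald z and two-sided **normal** p-values (the GEE convention; not t).  The
direction of the model — methylation as outcome, trait as predictor — gives
coefficients in M-value change per kg.  Sex is coded 0/1 and age enters in
years, uncentered; both are nuisance terms.  BH-FDR q-values are computed
over the sites actually tested after QC.

Degeneracies worth knowing: singleton clusters (or a working correlation of
zero) reduce the fit exactly to OLS, and duplicating independent
observations into fake pairs drives the estimated correlation to ~1 while
leaving coefficients at their OLS values — both are exploited as tests.

# ICE FALCON

For a CpG and the trait, three exchangeable-GEE models are fit over twins
(clustered on pair): outcome on own exposure (slope `beta_self`), on the
co-twin's exposure (`beta_cotwin`), and on both jointly (`beta_self'`,
`beta_cotwin'`).  With change coefficients `delta = marginal - joint`, a
causal exposure-outcome path strips the co-twin slope once the self exposure
is conditioned on, while pure familial confounding attenuates both equally;
the decision statistic is `ratio = |delta_cotwin| / |delta_self|`, called
causal when strictly above the threshold (default 1.5).  The ratio is
oriented co-twin-over-self because that quotient reproduces the published
worked-example ratios (e.g. |−2.215|/|−0.986| = 2.25); the threshold is a
configuration parameter.  Both directions are always fit: methylation to
trait, and trait to methylation.  The adjustment set (sex, age, cell
components) mirrors the EWAS scan; studies rarely state the ICE FALCON
adjustment set, so keeping it identical to the scan is the least surprising
choice.

Change p-values are computed by a pair-level nonparametric bootstrap
(default B = 1000): pairs are resampled with replacement, the deltas
recomputed per replicate, and two-sided p-values taken from the normal
approximation `2 * pnorm(-|delta| / SE_boot)`.  More than 20% replicate
failures aborts.  Published tables do not describe their change-p-value
mechanism; the pair bootstrap is the standard choice for this family of
estimators.

# Region calling

The per-CpG p-value track is combined into regions in the comb-p style:

* **Autocorrelation** (`estimate_acf()`): p-values become z = Φ⁻¹(1−p);
  same-chromosome site pairs are binned by distance (50 bp bins to 500 bp)
  and a symmetrised Pearson correlation is computed per bin, with sparse
  bins interpolated from neighbours.
* **Smoothing** (`smooth_pvalues()`): each site's p is replaced by the
  Stouffer–Liptak combination over its ±500 bp window, with pairwise
  correlations looked up from the ACF.
* **Seeding/merging** (`find_regions()`): smoothed p < 0.05 seeds a region;
  seeds within 500 bp merge; regions need at least 2 member sites.
* **Scoring** (`score_regions()`): the SLK region p combines the members'
  *raw* p-values under the ACF correlation (last bin carried forward beyond
  the estimated range); a Šidák correction `1−(1−p)^(G/width)` for the
  effective number of same-width regions is reported alongside, and
  significance is declared on SLK p < 0.05.  Direction is "positive" /
  "negative" when all member coefficients share a sign, "mixed" otherwise —
  the mixed class exists because published DMR sets routinely contain
  regions of inconsistent sign.

`stouffer_liptak()` computes `1 − Φ( Σz / sqrt(1ᵀC1) )`; with the identity
correlation this is exactly classical Stouffer, an identity the tests assert
on random vectors, and a 10⁵-draw Monte-Carlo oracle validates the
correlated case.  Non-PSD correlation matrices (possible because binned ACF
values are plugged into arbitrary distance patterns) are repaired by
eigenvalue clipping at 1e-8 followed by rescaling to unit diagonal.  Zero
p-values are clamped to the smallest positive representable number.  The
seed/merge/window defaults (0.05, 500 bp, 500 bp, 50 bp bins) are chosen to
bracket the span of typical RRBS DMRs (roughly 100–1000 bp) and match comb-p
conventions; published analyses rarely state them.

# The cohort simulator

`simulate_cohort()` draws, per individual *i* in pair *p* and site *s*:

```
logit beta_is = Σ_c w_ic L_sc + g_ps + e_is  (+ scenario terms)
trait_i       = mu + sd·( sqrt(rho) u_p + sqrt(1-rho) r_i )  (+ scenario terms)
```

with Dirichlet cell proportions `w_i`, per-site/cell-type baseline logits
`L_sc`, a pair-shared epigenetic term `g_ps`, and standard-normal pair and
individual trait factors — the simplest generative model with an MZ
shared-component structure, so the intra-pair trait correlation converges to
`pair_trait_corr` by construction.  Counts follow coverage ~ NegBin(mean 30,
size 3; RRBS coverage is overdispersed) and methylated ~ Binomial(coverage,
beta).  Planted scenarios define the causal structure the inference stages
must recover: `forward_causal` adds `effect·M` to the trait,
`reverse_causal` adds `effect·(trait−mu)` to the logit, and `confounded`
routes a pair-level standard normal into both with no direct path.  Pairs
violating the minimum discordance have their individual trait residuals
redrawn (up to 100 attempts, then an error), preserving the pair count.  All
randomness flows from a single integer seed with fixed draw order, so equal
seeds give byte-identical cohorts.

Default parameters encode the motivating study population: 66 pairs, trait
32 ± 10.3 kg (back-solved from the reported median and 95% range), a
within-pair correlation of 0.85 (back-solved from the reported median
intra-pair absolute difference of 3.9 kg via `2σ²(1−ρ) = (3.9/0.674)²`),
0.1 kg minimum discordance, and a whole-blood-like five-cell-type Dirichlet
(concentrations 10, 5, 2.5, 1.5, 1).  The default 2000 sites is a scaled
methylome — every stage is linear in sites, so genome-scale runs only change
`n_sites`.  What the simulator does **not** emulate: genomic sequence
context (CpG islands, fragment structure), bisulfite conversion error,
batch effects, and spatial correlation of methylation beyond the pair and
mixture terms — so passing tests demonstrate algorithmic correctness and
calibration under the stated model, not robustness to those real-data
features.

`estimate_power()` wraps the scan into a replicate loop for twin-design
power: one planted forward-causal CpG per replicate, detection = robust GEE
p below alpha.  It exposes the knobs (pairs, effect size, replicates,
nuisance configuration) rather than hard-coding any particular published
power grid.

# Numerical choices and degenerate inputs

* Working correlation clamped to (−1/(n_max−1)+1e-6, 0.999) so every
  cluster covariance stays invertible.
* Rank-deficient designs error naming the collinear column; site-level
  collinearity inside the scan is reported per site (`reason`), never
  silently dropped.
* ICE FALCON with identical self/co-twin exposures (possible for MZ twins)
  is flagged unestimable; a zero self-change makes the ratio undefined
  (reported missing, never flagged causal).
* Quantiles are type-7; count rescaling rounds half-to-even; ties in the
  ReFACTor panel ranking and in nearest-gene distance break by genomic
  order / smaller gene start, and component signs are pinned — the pipeline
  is deterministic end to end, which the checksum-identity test enforces.
* Spearman p-values use the t approximation (intended n ≈ 24 individuals);
  |rho| = 1 reports p = 0.

# Problem sizes used by the shipped checks

The test-suite simulations are sized to be decisive yet quick: type-I
calibration on 200 pairs × 500 null sites; slope recovery and ICE FALCON
scenario discrimination at 2000 pairs (6 scenario sites per cohort);
composition recovery on 100 pairs × 500 sites with 3 cell types; and an
end-to-end 50-pair × 2000-site pipeline run executed twice to prove
checksum idempotence.  These sizes are the package's validation conditions;
larger runs change nothing but wall time.

# Known limitations

* The GEE fitter covers the Gaussian/identity case used here, not other
  families.
* Reference-based deconvolution is out of scope; the components are
  surrogates, not interpretable proportions.
* The DMR stage reproduces the comb-p *logic*; exact agreement with any
  particular published region list additionally requires that study's raw
  p-value track and tuning parameters.
* Bootstrap change p-values are approximations whose accuracy degrades for
  very small pair counts (B and the threshold are configurable).
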