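---
title: "Methods: emotion-regulation network connectivity and family-nested models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emotion-regulation network connectivity and family-nested models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ernfc)
```

## The scientific problem

Children of parents with mental health problems carry an elevated risk of
psychopathology, and emotion regulation (ER) is one candidate pathway:
parental symptoms may co-occur with altered connectivity of the child's ER
brain circuitry, which in turn may relate to the child's own later
symptoms. `ernfc` implements the full statistical pipeline for testing
this on resting-state functional connectivity summarized over four
meta-analytically defined ER networks — a dorsolateral prefronto-parietal
regulatory network (`ERN1`), a ventrolateral prefrontal network (`ERN2`),
a subcortical/limbic reactivity network (`ERN3`), and a
subcortical–cortical integrative network (`ERN4`) — in a cohort of
families with siblings, scanned across many sites.

Because the motivating cohort is restricted-access, the package ships a
first-class synthetic-data module that reproduces the statistical
structure of such a cohort. Every downstream stage is developed and
validated against data with *known* ground truth; the package's claims
are therefore parameter-recovery claims, not re-analyses of real data.

## Pipeline stages and their models

### 1. Network-to-parcel mapping

ER networks are defined by peak coordinates (or cluster masks) in MNI
millimetre space; connectivity matrices are defined over atlas parcels.
`compute_overlap()` rasterizes each ROI — a 6 mm sphere around its peak,
by default — onto the label volume and counts, per (network, parcel)
pair, the voxels landing in the parcel. Three conventions are fixed and
tested rather than left implicit:

* **Membership** is by voxel *centre* within the radius (not any-corner);
  this is the common convention for sphere ROIs and makes the count an
  exact lattice quantity, testable against a brute-force per-voxel loop.
* **Voxels shared by two ROIs of one network are counted once** (the
  network's voxel set is the union of its ROI spheres). For disjoint
  spheres this equals summing per-ROI counts.
* **The affine is the single source of truth**: voxel indices are
  0-based, and translating both the volume origin and all peaks by the
  same offset leaves the overlap table unchanged (a tested invariant).

Parcels with weak overlap are dropped at the pooled first quartile of the
voxel-count distribution (`filter_overlap()`, linear-interpolation
quantile, `stats::quantile()` type 7; a fixed "≤ 5 voxels" rule and a
per-network quartile are available because the pooling scope of the
quartile is a genuinely open choice). Each surviving parcel is assigned
to the network with the largest overlap; exact ties go to the
lowest-numbered network with a warning. A network that retains fewer
than two parcels is an error, because its within-network mean would be
undefined downstream. Peaks falling into background are dropped with a
warning rather than snapped to the nearest parcel — snapping would invent
data.

### 2. Connectivity features

Subject-level connectivity is a symmetric parcel×parcel matrix of
Fisher-z transformed correlations (`z = atanh r`). All summaries stay on
the z scale — the variance-stabilized scale is also the analysis scale —
and the diagonal is always excluded. The ten features are the 4
within-network means (over the `k(k-1)/2` unique pairs) and the 6
between-network means (over all `k_a × k_b` cross pairs), in fixed key
order `ERN1..ERN4, ERN12..ERN34`. Asymmetry beyond `1e-8` and non-finite
off-diagonal entries are errors, never silently repaired.

### 3. Site harmonization

Multi-site MRI features carry additive and multiplicative scanner
effects. `fit_combat()` implements the standard parametric
empirical-Bayes location/scale model: per feature, batch intercepts and
covariate effects are estimated jointly; data are standardized by the
pooled residual scale; per-batch means and variances are shrunk toward a
normal and an inverse-gamma prior via the usual iterative moment updates
(absolute convergence `1e-6`, at most 100 iterations); and
`apply_combat()` removes the shrunk batch location/scale while adding the
covariate effects back. The fit/apply split makes the model serializable
(`write_combat_model()`) and applicable to new data from known batches.
The default covariate set preserved during harmonization is youth age,
sex, and all six parental/youth sum scores. A single batch yields the
identity adjustment; singleton batches and designs collinear with batch
are errors. The test suite checks property-level agreement with the
reference implementation in `sva` (to ~1e-6 on identical inputs) but the
package intentionally does not promise bit-parity with any external tool.

### 4. Association grids

Each analysis cell is a linear mixed model

\[ \text{feature}_{ij} = \beta_0 + \beta_1\,\text{score}_j +
   \beta_2\,\text{age}_{ij} + \beta_3\,\text{sex}_{ij} + u_j + e_{ij},
   \qquad u_j \sim N(0, \tau^2), \]

with a random intercept per family \(j\). Connectivity is always the
outcome; the predictor set is the three parental baseline scales (main
grid, 30 models) or the three youth follow-up scales (exploratory grid).
Standardized coefficients z-score the outcome and continuous predictors
on the analysis sample and contrast-code sex as ±0.5 — a recipe that
makes the standardized beta exactly the raw slope times
\(SD_x / SD_y\) (tested to `1e-6`).

Inference is by family-level **case bootstrap**: whole families are
resampled with replacement, the model is refit (B = 1000 by default),
and the percentile 2.5/97.5 quantiles give the CI. The two-sided
bootstrap p-value is \(2\min\big(\frac{1+\#\{\beta^*\le 0\}}{B+1},
\frac{1+\#\{\beta^*\ge 0\}}{B+1}\big)\); the +1 correction keeps p-values
off exact zero. Residual and parametric schemes are available, but the
case bootstrap is the default because it is robust to misspecification
of both variance components. Resampled fits that fail are dropped and
counted; a cell with more than 5% failures is flagged. FDR correction is
Benjamini–Hochberg (`stats::p.adjust`), pooled over the whole grid by
default — identical adjusted p-values across scales in the motivating
design are only possible under pooling — with a per-scale option.

Degrees-of-freedom approximations (Satterthwaite etc.) are deliberately
absent: inference is bootstrap-based throughout.

### 5. Multilevel mediation

The mediation model treats the parental scale \(X\) (family-constant) as
exposure, one connectivity feature \(M\) (child-level) as mediator, and
the matching youth follow-up scale \(Y\) (child-level) as outcome, with
children at level 1 and families at level 2. The mediator–outcome path is
split by the observed family-mean decomposition
\(M_{ij} = \bar M_j + (M_{ij} - \bar M_j)\):

\[ M_{ij} = a X_j + \dots + u_j + e_{ij} \]
\[ Y_{ij} = c' X_j + b_B \bar M_j + b_W (M_{ij}-\bar M_j) + \dots
            + v_j + \varepsilon_{ij} \]

The indirect effect is \(a \cdot b_B\) — a family-level exposure can only
transmit through the between-family component — and the total effect is
\(c' + a b_B\). Design choices made here, where the field genuinely
varies:

* **Observed family means, not latent centering.** The decomposition is
  closed-form, exactly testable (within components sum to zero per
  family to `1e-10`), and matches how the synthetic generator plants
  paths. The cost: with small clusters, observed means are noisy
  measurements of the latent between-family component, so a latent-model
  \(b_B\) would differ; this is documented rather than hidden, and the
  recovery tests plant on the observed-mean scale.
* **ML, not REML**, for both mediation equations, so that the free model
  (separate \(b_W, b_B\)) and the constrained model (\(b_W = b_B\)) can
  be compared by a likelihood-ratio (chi-squared difference) test on 1
  degree of freedom (`compare_b_paths()`), which refuses REML fits or
  fits on different samples.
* **Family-constant exposure is enforced.** Rows where parental scores
  differ within a family are rejected with an error;
  `subsample_one_per_family()` is the documented resolution utility.
  With singleton-only samples \(b_W\) is inestimable — it is reported as
  `NA` with a warning, never silently zero.
* The indirect CI is Monte-Carlo by default (sample \(a\) and \(b_B\)
  from their asymptotic distributions — they come from separate
  equations, hence independently — and take percentile quantiles of the
  product); a family-level bootstrap variant exists. Baseline-adjusted
  models add the matching parent-reported youth baseline score as a
  covariate. Baseline age is used in both equations by default.

### Two model engines

User-facing fits default to `lme4`. The grids and simulation studies use
the package's own profiled-deviance random-intercept fitter
(RcppArmadillo): for a single random intercept the marginal covariance is
block-diagonal with blocks \(I + \lambda J\), so the ML/REML criterion is
one-dimensional in \(\lambda\) and each evaluation needs only per-group
sums pooled by family size. One fit costs well under a millisecond, which
is what makes 1000-replicate family bootstraps over 30-cell grids, and
hundred-grid null calibration studies, run in minutes. The test suite
pins the two engines against each other (coefficients, standard errors,
variance components, and ML log-likelihood agree to optimizer
tolerance); the fast engine is a performance path behind the same model,
not a different model.

## The synthetic cohort generator

`sim_config()` defaults are the reference study conditions and are not
tuned per analysis:

| parameter | default | what it emulates |
|---|---|---|
| `n_families` | 3952 | cohort scale (~4200 children) |
| `sibling_probs` | 0.9386 / 0.0597 / 0.0018 | observed 1/2/3-child family mix |
| `n_sites` | 21 | acquisition sites, families nested in sites |
| `age_mean`, `age_sd` | 10.0, 0.6 years | baseline age distribution |
| `score_mu`, `score_size` | per scale | negative-binomial sum-score skew |
| `parent_youth_cor` | 0.15 | observed parent–youth score correlation band (0.1–0.2) |
| `within_mean`, `between_mean` | 0.35, 0.12 (z) | within > between network connectivity |
| `family_sd` | 0.03 (z) | family random intercept on features |
| `noise_sd` | 0.07 (z) | subject-level feature noise |
| `site_sd`, `site_scale_range` | 0.05, (0.8, 1.25) | additive and multiplicative scanner effects |
| `planted_effects` | 8 cells, \|β\| 0.04–0.05 | the reported effect map (defaults, not ground truth) |

Scores come from a Gaussian copula with negative-binomial margins:
parental latents per family, youth latents per child with a shared family
component (`sibling_cor`), and a baseline youth draw correlated with
follow-up. Two calibrations are built in and documented because naive
versions are biased:

* **Copula attenuation.** A Pearson correlation imposed on the latent
  normals shrinks when pushed through the skewed quantile transform. The
  latent correlation is therefore inflated by a fixed factor (1.18,
  measured once on large simulations of the default margins) so the
  *observed* matching-scale correlation lands on `parent_youth_cor`.
* **Standardized planting.** Adding a planted term \(\beta \sigma_f
  z(x)\) inflates the feature SD by \(\sqrt{1+\beta^2}\), attenuating the
  standardized coefficient. The generator plants
  \(\beta/\sqrt{1-\beta^2}\) on the raw scale so the standardized slope
  is exactly the configured \(\beta\). Negligible at \(|\beta| = 0.04\),
  material for mediation a-paths of 0.3.

When mediation paths are planted, the matching youth follow-up score is
rebuilt as a continuous standardized outcome from the planted model
(with the residual SD chosen to keep its variance near 1); count-valued
outcomes and planted linear paths cannot both hold exactly, and the
continuous version is what makes path recovery exactly checkable.

What the generator does **not** emulate: real spatial autocorrelation of
parcel time series, motion artefacts and their censoring, heavy-tailed
site effects, missing-data mechanisms, or informative family size.
Passing recovery tests therefore demonstrate that the *statistical
machinery* is correct under the assumed structure, not that the pipeline
is robust to everything real data can do.

## Reference problem sizes

The packaged checks use fixed simulation sizes chosen to make
Monte-Carlo error small relative to the tolerance being asserted:
atlas-mapping equivalence on 50 random volumes (≤ 20³ voxels, ≤ 6
parcels); recovery of β = −0.04 on 20 cohorts of ~4000 (mean within
±0.015, sign in ≥ 90%); null calibration on 100 grids of ~1000 subjects
at B = 200 (pooled type-I error inside the exact binomial band;
false-discovery proportion not significantly above q = 0.05 — with all
nulls true, per-grid FDP is 1 exactly when BH rejects anything);
harmonization on cohorts of ~2000 with additive SD 0.1 and scale factors
up to 2; mediation on 50 cohorts of ~2000 with 30% of children in
sibling pairs (indirect 0.3 × 0.2 = 0.06 recovered within ±0.01).
Fixed-seed checks that assert a single 95%-coverage event are aggregated
over replicates (e.g. ≥ 8 of 10 CIs covering) instead of betting one
seed against a 5% tail.

## Known limitations

* Observed-mean centering biases the between-family path relative to a
  latent multilevel SEM when clusters are small; with mostly-singleton
  families the within-family path is weakly identified at best.
* The bootstrap p-value has resolution 2/(B+1); B = 200 (used in the
  null studies) cannot produce p below ~0.01.
* The EB harmonization assumes roughly normal feature distributions
  within batch; the nonparametric ComBat variant is out of scope.
* Surface-based (CIFTI) mapping is out of scope; the mapping stage is
  volumetric by design.
* Sex-stratified and moderated-mediation models are not implemented.
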