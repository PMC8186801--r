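---
title: "Methods: a pathway-based structural and functional connectivity index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a pathway-based structural and functional connectivity index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfci)
```

## The metric

Multiple sclerosis damages both the microstructure of white-matter tracts and
the functional coupling of the grey-matter regions they connect. This package
computes a single composite index of pathway integrity from two complementary
MRI measurements on three pathways — the transcallosal sensorimotor (SMC)
pathway and the left and right posterior cingulum bundles connecting the
posterior cingulate cortex (PCC) to the antero-mesial temporal lobe (AMTL):

* **fc** — functional connectivity: the mean of a whole-brain-normalised
  correlation z-map over a 9-voxel target seed (unitless z).
* **sc** — structural connectivity: radial diffusivity (RD, mm²/s) averaged
  along the pathway, weighted by a track probability map within white matter.
  RD rises with demyelination, so *higher* sc means *worse* structure.

Each pathway component is z-scored against a normative sample (per-pathway
sample mean and SD, N − 1 denominator):

$$Z = \tfrac12\left[s_{fc}\,\frac{fc - \overline{fc}}{\sigma_{fc}} +
      s_{sc}\,\frac{sc - \overline{sc}}{\sigma_{sc}}\right],$$

and the composite is

$$\mathrm{SFCI} = \tfrac12 Z_{motor} + \tfrac12\min(Z_{cog}^{L}, Z_{cog}^{R}),$$

with the cognitive term taken as the *worse* hemisphere so that unilateral
decline is not averaged away.

**Orientation signs.** The defaults are $s_{fc} = +1$, $s_{sc} = -1$: because
sc is a diffusivity that increases with tissue damage, negating its z-score
makes both components — and hence the index — decline with impairment, which
matches every directionality the index is meant to capture (patients scoring
below controls, decline tracking worsening behaviour). A literal mode
(`literal = TRUE`) sums both z-scores with positive sign for users who want
the plain two-term average; the two modes agree exactly whenever sc sits at
its normative mean, and tests pin both behaviours.

**Norming sample.** By default the control group's baseline visits
(`sfci_fit(norm_group = "HC", norm_visits = "baseline")`). Norming on all
control visits, or on the patient sample itself, is configurable; the
standardisation identity (component z means 0, SDs 1 on the norming sample)
holds for any choice and is enforced by tests.

Missing data rule: a subject-visit missing any of the three pathways is
skipped and reported, never imputed — a minimum over one hemisphere silently
changes what is being estimated.

## Functional connectivity pipeline

Order of operations on the resting-state series (`fc_pathway()`):

1. **2-D in-plane Hamming filter** — k-space apodisation, gain 1 at DC and
   0.08 at the in-plane Nyquist; slice means are preserved exactly.
2. **Temporal low-pass at 0.08 Hz** — zero-phase frequency-domain mask with
   a raised-cosine rolloff between 0.85 and 1.15 × cutoff. Zero phase avoids
   lag distortion of correlations; the passband (≤ 0.8 × cutoff) is
   attenuated < 5 % and the stopband (≥ 1.25 × cutoff) > 90 %.
3. **Seed reference** — arithmetic mean of the 9 seed voxels, then linear
   detrend (the fitted least-squares line is removed entirely).
4. **Whole-brain Pearson correlation** against the reference; zero-variance
   voxels are recorded as r = 0 and flagged.
5. **t conversion** — $t = r\sqrt{(n_{\mathrm{eff}}-2)/(1-r^2)}$, with
   $|r| = 1$ mapped to a finite sentinel (`t_cap`, default 10⁶).
6. **Whole-brain z-normalisation** — in-mask mean 0, SD 1. The *population*
   SD convention (divide by N) is the default; sample SD is available. The
   two differ by a constant factor, which matters only if mixed — one fixed
   default keeps cohorts comparable.
7. **fc** = mean z over the 9-voxel target.

Because step 6 removes global scale, the choice of effective sample size in
step 5 (nominal volume count by default; low-pass filtering reduces true
temporal degrees of freedom, and a corrected `n_effective` can be supplied)
changes fc only through a monotone map — it cannot reorder subjects.

Task activation for seed placement uses a separate branch: a 4 mm FWHM 2-D
in-plane Gaussian filter, then an ordinary-least-squares boxcar GLM
(intercept + polynomial drift + boxcar). The drift basis is polynomial of
order 2 by default — the external tooling this emulates does not pin a basis,
so it is configurable. Noise-free fits (zero residual) report the capped
sentinel rather than an infinite t.

Seed geometry: spheres are defined in world (mm) coordinates through the
NIfTI affine; in-plane 3×3 seeds are clipped to the grid and intersected with
the grey-matter mask, with an `eroded` flag replacing the manual gyral/CSF
erosion a human operator would perform. All voxel indices are 0-based; ROI
transfer between co-registered spaces maps voxel *centres* through the affine
chain with nearest-neighbour assignment, and all tie-breaks (activation
peaks, correlation pairs) are lexicographic for cross-platform determinism.

## Structural connectivity

The diffusion tensor is fitted per voxel by the standard log-linear least
squares on $\ln S = \ln S_0 - b\,g^\top D g$ (7 unknowns; at least one b = 0
volume and 7 volumes required). Negative eigenvalues — a noise effect — are
retained and flagged, not clipped: silent clipping biases RD downward.
Scalars follow the standard definitions (AD = λ₁, RD = (λ₂+λ₃)/2, MD = mean,
FA with the √(3/2) normalisation; FA of an all-zero tensor is defined as 0).

The pathway measure is

$$\langle D\rangle = \frac{\sum_v D(v)\,w(v)\,\mathrm{WM}(v)}
                           {\sum_v w(v)\,\mathrm{WM}(v)},$$

a true weighted average over the track probability map $w$ inside the
white-matter mask. The unnormalised weighted *sum* is available behind
`normalized = FALSE`; it scales with tract size and track-map scaling, which
makes cross-subject comparison meaningless, hence the normalised default.
Track maps supplied as visitation counts (max > 1) are rescaled by their
maximum, with a message — tractography tools emit both dialects.

## Cohort statistics

* **Motion gate**: a scan fails when TDzmax > 1 mm *and* TDzmean > 0.2 mm
  (conjunction); baseline failures withdraw the participant, follow-up
  failures flag the scan for inspection. A disjunctive mode exists for
  sensitivity analyses.
* **Exclusion cascade**: `exclusion_cascade()` turns participant- and
  visit-level flags into an enrolled → withdrawn → removed → final ledger and
  a scheduled → attended → usable → connectivity-usable visit ledger.
  `study_cohort_flags()` encodes the published study's printed flags (25 + 12
  enrolled; the subject identifiers are synthetic labels, the counts are as
  printed).
* **Longitudinal slopes**: `fit_longitudinal()` fits a random-intercept,
  random-slope mixed model by **maximum likelihood** (REML likelihoods are
  not comparable across fixed-effect structures) and compares full vs reduced
  models by a likelihood-ratio test against a χ² reference. Per-subject
  slopes are fixed effect + BLUP deviation. If the mixed fit fails, a fully
  specified per-subject OLS fallback is used and tagged (`engine = "ols"`).
  Visit enters as a continuous index.
* **FDR**: Benjamini–Hochberg step-up via `stats::p.adjust`; the *family* is
  caller-declared (e.g. per-table or per-imaging-measure), since family
  choice is an analysis decision, not a property of the adjustment.
* **Behaviour correlations**: Pearson, with natural-log transform for timed
  motor measures and exclusion of values beyond 3 SD of the (transformed)
  sample mean.

## The synthetic cohort and what it does (not) show

`simulate_cohort()` draws, per subject × pathway × component,
`baseline + slope·(visit − 1) + noise` with group-specific slope
distributions. The defaults define the package's study conditions:

| parameter | default | units | rationale |
|---|---|---|---|
| group sizes | 20 + 20 | subjects | patient-group size of a small longitudinal study; balanced for ROC stability |
| time points | 9 | visits | the largest design evaluated by the power curves |
| fc baseline | 2.0 ± 0.5 | z | typical in-pathway normalised correlation strength |
| sc baseline | 0.55e-3 ± 0.05e-3 | mm²/s | healthy-adult RD in cingulum/callosal tracts |
| progressor slopes | −0.05 (fc), +4e-6 (sc) | per visit | ≈ a tenth of a baseline SD per visit — slow, realistic decline |
| slope SDs | 0.03 / 3e-6 | per visit | between-subject heterogeneity of progression |
| measurement noise | 0.25 (fc), 2e-5 (sc) | per visit | half a baseline SD, session-level reproducibility |

The exact generative model and effect sizes behind the original
measure-development simulation are not recoverable from the published
material; these values are this package's own reconstruction, chosen once
from field-typical magnitudes, and the power results should be read as the
*shape* of the design-size relationship, not a replication. The two scenarios
mirror that structure: `uniform_decline` applies the progressor slopes to all
pathways, `domain_specific` only to the cognitive (PCC–AMTL) pathways.
Candidate measures M1 (combined), M2 (fc-only) and M3 (sc-only) share the
motor/hemisphere-minimum composite structure and differ only in which
component z-scores enter. Subject slopes are untruncated normals — the
simplest stated-distribution model.

Detection scores are negative per-subject OLS slopes over the first *t*
visits; ROC/AUC uses the Mann–Whitney U form with ties counted ½, which
equals the trapezoidal area exactly.

What the volumetric fixture generator (`make_image_fixtures()`) emulates:
geometry-consistent masks, a planted seed→target correlation at configurable
ρ, a constant-RD tract under a smooth track probability map, and a boxcar
activation at a known voxel. What it does **not** emulate: MR physics —
physiological noise spectra, motion, spatial autocorrelation of real BOLD
data, partial-volume effects, lesions. Green tests therefore demonstrate
algorithmic correctness and signal recovery under clean conditions, not
performance on clinical data.

## Numerical choices and degenerate inputs

* Population-SD z-normalisation; sample SD optional (constant-factor
  difference, tested).
* `t_cap = 1e6` replaces infinities from perfect correlations or noise-free
  GLM fits.
* Zero-variance time courses: excluded from correlation-pair searches,
  flagged r = 0 in maps, an error for references.
* Zero in-mask SD, empty masks/ROIs, all-identical norming samples,
  single-class ROC labels, non-positive DWI signals: all raise informative
  errors rather than propagating NaN.
* A file-header TR of 0 must be overridden explicitly — temporal filtering
  needs a trusted sampling rate.
* Random number use is isolated: simulators take explicit seeds and restore
  the caller's RNG state.

## Problem sizes used by the test suite

The suite exercises the pipeline at deliberately small scales chosen as the
package's own test design: oracle equivalences on grids ≤ 6³ and score sets
≤ 10; fixture volumes of 24 × 24 × 12 × 60 (50 seeded replicates for the
planted-correlation monotonicity check); 100 mixed-model replicates for slope
recovery; 200 replicates for null-AUC calibration and 500 for the
AUC-monotonicity checks. `scripts/acceptance.R` recomputes the cohort ledger
counts and the simulator/pipeline quantities at the same sizes.

## Known limitations

* Registration is consumed, never estimated: affines come from upstream
  tooling, and only label/ROI transfer is supported (no intensity
  resampling).
* Track probability maps are inputs; no tractography or FOD estimation.
* The effective temporal degrees of freedom after low-pass filtering are not
  corrected automatically (monotone effect only, see above).
* Whether per-visit affines should be composed through the anatomical volume
  is left to the caller — transfers compose explicitly via `affine_pair`s.
* The per-hemisphere reading of the cognitive pathway (one PCC seed → one
  map → ipsilateral AMTL target) is the default and the tested path; a
  bilateral reference is available by passing the union of both PCC seeds
  (`hemisphere = "bilateral"`) as the seed ROI, but the two readings are not
  interchangeable and the package does not assume both were intended.
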