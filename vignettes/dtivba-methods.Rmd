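---
title: "Methods: diffusion-tensor group analysis with voxel-based statistics"
author: "dtivba"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diffusion-tensor group analysis with voxel-based statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its own methods: the models and
procedures implemented, the parameters that matter, the synthetic phantom
that stands in for cohort data, and the numerical and design choices made
where the problem left them open.

## 1. Signal model and tensor estimation

Every stage rests on the mono-exponential single-tensor model of the
diffusion-weighted signal,

$$ S_k = S_0 \exp(-b_k \, g_k^{\mathsf T} D \, g_k), $$

with $D$ a symmetric positive-definite 3×3 tensor (mm²/s), $b_k$ the
diffusion weighting (s/mm²) and $g_k$ a unit gradient direction.
Gradients are interpreted in image coordinates; no scanner-frame
reorientation is applied, which is correct for the synthetic data and for
any real data whose gradient table is already in image space.

`fitTensors()` estimates $(\log S_0, D)$ per voxel by ordinary least
squares on log-signals. The estimator upstream of the published analyses
of this kind is typically a closed-source GUI tool whose internal choices
are not documented, so the estimator here is the transparent default of
the field; a one-pass weighted variant (weights equal to the squared
predicted signals, the usual first-order correction for the
log-transformed noise) is available via `method = "wls"`. Voxels with a
non-positive signal in any channel are excluded from the valid mask
(their log-signal is undefined); negative eigenvalues after
decomposition are clamped to zero and the number of affected voxels is
reported in the `nClamped` slot, so silent data loss is visible. The
per-voxel eigendecomposition runs in compiled code (a batched symmetric
3×3 solver); tests verify it against base `eigen()` and verify the whole
fit against an independent `lm()`-based fit.

From the sorted eigenvalues the seven scalar maps are ADC
$(\lambda_1+\lambda_2+\lambda_3)/3$, axial $\lambda_1$, radial
$(\lambda_2+\lambda_3)/2$, FA, and the Westin shape coefficients
normalised by the trace: $c_l = (\lambda_1-\lambda_2)/\sum\lambda$,
$c_p = 2(\lambda_2-\lambda_3)/\sum\lambda$,
$c_s = 3\lambda_3/\sum\lambda$. This normalisation makes the three
coefficients an exact partition of shape ($c_l+c_p+c_s = 1$ wherever the
trace is positive), which is the property the downstream coherence
analysis relies on. Zero-trace voxels get 0 in all three shape maps and
are flagged rather than made NaN.

## 2. Brain extraction

`computeBrainMask()` operates on the iDWI (the mean of the weighted
channels; the unweighted reference is excluded because its contrast is
different): (1) min–max normalise to [0, 1]; (2) binarise at
`thresholdFraction` (default 0.05 — background in a high-SNR ex vivo
acquisition sits well below 5 % of the tissue maximum); (3) 3D
morphological closing to fill interior holes; (4) 3D opening to remove
isolated islands, followed by keeping the largest 26-connected component,
which makes "isolated islands were removed" explicit and testable.

The structuring element is the 6-connected unit ball applied
`closingRadius`/`openingRadius` times (default 1). No reference choice
exists for this element, so it is exposed in the configuration. One
consequence worth knowing: opening with the cross-shaped element shaves
the sharp edges and corners of a perfect cube, so the mask of a
synthetic cube is the cube minus its edge voxels — the test suite pins
this behaviour against a brute-force definitional oracle. Min–max
normalisation uses the full-volume extrema; a robust-percentile variant
was considered and rejected as a default because the phantom and fixed
ex vivo brains have no bright outliers, and the plain version is what the
5 % threshold is defined against.

Brain volume is the voxel count times the voxel volume; the
volume/birth-weight ratio is reported in mm³/g.

## 3. Global and regional statistics

`summarizeSubject()` averages each metric over brain ∧ valid voxels (the
conservative resolution of whether whole-brain summaries should include
voxels whose tensor fit failed — they do not), over white-matter masks
FA > t for t in 0.05…0.40 (step 0.05), and over ROI labels when a label
map is supplied (in DWI space, or with an affine applied by
nearest-neighbour). The reporting threshold is FA > 0.20, the value that
best discriminates white-matter structure in perinatal brain at this
resolution; the full sweep is always computed so the threshold choice can
be audited.

The two-sample layer (`twoSampleCompare`) gates on the Shapiro–Francia
W′ test at `alphaNormality = 0.05` (no reference value exists for the
gate level; it is configurable and the chosen branch is always recorded):
if both samples pass, a two-sided pooled-variance Student t-test;
otherwise the Mann–Whitney U with an exact p by full enumeration of rank
assignments for group sizes ≤ 9 (correct under ties) and the
tie-corrected normal approximation (no continuity correction) above.
Samples of n < 5 cannot be screened by W′ (its validity range starts at
5) and take the nonparametric branch. Group descriptives follow the
table convention: mean (sd) under the t branch, median (IQR) otherwise.
Missing scores are dropped pairwise, never imputed and never zero-filled.
Spearman correlations use mid-ranks and the t-approximation for p;
constant inputs yield a flagged undefined result. No multiple-testing
correction is applied to the global/ROI tables or the voxel maps — the
p-values are reported uncorrected by design, and the multi-template
consensus is the device used to control false positives spatially.

## 4. Voxel-based analysis

`buildStack()` brings per-subject maps to a template grid. Elastic
(diffeomorphic) registration is deliberately a *contract*, not an
implementation: the stage accepts precomputed affines or dense
voxel-displacement fields from established external tools, and
implements internally only identity (shared grids, exact for phantoms)
and a 12-parameter mutual-information affine (Nelder–Mead, staged
rigid-then-affine, trilinear resampling, 32-bin joint histogram).
Implementing demons-style warping here would duplicate mature external
machinery without adding testability.

Smoothing is a truncated discrete Gaussian (3×3×3 voxels, σ = 1 voxel by
default), renormalised to unit sum, and *masked*: weights are
renormalised over in-mask voxels so background zeros never bleed into the
brain. Because the kernel is truncated, smoothing twice is not exactly a
single pass at √2 σ; the tests document this as a stability property
rather than an identity.

`voxelwiseGroupTest()` is the pooled-variance t-test per voxel (no
per-voxel normality gate — at 10 subjects per group a voxel-wise gate
would be noise; a Mann–Whitney voxel-wise variant exists in the
statistics layer for users who want it), with significance masks at
uncorrected p < 0.01 and p < 0.05 (nested by construction) and a
direction volume. `voxelwiseCorrelation()` computes Spearman ρ per voxel
against a behavioural score; |ρ| > 0.2 is the conventional display
threshold and the p < 0.01 mask serves region reporting.

The analysis is repeated with each subject as registration template;
`multiTemplateConsensus()` keeps a voxel iff it is significant in at
least `consensusFraction` of the per-template results. "Consistently
across templates" is not quantified anywhere authoritative, so the
default is the strict intersection (fraction 1.0) and per-voxel support
counts are always emitted so any other fraction is recoverable after the
fact. The reporting grid — the space that hosts consensus output and the
correlation maps — is the first template in the list; on phantom data all
subjects share one grid, so this choice is cosmetic there.

## 5. The synthetic phantom

`defaultPhantomSpec()` builds the reference phantom on a 32³ grid of
0.35 mm voxels (a desk-scale stand-in for the 46×46×60 acquisition
grid): an ellipsoidal "brain" (semi-axes 13, 11, 10 voxels) of mildly
anisotropic grey matter with random per-voxel fibre orientation, two
white-matter tracts (cylinders along x and y, radius 3 voxels) with fixed
orientations, and a central spherical effect region (radius 8 voxels,
~36 % of the brain) in which the IUGR group's FA is reduced by
`deltaFA = 0.03`.

**Eigenvalue baselines.** Both tissues share trace 1.32×10⁻³ mm²/s (ADC
0.44×10⁻³, the regime of fixed tissue at high b-value); grey matter is
prolate with FA ≈ 0.127 and the tracts have FA ≈ 0.27. These were
calibrated once so the expected control whole-brain mean FA is 0.160 and
the IUGR mean 0.149 — the group means the phantom is designed to
emulate — and frozen.

**The FA reduction is trace-preserving.** In effect regions of IUGR
subjects, eigenvalue deviations from their mean are rescaled by the
closed-form factor
$s = \sqrt{3}\,\bar\lambda f / (d\sqrt{3/2 - f^2})$ (where $d$ is the
deviation norm and $f$ the target FA) so FA drops by exactly `deltaFA`
while the trace — hence ADC — is untouched. This mirrors the empirical
pattern the pipeline must be able to resolve: an anisotropy change
without a diffusivity change, with sphericity rising and linearity
falling in the same voxels.

**Between-subject variability** has four components, all multiplicative
on eigenvalues: a global diffusivity factor (sd 0.18 — ADC varies
substantially between fixed brains), a global anisotropy factor
(sd 0.03), independent per-region anisotropy factors (sd 0.05), and one
*shared* anisotropy factor (sd 0.07) across the white-matter tracts and
the effect region. The shared factor models coherent white-matter
maturation — the biological premise of the study design is exactly that
regional microstructure varies coherently between animals and carries
the behavioural association; without it, a score coupled to the effect
region would correlate with nothing else and the global white-matter
correlation analysis would have nothing to recover. Factors multiply
deviations from the eigenvalue mean, so they change FA but not ADC.

**Noise** is Rician (magnitude of the complex signal with i.i.d.
Gaussian noise on both channels; Gaussian available as an option), with
`noiseSigma = 0.005` relative to S₀ — the very high SNR of a long
ex vivo acquisition, and a level at which the image background stays
safely below the 5 % masking threshold.

**Behavioural scores.** The 13-item registry covers ordinal 0–3 scores,
the 0–10 righting-reflex count, line crossings, fore–hindpaw distance
(mm) and the olfactory latency (s). Coupled scores are drawn through a
Gaussian copula — latent = r·z(region FA) + √(1−r²)·ε with r the target
correlation (default: "head_turn" at 0.65 to effect-region FA) — then
discretised to the registry scale. Discretisation attenuates the
correlation; the achieved value is reported in the cohort object and a
warning is raised when it strays more than 0.2 from the target. Birth
weights are drawn per group (control 47.0 ± 9.3 g, IUGR 30.4 ± 12.2 g).

**What the phantom does not emulate**, and therefore what passing tests
do not show about real data: anatomically realistic neuroanatomy;
crossing-fibre voxels (single-tensor voxels only, so the fitted model is
exactly true — real brains violate it); within-region texture (region
eigenvalues are constant per subject, so the paper-style whole-brain
Westin profile, which reflects voxel-shape heterogeneity, is not
reproduced — the phantom's whole-brain sphericity is higher than real
tissue's); real between-subject variance structure (the phantom's
whole-brain FA sd across subjects comes out near 0.008, under-dispersed
relative to real cohorts, because larger coherent factors would swamp
voxel-wise detection of a 0.03 FA effect at n = 10 — with the study-size
cohorts this package targets, both cannot hold at once); and real
misregistration (phantom subjects share a grid, so the internal affine
registration is exercised near identity).

**Null-calibration condition.** The voxel-wise type-I checks run on a
zero-effect cohort with *all* between-subject factors set to zero, so
per-voxel values are independent pure-measurement-noise draws and the
p < 0.01 rejection rate can be held to binomial tolerance across brain
voxels. With the biological factors on, the marginal rate is unchanged
but voxels co-vary at region scale, and no single cohort can resolve the
rate at that precision — a property of correlated data, not of the test.

## 6. Numerical choices and degenerate inputs

- Exact Mann–Whitney enumeration switches to the normal approximation
  above group size 9 (`choose(18, 9)` = 48 620 assignments is the
  largest enumerated).
- Eigenvalue clamping (not voxel exclusion) is the default
  negative-eigenvalue policy; exclusion would bias regional means in
  low-SNR regions toward surviving voxels.
- The consensus requires all inputs on one grid and a named alpha level
  (0.01/0.05); mixing levels across templates is an error.
- Degenerate inputs are flagged, not silently dropped: constant scores
  (undefined ρ), zero-trace voxels, empty WM masks (warning), empty
  brain masks (error with diagnostics).
- Seeds: every generator entry point takes an explicit seed; cohort
  members derive child seeds via a rolling hash, keeping all seeds in
  32-bit range and all subject streams distinct.

## 7. Problem sizes used by the test suite

The suite exercises the full pipeline at the package's standard
desk-scale conditions: 32³ grids, 30-direction b = 3000 schemes, 10
subjects per group. The tensor round trip runs noiseless at full grid;
the shape-partition identity uses 10⁵ random SPD tensors; the normality
calibration uses 10 000 replicates; effect-localisation and
null-calibration each use one cohort with affine-registered
multi-template consensus (3 and 5 templates respectively); the
behaviour-coupling recovery averages 3 cohorts of n = 20 (a single
Spearman estimate at n = 20 has sampling sd ≈ 0.15, so the mean of three
replicates estimates the recovered coupling with usefully small
Monte-Carlo error); the generator-calibration check uses a 500-replicate
Monte-Carlo of true cohort means.

## 8. Known limitations

Beyond the phantom's idealisations (section 5): the affine registration
is same-modality and histogram-based, adequate for FA-to-FA alignment on
comparable grids but not a substitute for elastic registration of real
cohorts; the pipeline consumes external warp fields for that. ROI
delineation is out of scope — label maps are consumed, not drawn. The
uncorrected voxel-wise thresholds inherit the type-I burden of the
original design; the consensus reduces but does not formally control it,
and a permutation-based correction would be the natural extension.
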