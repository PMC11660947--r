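---
title: "Crossing-fibre-aware DTI-ALPS: model, phantoms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crossing-fibre-aware DTI-ALPS: model, phantoms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossalps)
```

## The ALPS index and why crossing fibres bias it

At the level of the lateral ventricle body, the perivascular spaces of the
deep medullary veins run along the left–right (x) axis, while the dominant
white-matter tracts run perpendicular to it: projection fibres
superior–inferior (z) and association fibres anterior–posterior (y). The
DTI-ALPS index exploits this geometry. With mean tensor diffusivities taken
from a 2 × 2-voxel ROI in each tract,

$$ALPS = \frac{D_{xx,proj} + D_{xx,assoc}}{D_{yy,proj} + D_{zz,assoc}},$$

x-diffusivity in excess of the fibres' radial diffusivity — attributed to
perivascular water movement — raises the index above 1. Under an axially
symmetric fibre model with radial diffusivity $D_{rad}$ and perivascular
diffusivity $D_{pv}$ added along x ($D_{xx} = D_{rad} + D_{pv}$,
$D_{yy,proj} = D_{zz,assoc} = D_{rad}$), the index reduces to

$$ALPS = 1 + D_{pv}/D_{rad},$$

implemented as `trueAlps()`. The catch is that a third, x-oriented fibre
population ("subcortical"/crossing fibres) mimics exactly the same signature.
Mixing a volume fraction $f_X$ of crossing fibres with axial diffusivity
$D_{xx,cross}$ into a site replaces the site diffusivities by linear
mixtures (`mixtureDiffusivities()`), and the measured ("apparent") index
becomes, when the crossing fibres' transverse diffusivities equal
$D_{rad}$ and the crossing is confined to a single site,

$$ALPS_X = ALPS + \frac{f_X}{2}\left(r - ALPS\right),
  \qquad r = D_{xx,cross}/D_{rad},$$

with the factor $f_X/2$ doubling to $f_X$ when both sites are affected
(`apparentAlpsClosedForm()`; the general mixture route is
`apparentAlps()`, and the two agree to machine precision whenever the
closed form's transverse assumption holds — a property the test suite
checks over 10^4 random configurations). Since coherent crossing fibres
have $r \approx 5$–6 while physiologic ALPS values are 1–2, the bias is
positive and large at small true ALPS; it vanishes at $ALPS = r$ and can in
principle turn negative beyond it. `biasSurface()` and
`relativeBiasCurve()` tabulate these relationships; the default grids
($f_X \in [0, 0.3]$, $r \in [1, 8]$, true ALPS $\in [1, 2]$) cover the
physiologic ranges and are implementation choices.

## Detecting crossing voxels

A single-tensor fit cannot represent two crossing populations: the middle
eigenvalue inflates relative to the lowest. The package flags voxels where
$\lambda_2/\lambda_3$ *strictly exceeds* 1.8 (`flagCrossing()`; a ratio of
exactly 1.8 is not flagged, and a non-positive $\lambda_3$ — possible in
noisy fits — is treated as flagged since such voxels are unusable either
way). Darkening flagged voxels in the FA-weighted direction-encoded colour
map (`decMap()`, `adjustDecMap()`) reproduces the adjusted maps used for
ROI re-annotation.

For two identical prolate tensors (axial 1.7, radial 0.3 µm²/ms) mixed at
equal fractions and crossing at angle $\theta$, the mixture eigenvalues are
$\{D_{rad} + (AD - RD)(1 \pm \cos\theta)/2,\ D_{rad}\}$, so the ratio grows
monotonically with the angle and crosses 1.8 at
$\theta_c = \arccos(1 - 2(t-1)RD/(AD-RD)) \approx 48.9°$
(`criticalAngle()`, verified against a 0.01°-step eigendecomposition sweep
in `crossingAngleSweep()`). Crossings shallower than ~49° therefore pass
undetected — consistent with the ~50° sensitivity limit quoted for
single-threshold crossing detection. The tensor parameters of this
simulation (AD = 1.7, RD = 0.3 µm²/ms, equal fractions) are typical
coherent white-matter values and are configurable.

## Tensor machinery and numerical choices

* **Units.** Diffusivities are µm²/ms throughout, so b = 1000 s/mm²
  equals 1.0 ms/µm² and all ALPS-relevant numbers are O(1). Converters sit
  at the I/O boundary (`readGradientScheme()` keeps b in s/mm²).
* **Fitting.** Ordinary log-linear least squares on
  $\log S = \log s_0 - b\,g^\top D g$ (`fitTensor()`,
  `fitTensorField()`): deterministic, exact on noiseless monoexponential
  data (round-trip residuals < 1e-14 in practice; the suite requires
  1e-8). Non-positive signals are clamped to a small positive floor before
  the log and the voxel is QC-flagged; fitted tensors are *not* forced
  positive semidefinite — negative eigenvalues are retained for ALPS
  arithmetic but QC-flagged, preserving auditability.
* **Eigen-decomposition.** Single tensors use base `eigen()` with a
  deterministic sign fix (largest-magnitude component positive). Whole
  fields use a vectorized closed-form (trigonometric) solution for
  symmetric 3 × 3 eigenvalues, verified against `eigen()` in the tests;
  degenerate (isotropic) tensors fall back to the trace.
* **Gradient schemes.** `makeScheme()` builds 30 directions at
  b = 1000 s/mm² plus one b = 0 by default (31 measurements), starting
  from a spherical Fibonacci lattice and refined by a fixed number of
  antipodally symmetric electrostatic-repulsion steps — fully
  deterministic, so identical arguments give identical schemes.
* **ROIs.** 2 × 2 in-plane squares at one slice, matching common ALPS
  practice. ROI means are taken on tensor components first and the ALPS
  ratio applied afterwards (not per-voxel ALPS averaged). Indices are
  1-based in memory and 0-based in the JSON/NIfTI file conventions.
  Hemispheres are processed independently; the package never averages
  bilaterally.

## Adjusted ALPS: relocation versus exclusion

Two adjustment modes are provided (`computeAlps()`):

* `adjust = "relocate"` (default): the ROI is moved, within the same slice
  and tissue label, to the same-shaped candidate with the fewest flagged
  voxels (`findCleanRoi()`; ties broken by distance to the seed, then
  lowest linear index). The relocated ROI represents a fresh annotation on
  the adjusted map and is measured like any other ROI — no voxels are
  excluded. This mirrors re-annotation workflows, where the adjusted index
  is computed from newly placed ROIs in the usual way.
* `adjust = "exclude"`: the ROI stays put and flagged voxels are dropped
  from the means, with the exclusion count reported. If every voxel is
  flagged the extraction refuses and asks for relocation.

When nothing is flagged, both modes agree exactly with the conventional
index.

## The synthetic phantom

`makePhantom()` builds a slab phantom of periventricular white matter: a
z-oriented projection slab and a y-oriented association slab per
hemisphere, a CSF border (3.0 µm²/ms isotropic), perivascular diffusivity
added to $D_{xx}$ throughout the fibre slabs, and optional x-oriented
crossing mixtures inside the 4 × 4 "annotation zones" where ROIs are
placed. Defaults: 16 × 12 × 3 grid at 2 mm isotropic, axial/radial fibre
diffusivities 1.7/0.3 µm²/ms, $D_{pv} = 0.15$ µm²/ms (true ALPS 1.5),
s0 = 100. Signals follow the monoexponential tensor model exactly; Rician
noise ($\sqrt{(S+n_1)^2 + n_2^2}$, SD $= s_0/\mathrm{SNR}$ at b = 0,
`addRicianNoise()`) is optional and fully seeded. The ground truth object
records the generating tensors, the crossing-voxel mask and the true ALPS,
so recovery and flag-accuracy tests need no external data.

Two crossing layouts exist: `"full"` (every zone voxel is a mixture at the
configured fraction — convenient for forward checks against the analytic
bias model) and `"lattice"` (a period-2 lattice so that any 2 × 2 ROI
inside the zone contains exactly one crossing voxel, making the effective
ROI-level fraction a quarter of the per-voxel fraction — the regime that
produces in-vivo-sized conventional-minus-adjusted differences of ~0.1
while each crossing voxel individually trips the 1.8 flag).

What the phantom does *not* emulate: realistic anatomy (ventricle shapes,
partial-volume gradients), susceptibility or motion artefacts, and spatial
noise correlations. Passing recovery tests therefore demonstrates
correctness of the estimator chain, not robustness to real-scanner
artefacts.

## The synthetic cohort

`makeCohort()` emulates a three-group movement-disorder study (HC n = 41,
PD n = 60, PSP n = 17 by default) with per-subject draws of $D_{pv}$,
$D_{rad}$ and crossing fraction, a small per-subject phantom, and an
annotation model that produces conventional and adjusted indices per
hemisphere. The defaults were calibrated once, before any acceptance
measurement, so that group-mean adjusted ALPS sits near 1.43/1.41/1.26
(HC/PD/PSP) and conventional-minus-adjusted differences near
0.12/0.10/0.05 — the PSP crossing fraction deliberately sits below the
flagging boundary, reproducing the weaker PSP adjustment effect. The
synthetic clinical score emulates a motor-severity scale (PD 10.7 ± 8.3,
PSP 37.8 ± 16.3) coupled to the subject's $D_{pv}$ at a configurable
correlation (0.5 in PSP by default).

Design choices that matter for the statistics:

* **Independent annotations.** The conventional ROI and the seed of the
  adjusted ROI are jittered independently within the annotation zone,
  emulating two separate manual annotation passes. Without this, a
  crossing-free cohort would yield bitwise-identical conventional and
  adjusted indices and paired tests would be degenerate.
* **Salience-triggered relocation.** The adjusted annotation relocates
  only when the darkening near the seed is salient (at least two flagged
  voxels in the seed's 4 × 4 neighbourhood); isolated noise-level dark
  voxels do not move the ROI, and when no clean candidate exists (an
  entirely dark region) the placement stays standard. This models how a
  human annotator reacts to visible, spatially coherent darkening rather
  than single-voxel noise.
* **SNR.** Cohort phantoms default to SNR 80 at b = 0: tensor fitting in
  such studies operates on denoised data, whose effective SNR is well
  above the raw-acquisition ~30. (Phantom-level recovery tests use SNR 30
  explicitly to characterise the raw regime.)
* **A caution on near-threshold biology.** Because the clean-fibre
  eigenvalue ratio equals $1 + D_{pv}/D_{rad}$ — the true ALPS itself —
  subjects whose true index approaches the 1.8 flag threshold darken
  without any crossing fibres, and any flag-reactive re-annotation then
  correlates negatively with the measured index. In cohort simulations
  with a realistic between-subject spread of $D_{pv}$ this inflates the
  apparent conventional-versus-adjusted difference even with no crossing
  inserts. This is a genuine property of threshold-based adjustment, worth
  keeping in mind when interpreting in-vivo adjusted-versus-conventional
  contrasts. For this reason the type-I calibration experiment in the
  acceptance suite fixes the between-subject biology (zero SDs at the HC
  means), which makes the conventional/adjusted contrast a pure
  measurement-noise null; the power experiment keeps the realistic
  spreads.

## Statistics

`groupSummary()` produces mean ± sample SD (n − 1) per
group × hemisphere × mode × measure. `pairedCompare()` is a two-sided
Wilcoxon signed-rank test with zero differences dropped (the standard
convention; all-zero input returns p = 1 with a note), exact null for up
to 25 untied non-zero differences and the continuity-corrected normal
approximation beyond. `spearmanCorrelation()` uses average ranks for
ties, the exact permutation null for n ≤ 10 without ties and the
asymptotic approximation otherwise; constant input yields an undefined
rho, returned as NA. Multi-group covariate-adjusted testing (MANCOVA and
friends) is deliberately out of scope: the cohort table is tidy CSV so any
statistics environment can consume it.

## Problem sizes used by the test and acceptance suites

Chosen to characterise the estimators well while keeping a full run
comfortable on a single CPU: tensor round-trips over 100 random tensors;
the mixture-versus-closed-form equivalence over 10^4 random
configurations; noise-floor Monte Carlo at 10^5 draws; pipeline recovery
over 20 noisy phantoms; paired-test power over 200 cohort replicates of
n = 40 and type-I calibration over 1000 replicates of n = 40, both on
single-hemisphere 16 × 12 × 1 phantoms.

## Known limitations

* The two-fibre simulation and the bias model assume axially symmetric
  populations with shared radial diffusivity; Eq.-style closed forms are
  exact only when crossing transverse diffusivities equal $D_{rad}$ (the
  general mixture route has no such restriction).
* The flag threshold (1.8) is an empirical constant; its interaction with
  high perivascular diffusivity is described above.
* Slice placement and anatomical localisation of the ventricle body are
  inputs (masks or coordinates), not computed.
* No denoising or motion/eddy/susceptibility correction: the pipeline
  expects preprocessed DWI volumes.
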