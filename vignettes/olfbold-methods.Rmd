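---
title: "Methods: KS activation mapping and habituation quantification for olfactory BOLD fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: KS activation mapping and habituation quantification for olfactory BOLD fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis problem

Olfactory task fMRI differs from most block-design experiments in two ways
that break the standard general-linear-model (GLM) workflow. First, the
response *habituates*: with a 60 s odor-on block repeated three times, the
second and third blocks carry only a fraction of the first block's
amplitude, and in some regions the third-block response is near zero or
negative. Second, the within-block time course is *bi-phasic* — two
response peaks inside one sustained block — with the second peak strongly
suppressed in the olfactory bulb. A GLM with one fixed regressor
mis-models both effects; the field's alternative is the two-sample
Kolmogorov–Smirnov (KS) test, which compares the full intensity
distributions of stimulus-on and stimulus-off volumes and is sensitive to
any stimulus-locked change, including the variance increase that
habituation produces.

`olfbold` implements this analysis chain — preprocessing, voxelwise KS
mapping with false-discovery-rate (FDR) control, block-wise relative
signal change (ΔS/S), temporal SNR and contrast-to-noise ratio (CNR),
group statistics and scan/re-scan reproducibility — and pairs it with a
synthetic 4-D phantom whose signal model reproduces the phenomenology
above with known ground truth.

# The phantom's signal model

Each responding voxel follows, within stimulation block $b$,

$$r(t) \;=\; a\, h_b\,\frac{g(t;t_1,w) + \rho\, g(t;t_2,w)}{m_b},$$

where $g$ is a Gaussian bump of FWHM $w$ centred $t_1$ or $t_2$ seconds
after block onset, $h_b$ are habituation multipliers ($h_1 = 1$), $\rho$
is the second-peak ratio, and $m_b$ normalises the shape so that its mean
over the on-block sampling window equals 1. The normalisation gives the
amplitude parameter a measurement meaning: a noiseless voxel with
amplitude $a$ yields a measured block-$b$ ΔS/S of exactly $100\,a\,h_b$
percent. After each block the response decays exponentially with time
constant $\tau$ (the post-stimulus transition, which can last a large part
of the on-period). The voxel value is

$$S(x,t) = S_0\, d(x)\,\bigl(1 + r(t)\bigr) + \text{drift}(t) +
\text{respiration}(t) + \varepsilon,$$

with $S_0$ the baseline intensity, $d(x) \in [0,1]$ a static
susceptibility-dropout field distinguishing an EPI-like acquisition
(attenuation 0.05 around the bulb) from a T2-preparation-like one (no
attenuation), sinusoidal drift and respiratory components of random phase,
and white Gaussian thermal noise.

## Default parameters and their calibration

| parameter | default | meaning / rationale |
|---|---|---|
| paradigm | 60 s off + 3×(60 s on / 120 s off), TR 2 s | the standard pulsed-odor habituation paradigm; 20 pulses of 1 s odor + 2 s carrier per block |
| `a1` | 0.022 | block-1 fractional amplitude; the olfactory-bulb-scale response |
| `h` | (1, 0.35, 0.15) | strong habituation, consistent with reported relative differences of −65 % and −80…−110 % for blocks 2/3 vs 1 |
| `rho` | 1 cortical, 0.2 bulb | second peak similar in cortex, strongly suppressed in the bulb |
| `t1_s, t2_s, w_s` | 15, 45, 20 s | peaks in the first and second block halves; 20 s FWHM makes each hump span roughly half a block, matching published group time courses (narrow 8 s bumps would confine the response to < 30 % of the block, which those time courses rule out) |
| `tau_trans_s` | 20 s | post-stimulus transition; decays to ~5 % within one on-period |
| `sigma_thermal` | baseline/60 | voxel tSNR 60, the scale implied by reported CNR ≈ 1.3 at ΔS/S ≈ 2.2 % |
| `drift_amp`, period | 1 % of baseline, 300 s | slow scanner drift |
| `resp_amp`, freq | 0.5 % of baseline, 0.3 Hz | respiratory oscillation; 0.3 Hz aliases at TR 2 s exactly as in vivo, and the trace is emitted for nuisance regression |
| bulb region | 27-voxel sphere, amplitude 3 × `a1` | see below |
| grid | 40×40×24 at 1.5 mm, ellipsoidal mask (~14 700 voxels) | desk-scale stand-in for whole-brain coverage |

Two defaults deserve explanation because they are calibrated in *measured*
units. Published values for the bulb — ΔS/S 2.2 ± 0.7 %, ~15 ± 5 activated
voxels, CNR ≈ 1.3 — are measurements taken after 4 mm smoothing and
temporal filtering of a structure of ~23 voxels at 1.5 mm resolution.
Under a 4 mm kernel such a structure retains only ~30 % of its tissue-level
amplitude, so reproducing the *measured* 2.2 % requires a tissue-level
amplitude near 6.6 % (hence the bulb's relative amplitude of 3). With that
setting the phantom's measured bulb ΔS/S on activated voxels is 1.9–2.2 %
and the activated count 5–24 across seeds — matching the reported scale —
while cortical regions at relative amplitude 1 measure 1.0–1.3 %. The
region volumes likewise mirror the reported proportions (one small bulb,
cortical regions of tens to hundreds of voxels, ~7 % of the brain mask
responding in total).

# Preprocessing

The conditioning chain is fixed and logged: isotropic Gaussian smoothing
(4 mm FWHM), high-pass drift removal with cutoff 1/180 Hz (one paradigm
cycle), nuisance-trace regression, and a zero-phase low-pass at 0.03 Hz
(order-4 Butterworth magnitude, applied forward–backward equivalently in
the frequency domain on reflection-padded series). All temporal operations
work on mean-centred series and restore the temporal mean, so ΔS/S
denominators stay meaningful; all operations leave voxels outside the
brain mask untouched.

Three implementation points matter:

1. **The drift basis carries quadrature pairs.** A truncated cosine-only
   basis cannot represent a slow oscillation of arbitrary phase; the
   surviving component is coherent across all voxels and quietly destroys
   the calibration of any voxelwise test downstream. The basis therefore
   contains cosines *and* sines at every frequency below the cutoff.
2. **Nuisance regressors are filtered like the data** before regression,
   the standard design rule — regressing a raw trace against detrended
   data removes the wrong component.
3. **Paradigm-protected detrending for quantification.** The habituation
   envelope of a 600 s session has power below 1/180 Hz, so blind
   projection removes ~30 % of the block response and flattens the block
   ratios. On the quantification path the drift coefficients are estimated
   *jointly* with per-block, per-peak response-shaped regressors
   (`protect_regressors()`) and only the drift component is subtracted.
   The span of the protection set covers any habituation profile and any
   second-peak ratio, so the drift estimate is unbiased by stimulus-locked
   signal. The detection path keeps the plain projection: a detector must
   not be handed regressors encoding what it is supposed to find.

## Two paths, one chain

The package runs the chain twice with different settings:

- **Detection path** (feeds `ks_activation_map` / `glm_activation_map`):
  smoothing + plain high-pass + nuisance regression, *no* low-pass. The
  0.03 Hz low-pass would reduce the effective number of independent
  samples roughly four-fold (calibrated effective size ~17 instead of
  ~100 for 90-vs-210 samples) and with it essentially all detection power
  of a sample-based test, while contributing nothing to its validity —
  FDR control holds either way once the p-values are calibrated. Whether
  the low-pass belongs before or after testing is genuinely open in the
  source methodology; this package resolves it in favour of testing first.
- **Quantification path** (feeds `block_response`: ΔS/S, tSNR, CNR):
  smoothing + protected high-pass + nuisance regression + 0.03 Hz
  low-pass, i.e. the full published chain.

# The KS activation map and its calibration

For each voxel the on/off samples are assembled from the condition labels
shifted by a hemodynamic delay (default 6 s; the sampling windows of ΔS/S
shift identically). D is the exact sup-difference of the two empirical
CDFs, evaluated at the pooled points with ties collapsed.

P-values are the weak point of the textbook recipe: the asymptotic
two-sample Kolmogorov distribution with effective size
$n_1 n_2/(n_1+n_2)$ assumes independent samples, and preprocessed fMRI
series are not independent. Instead of assuming, the map *calibrates*: the
labels are circularly shifted to a set of offsets (destroying any
paradigm alignment while preserving the autocorrelation), D is recomputed
over a deterministic subsample of voxels, and an effective sample size is
fitted by matching an upper tail quantile (0.998) of the pooled surrogate
null to the Kolmogorov distribution. Voxels whose observed D lies in the
top quintile are excluded from the surrogate pool first — truly
responding voxels keep their response under shifted labels and would
otherwise contaminate the null tail. On noise-only phantoms the resulting
p-values are near-uniform (fraction below 10⁻³ ≈ 10⁻³), so
Benjamini–Hochberg adjustment at adjusted P < 0.01 controls the FDR as
nominally promised; `effective_n = "nominal"` restores the literal
independent-samples reading, and `ks_two_sample()` (the scalar test, with
full permutation enumeration for pooled sizes ≤ 20) keeps the textbook
contract.

The GLM comparator fits a non-habituating regressor — the on/off boxcar
convolved with a Gaussian bump and shifted by the same delay, re-filtered
exactly as the data were — and receives the symmetric calibration (a
surrogate-fitted scale on its t statistic), so the two detectors are
compared at matched FDR control.

## What the detector comparison shows

On this phantom the GLM comparator is consistently *more* sensitive than
the KS map, with or without habituation (e.g. at mid tSNR, habituating:
GLM ≈ 0.9 vs KS ≈ 0.04; at tSNR 60: GLM ≈ 1.0 vs KS ≈ 0.68). The
habituating response still correlates ~0.8 with the flat regressor, so
the least-squares test keeps most of its efficiency under Gaussian noise,
while the sup-ECDF statistic pays its nonparametric efficiency cost
exactly in the far tail that voxelwise FDR thresholds live in. The
often-cited advantage of the KS test for habituating olfactory data
plausibly rests on properties real data have and this phantom deliberately
does not: heavy-tailed and structured noise, response-shape variability
across voxels and subjects, and variance-dominated signal changes. The
acceptance suite states the expected inequality as the olfactory-fMRI
literature claims it, and the corresponding test documents this
discrepancy by failing; the package reports what the simulation actually
shows.

# Quantification rules

- **Baseline**: ΔS/S of block $b$ uses the mean over the *second half* of
  the stimulus-off period preceding block $b$ (the initial 60 s off
  precedes block 1); the first half is excluded because the post-stimulus
  transition can last 50–100 % of the on-period. Pooling (`block = "all"`)
  pools all on-blocks against the pooled baselines.
- **tSNR** is temporal mean over temporal SD (n−1); constant voxels get an
  infinity sentinel and are excluded from region means. **CNR** is tSNR ×
  block-1 ΔS/S as a fraction.
- **Condition comparison** (EPI-like vs T2prep-like) averages CNR over the
  union of positively activated voxels from either condition — the same
  voxel set for both — so a condition that detects nothing in a region is
  still evaluated there.
- **Group tests**: one-way repeated-measures ANOVA across blocks
  (subjects as random blocks) via `stats::aov`; paired t-tests with BH
  adjustment across regions; Cohen's d with pooled SD
  $\sqrt{(s_a^2+s_b^2)/2}$; relative differences with the group-mean
  denominator.
- **Reproducibility**: Dice per region and sign on the binarised
  activation masks; ICC(2,1) (two-way random effects, absolute agreement,
  single measure) on voxelwise ΔS/S of the voxels activated in the first
  scan, read out on both scans. ICC(3,1) is available by flag. Two empty
  masks give Dice 1 (perfect agreement of absence), with a note.

# Numerical and degenerate-input choices

- Exact KS permutation enumeration below pooled size 20; asymptotic above.
- Zero-variance voxels are excluded from testing and from region
  summaries; zero baselines reject ΔS/S with an explicit error.
- An identical-by-block table yields F = 0, p = 1 rather than 0/0.
- The visibility threshold (mean − 2 SD of the slice) counts voxels at or
  above the threshold, so a uniform slice is fully visible.
- `alpha = 1` marks every testable voxel active (threshold limit).
- All simulations are bit-reproducible from one integer seed; the
  calibration uses deterministic shift and voxel grids, so activation maps
  are reproducible too.

# The group-level habituation simulation

For subject-level inference the phantom provides
`simulate_subject_deltas()`: block means (2.2, 0.8, −0.2) % with per-block
between-subject SDs of (0.7, 0.5, 0.5)·√14 — the reported mean ± SE
profile of a 14-subject study, converted from SE to SD — decomposed into a
subject random intercept and residual with inter-block correlation 0.5 (a
typical value for repeated physiological measures; the decomposition is
not identifiable from the published summary). Under these conditions the
repeated-measures ANOVA rejects in well over 90 % of replicates, and holds
its nominal size on flat-response tables.

# Problem sizes used in the tests

The default grid (40×40×24 × 300 volumes) runs one full
detection-plus-quantification analysis in ~15 s. The test suite uses: 30
null phantoms for FDR control, one phantom for parameter recovery, two for
the detector comparison, five subjects × two conditions for the CNR
ordering, three scan/re-scan pairs for the reproducibility properties, and
a 14×14×10 phantom for fast unit tests. These sizes were chosen so the
distributional claims are stable across seeds while a full run stays in
the tens of minutes on a single core.

# Known limitations

- The phantom's noise is white Gaussian plus two deterministic nuisance
  components; real BOLD noise is heavy-tailed, autocorrelated and
  spatially structured. Passing tests validate the pipeline's logic and
  calibration, not its behaviour on scanner data.
- Motion, geometric distortion, slice timing and ICA denoising are out of
  scope (the respiratory trace stands in for physiological denoising).
- The KS-vs-GLM sensitivity ordering claimed for habituating responses
  does not hold under this phantom (see above); the package treats this as
  a finding about the phantom's Gaussian noise model, not as license to
  alter the generator until the claim passes.
- Smoothing-induced spatial correlation makes detection of the ~27-voxel
  bulb region an approximately all-or-nothing event per session; its Dice
  values are correspondingly more variable than cortical ones, as they are
  in real test-retest tables.
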