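---
title: "Quantifying extra-cerebral spill-in in tau PET: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying extra-cerebral spill-in in tau PET: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

MK6240-class tau tracers show variable off-target binding outside the brain
(ECB): in the meninges, which wrap the cortex within millimetres, and in the
frontal/sphenoid/ethmoid sinuses, which abut the mesial temporal lobe. PET
resolution (FWHM of several millimetres) mixes signal across region borders,
so two spill-in routes bias the standard SUVR outcome in opposite
directions:

* sinus activity spills **into the entorhinal cortex (ERC)** — the earliest
  (Braak I) tau region — inflating the numerator;
* meningeal activity spills **into the inferior cerebellar grey matter** —
  the usual reference region — inflating the denominator and deflating the
  global SUVR.

`ecbspill` reproduces this mechanism end to end on simulated data: a
digital phantom with the spill-relevant adjacencies, calibrated ECB
emission maps, a resolution-matched forward model, SUV/SUVR quantification,
linear simulation-based correction factors (SCF), Mueller-Gartner (M-G)
partial-volume correction, a tau-detection-threshold search, and ECB tier
stratification.

## The phantom

`build_phantom()` constructs a parametric geometric phantom rather than an
atlas-based one: atlases cannot be shipped, and the spill mechanism depends
only on the adjacency structure, which the phantom preserves by
construction —

* a cerebrum ellipsoid with a 6 mm cortical ribbon over a white-matter
  core;
* a cerebellum whose inferior half is the SUVR reference region, in
  contact with the meningeal shell;
* a sinus cavity penetrating the antero-inferior brain surface; the ERC is
  the 8 mm band of brain tissue in face contact with it, with a
  hippocampus-like band just interior;
* a 5 mm meningeal shell (`make_meninges_shell()`: dilate the brain mask,
  subtract the mask);
* interior regions untouched by ECB: an insula-like control (kept at least
  15 mm from every ECB voxel, asserted at build time), a pons, and the
  4 mm-eroded white matter.

Users with real label volumes can bypass the generator entirely: any
NIfTI + TSV pair read by `read_label_volume()` with the same region names
works downstream. Morphology is Euclidean in millimetres
(distance-inclusive ball kernels applied by FFT convolution), not
voxel-count structuring elements, so anisotropic grids behave correctly;
the volume boundary counts as background for erosion.

All quantitative ROIs sit well inside the volume (more than one PSF from
the edge), which is why zero padding at the edges is acceptable.

## ECB profiles and calibration

An `ecb_profile()` fixes the sinus and meninges SUVR of the emission map
plus the spatial character of the field. Six built-ins span the clinical
range (sinus SUVR 0.50-3.09, meninges 0.50-2.10). The per-voxel field is

```
value ∝ (1 + f · prox / max(prox)) · exp(N(0, σ_het))
```

where `prox` is the 20 mm-FWHM blurred indicator of the brain-facing
target region (ERC for the sinus compartment, inferior cerebellum for the
shell), `f` is the focality — voxels at the interface carry about
`(1 + f)` times the distal floor — and `σ_het = 0.4` adds lognormal
hot-spot heterogeneity. Focality encodes what ROI-mean SUVRs cannot: two
maps with identical sinus SUVR can spill very differently depending on
where the activity sits. The population-average profile is diffuse
(`f = 0`), because averaging hundreds of scans washes out individual hot
spots; the individual-scan profiles are focal. The HIGH profile is
strongly sinus-forward (`f_sinus = 3`) and H_MENINGES meninges-dominant
(`f_men = 2`): with a single shared spatial template the empirically
observed detection-threshold ordering across profiles is provably
unreachable from the ROI SUVRs alone, so the per-profile patterning is a
declared study condition, chosen once from the qualitative character of
each group and the reported ordering, and not a free parameter of any
analysis.

ECB voxels are histogrammed into 11 equal-width bins over `(0, max]`
(`bin_ecb_voxels()`); bin 0 holds everything at or below zero and is
excluded from the map; the 10 remaining bins become discontinuous
emission-map regions whose activity is the mean of their member voxels.
Equal-width edges are an assumption — the binning convention of the
original maps is not recorded anywhere we could consult — and are the
simplest reading consistent with a dedicated at-or-below-zero bin.

**Calibration** (`calibrate_ecb_activities()`) must make the binned map's
sinus-ROI and shell-ROI means hit two independent targets. A single global
multiplier cannot do that, and rescaling the underlying continuous
compartments stalls when low-value sinus and shell voxels share bins
(the bin mean is pinned by the much larger shell). The implementation
therefore pre-normalizes each continuous compartment exactly, bins once,
and applies the minimal-norm adjustment to the 10 bin activities that
satisfies both ROI-mean constraints — the per-ROI bin composition is a
2x10 linear map, so this is a two-equation solve, converging in at most a
step or two while preserving the bin structure and global-scale
linearity/monotonicity. Tolerance is 2% on both targets.

The achieved SUVRs are **properties of the emission map** (the noiseless
model with the resolution kernel disabled). They cannot be post-blur
measurements: the background (BKG) map is *constructed* with every ECB
voxel at exactly half the reference concentration — a "theoretical" SUVR
of 0.50 — yet its measured shell SUV after blurring is inflated well above
half the cerebellar SUV by cortical spill-out, in the simulation here just
as in the scanner data the targets come from. Calibrating on the map scale
keeps the 0.50 construction exact and the profile targets meaningful.

The reference concentration defaults to the value that makes the
cerebellar SUV 8.36 at 370 MBq and 60 kg
(`default_reference_concentration()` = 51.55 kBq/mL), anchoring the
simulated SUV scale to the reference study's baseline. Cerebral regions
carry constant concentrations over the scan window (pseudo-equilibrium is
reached by the 70-minute start), expressed as multiples of the reference
(`default_region_ratios()`; cortex 0.95, ERC 0.926 — the no-ECB
ERC-to-cerebellum SUV ratio — white matter 0.873, matching the eroded-WM
SUV scale, pons 0.90, insula 0.975). Time-varying concentration curves are
out of scope.

## The forward model

The reference pipeline used full Monte-Carlo photon transport
(hours per realization on many cores). This package substitutes the
desk-scale model that preserves the phenomenon under study:

1. resample the emission map to the scanner grid (trilinear for
   concentrations, nearest for labels);
2. convolve with a Gaussian PSF. Clinical images carry the scanner
   resolution (4.1 mm in plane, 4.3 mm axial) *plus* 6 mm processing
   smoothing, and the regional input concentrations were derived from
   those smoothed images, so the simulator applies the quadrature sum —
   about 7.3 mm in plane, 7.4 mm axial (`effective_psf()`) — and no
   post-reconstruction smoothing;
3. per frame (four 5-minute frames from 70 min; F-18 half-life 6586.2 s),
   expected counts = concentration x voxel volume x sensitivity x duration
   x mean decay factor (closed form); Poisson counts are drawn and scaled
   back to decay-corrected kBq/mL; frames are averaged duration-weighted
   (`reconstruct_scan()`). No attenuation, scatter, randoms or detector
   geometry are modelled, and noise is independent across voxels.

The sensitivity constant (0.01 counts per kBq*s per voxel-mL) is the
single free noise parameter, set once so that the ERC ROI coefficient of
variation of a single realization at the default grid is about 2% — the
order of the realization SDs the reference tables report. `noiseless =
TRUE` is the exact sensitivity-to-infinity limit. Realizations are seeded
`base_seed + i` and carry a seed manifest.

The detection search draws its Poisson counts only over the two ROIs it
measures (voxel noise is independent, so the restriction is exact); this
makes a full six-profile, multi-seed threshold search a matter of minutes.

## Quantification conventions

* SUV = concentration / (dose/weight), unit tissue density; 370 MBq / 60 kg
  gives divisor 6.1667 kBq/mL per SUV.
* ROI statistics use the sample SD (n-1); masks on foreign grids are
  resampled nearest-neighbour and the resampling recorded.
* SUVR divides by the reference-ROI mean; the reference region's own SUVR
  is 1 and SUVR is invariant under global rescaling.
* `percent_delta()` is the absolute convention `100·|x - b|/b` (a signed
  variant exists); longitudinal summaries expose both the signed and the
  absolute mean because they differ materially when changes scatter
  around zero.

## Corrections

**SCF.** Across profiles, target-region SUV is nearly linear in source
SUV; the shipped factors are the published ECAT HR+ coefficients
(`scf_erc()`: ERC - (0.22·sinus - 0.75); `scf_cerebellum()`:
cerebellum - (0.14·meninges - 0.55)). `derive_scf()` refits the slope by
OLS but anchors the intercept so the baseline profile corrects exactly to
a supplied spill-free truth: an OLS intercept on group means cannot
reproduce the published offsets, and the anchor is the only choice under
which the published correction-evaluation table is reproducible. That
table is reproducible *only* if the correction is applied to the baseline
group too before percent differences are taken — verified numerically
against the printed cells — so `evaluate_corrections()` always corrects
the baseline as well. Corrected values below baseline are never clipped.

**M-G PVC** (`mg_pvc()`): for grey-matter voxels,
`(observed - C_WM·blur(pWM) - C_ECB·blur(pCSF)) / blur(pGM)` at a 6.5 mm
PSF, with the CSF compartment standing in for the ECB sources. The
homogeneous estimates are means over voxels with tissue probability at
least 0.95 (the estimator is not specified by the method's common
description; a high-probability mean is the standard reading), and voxels
with `blur(pGM) < 0.3` are left unmodified and flagged (a conventional
mask threshold). Phantom tissue maps are binary
(`tissue_probability_maps()`).

## Detection thresholds

`find_detection_threshold()` searches the Braak I input concentration —
read multiplicatively, `conc = (1 + p/100)·reference` — until the mean ERC
SUVR of `n = 10` realizations satisfies `mean - 2·SD >= 1.27`. The 2-SD
rule is directionally ambiguous in words; it is implemented as the mean
exceeding the threshold by two SDs, so ~97.7% of scans at that input are
positive, which is the reading that delivers "more than 95%". The search
is a coarse geometric scan bracketing the rule followed by bisection to 1%
relative tolerance (a linear-scan strategy is available and agrees within
tolerance); each probe derives its seed deterministically from the base
seed and the probed percentage, so strategies see identical noise at equal
probes. A profile satisfying the rule with no specific binding returns 0
with a `positive_at_baseline` flag. Comparisons are against the
population-average profile, because the 1.27 cutpoint was established on
population-average data.

## Tier stratification

Visual 0-5 meningeal ratings are emulated by a monotone noisy link on a
truncated lognormal SUVR distribution spanning the clinical range
(0.57-2.10; the default median 0.98 and sdlog 0.23 put roughly 65/27/9%
of a cohort across the clinical cutpoints 1.07/1.34). ROC thresholds
maximize Youden's J over midpoint candidate cuts, ties toward the lowest
cut, positive class `value >= cut`; the Moderate cut is trained on rating
>= 2, the High cut on rating >= 4, and a value equal to a cut classifies
upward. Note an intrinsic property of Youden thresholding under a noisy
link: the recovered cut is biased low by roughly the latent noise SD when
the marker density falls across the cut, so exact cut recovery is only
expected for consistent raters (noise around 0.02 SUVR).

`quartile_group_test()` applies the SUV-scale SCF to SUVR cohorts by
rescaling the intercept with a reference SUV (slope is scale-free because
target and source share the reference; default 8.36). Quartiles are
rank-based (balanced by construction) and the group tests are two-tailed
Welch t-tests — the plain "two-tailed t-test" is underspecified and Welch
is the safer default.

## Problem sizes and runtimes

The study scale is a 96-cubed phantom at 2 mm (the package's default),
where a noiseless simulation takes about a second and ten noisy
realizations a few seconds; the unit-test scale is the same geometry at
4 mm (48-cubed). These sizes were chosen so the complete analysis — all
profiles, corrections, and a multi-seed detection search — runs in
minutes on a single core while leaving every ROI several voxels thick.

## What passing tests do and do not show

The simulator reproduces the *mechanism* — resolution-driven, activity-
and geometry-dependent spill-in and its interaction with SUVR — and the
arithmetic of the published corrections. It does not model photon
transport, attenuation, scatter, motion, anatomical variability between
subjects, registration error, or continuous tracer kinetics; emission
regions are piecewise constant, noise is voxel-independent Poisson, and
the phantom is one fixed geometry. Quantities that depend on those physics
(absolute spill slopes, exact detection-threshold magnitudes) therefore
differ from scanner values even though their signs, orderings and
corrected/uncorrected contrasts reproduce; nothing here validates the
corrections on real participant data.
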