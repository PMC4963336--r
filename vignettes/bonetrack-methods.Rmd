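---
title: "Quantitative longitudinal bone SPECT/CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative longitudinal bone SPECT/CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bonetrack)
```

## The problem

Skeletal metastases of breast and prostate cancer are routinely monitored
with bone scintigraphy. Whether a lesion is progressing or regressing is
usually decided by eye, comparing two scans months apart — a subjective
exercise with substantial inter-reader variability. Modern quantitative
SPECT/CT reconstructions, calibrated to absolute activity concentration
(kBq/mL), allow the same question to be answered numerically: measure the
standardized uptake value (SUV) of each lesion at both time points, compute
the fractional change, and classify it against a fixed threshold, exactly
as PERCIST does for FDG-PET.

`bonetrack` implements that workflow end to end, together with the
agreement statistics needed to compare classification sources (two human
readers, two imaging modalities, or visual versus quantitative reading),
and a synthetic phantom generator so that every stage is testable without
patient data.

## The quantification model

### From counts to SUV

A calibrated, fully corrected (attenuation, scatter, resolution) SPECT
reconstruction registers, in a voxel of volume $v$ mL containing activity
concentration $C_{acq}$ kBq/mL, an expected count

$$\lambda = C_{acq} \cdot v \cdot S \cdot T,$$

where $S$ (counts s$^{-1}$ per kBq) is the camera calibration factor and
$T$ (s) the dwell time. Quantification inverts this relation and then
decay-corrects to injection time,

$$C_{inj} = \frac{\text{counts}}{v\,S\,T} \cdot 2^{\Delta t / T_{1/2}},
\qquad \Delta t = t_{acq} - t_{inj},$$

so that studies acquired at different delays after injection are
comparable. All SUVs in this package are therefore referenced to injection
time (the convention of the quantitative bone-SPECT literature, unlike the
scan-time convention common in PET). The body-weight SUV under a 1 g/mL
density convention is

$$\mathrm{SUV} = \frac{C_{inj}\,[\mathrm{kBq/mL}] \cdot W\,[\mathrm{g}]}
{A_{net}\,[\mathrm{kBq}]},$$

with the net injected activity obtained by decaying the prepared syringe
activity and the post-injection residual activity each to injection time
and subtracting:

$$A_{net} = A_{prep}\, 2^{-(t_{inj}-t_{prep})/T_{1/2}}
 - A_{res}\, 2^{-(t_{inj}-t_{res})/T_{1/2}}.$$

Defaults: half-life 360.4 min (Tc-99m), calibration factor 10 counts/s per
kBq, dwell 15 s — all configurable per `acquisition_meta()`.

### VOI metrics

Lesions and reference regions are axis-aligned ellipsoids in world mm
coordinates; a voxel belongs to a VOI when its centre satisfies
$\sum_i ((x_i-c_i)/a_i)^2 \le 1$. Centre-inclusion membership (no partial
volumes) keeps every mask deterministic and brute-force verifiable.

* `suv_mean`, `suv_max`: arithmetic mean and maximum over the mask.
* `suv_peak`: mean over a 1 mL sphere (radius $(3V/4\pi)^{1/3} \approx$
  6.204 mm) centred on the hottest masked voxel, clipped to the grid but
  not to the VOI.

Two numerical choices deserve comment:

* **Sphere shape and placement.** The peak sub-volume is specified only as
  "1 cm³"; we use a sphere centred on the VOI maximum, matching the
  PERCIST SUV_peak convention the clinical classification borrows from.
  Whether the sphere must stay inside the VOI is likewise unstated; we let
  it extend beyond (a thin shell constraint would make the metric depend
  on VOI drawing margins).
* **Ties for the hottest voxel.** In noise-free phantoms every voxel of a
  homogeneous lesion ties for the maximum. Seeding at the first tied voxel
  in storage order would park the sphere at the lesion *edge* and report a
  peak far below the lesion value. Among tied maxima we therefore seed at
  the voxel whose sphere average is greatest (the placement that maximizes
  the reported peak, as PERCIST intends), breaking remaining ties by
  lowest column-major linear index. With this rule a homogeneous lesion
  that contains the sphere reports exactly its own value, and
  `suv_mean <= suv_peak <= suv_max` holds on homogeneous and smooth
  unimodal uptake. Note that the ordering `suv_mean <= suv_peak` is *not*
  a theorem for arbitrary noisy volumes under max-centred seeding (a hot
  isolated voxel in a cold corner of an otherwise warm VOI violates it);
  only `suv_peak <= suv_max` is unconditional.

### Uptake ratios

Dividing a lesion's SUV_peak by the SUV_mean of a healthy vertebral
spongeous-bone reference region of the same time point cancels global
fluctuations of bone metabolism (hydration, renal clearance, systemic
therapy effects). Ratio-mode classification is invariant to any
per-time-point global rescaling applied to lesion and reference alike —
a property the test suite checks explicitly.

## Classification

With $v_1, v_2$ the lesion values (SUV_peak, or peak/reference ratio) at
the two time points and $\delta = (v_2-v_1)/v_1$:

* $\delta > +0.30$: progressive
* $\delta < -0.30$: regressive
* otherwise: stable.

The threshold is configurable; 0.30 is the default applied throughout the
source study's tables (its methods text also motivates a 25 % significance
level via RECIST/PERCIST, a discrepancy we record but do not resolve).
The inequalities are strict: a change of exactly ±30 % is stable, a
literal reading of the ">30 %" wording. Lesions without a reference region
at either time point are excluded from ratio mode with a message (in the
source cohort, 46 of 52 lesions had references).

## Agreement statistics

For two sources rating the same $n$ lesions into $k$ categories, Cohen's
kappa is

$$\kappa = \frac{p_0 - p_e}{1 - p_e}, \qquad
p_0 = \frac{\mathrm{trace}}{n}, \qquad
p_e = \sum_i \frac{r_i c_i}{n^2},$$

with $r_i, c_i$ the marginal counts. Because the unweighted $\kappa$
depends only on the marginals and the number of agreements, it can be
reconstructed *exactly* from published summary tables that print, per
method, the three category tallies and the count of discrepant lesions:
`kappa_from_marginals()` implements this path and is provably identical to
`kappa_from_table()` for any table with those marginals and diagonal sum
(a property the suite verifies on 1,000 random tables). The bundled
fixture `load_reader_tallies()` carries the per-reader tallies of a
two-reader study of 52 metastatic bone lesions (46 in ratio mode), from
which `inter_method_agreement()` reconstructs four aggregated
visual-versus-quantitative kappas (0.42, 0.62, 0.40, 0.44 at 2 dp).

Verbal interpretation follows the Landis–Koch strata, applied to the
unrounded $\kappa$ with inclusive upper bounds: below 0 poor, 0–0.20
slight, then fair, moderate, substantial, and almost perfect above 0.80.
A large-sample (Fleiss) standard error under independence supplies a
two-sided test of $\kappa = 0$; it is reported alongside but not used for
any reconstruction. The inter-*observer* kappas printed by the source
study (0.46, 0.35, 0.94, 0.87) are not reconstructible from its published
tables — no inter-reader discrepancy counts exist — and are deliberately
not asserted anywhere.

Supporting statistics: `mann_whitney_u()` computes the midrank U with an
exactly enumerated two-sided p-value when the smaller sample has at most 8
observations and the pooled sample is small enough to enumerate (n ≤ 30),
falling back to the tie-corrected normal approximation without continuity
correction; `spearman_rho()` delegates to the t-approximation of
`stats::cor.test`. Published percentages are reproduced with
`format_percent()`, which truncates at the printed precision (the source
tables print 11/52 = 21.15 % as "21.1 %").

## The phantom generator

The generator emulates the structure of the study the package targets: a
subject with up to six ellipsoidal lesions and one reference vertebra on a
64³ grid of 2.4 mm isotropic voxels (near clinical SPECT resolution, small
enough for desk-scale tests), two time points, Poisson counting noise, and
stochastic readers.

Default parameters are the study conditions and are not tuning knobs:
baseline lesion SUV 20.4 with a configurable true fractional change per
lesion; reference SUV_mean 5.6 (TP1) and 4.9 (TP2); soft-tissue background
SUV 1.0 (a typical soft-tissue level, chosen once); subject weight 75 kg;
injected activity 573 / 542 MBq; acquisition 231 / 234 min after
injection; weight constant across time points.

The forward model paints target SUVs with precedence lesion > reference >
background (lesions replace marrow uptake; a lesion overlapping the
reference boundary takes the lesion value), converts to injection-time
concentration by inverting the SUV definition, decays forward to
acquisition start, scales to expected counts, and draws Poisson noise
under an explicit seed (bitwise reproducible; the caller's RNG state is
untouched). Overlapping lesions are an error naming the colliding ids;
more than six lesions per subject violates the emulated study design and
is rejected.

**What the phantom does not emulate.** No projection/sinogram domain, no
OSEM reconstruction, no attenuation/scatter/PSF (the simulation starts in
the already-corrected calibrated image domain where quantification
operates), no intra-lesion heterogeneity (lesions are homogeneous by
default), no VOI misplacement between time points. Consequently, passing
tests demonstrate the correctness of the quantification, classification
and agreement machinery — not robustness to reconstruction artefacts or
reader VOI variability, which in real data are substantial (the study's
lesions show SUV_max/SUV_peak ≈ 1.8, i.e. marked heterogeneity). One
visible consequence: with Poisson noise on a small *homogeneous* lesion,
the hottest voxel is uniformly located within the lesion and the 1 mL
peak sphere then averages in surrounding background, biasing SUV_peak low.
This is a property of the homogeneous-phantom geometry, not of the
quantification chain, which is why the acceptance script measures lesion
SUV_peak through the noiseless chain and uses the noise-robust
reference-region SUV_mean (an average over the whole vertebra VOI) to
demonstrate quantification from noisy counts.

Simulated visual readers are 3×3 row-stochastic confusion matrices over
the true change category. An identity matrix reproduces the truth; uniform
rows give statistically independent readers, whose expected kappa is 0 —
the suite checks $|\kappa| < 0.03$ at $n = 10^4$.

## Problem sizes and runtime choices

Unit and property tests run on 9³–24³ grids with brute-force oracles
(exhaustive ellipsoid membership, exhaustive peak-sphere averaging,
independent kappa implementations); end-to-end acceptance checks use the
default 64³ phantom noiselessly and one noisy cohort-style simulation.
The whole suite completes in well under a minute on a single CPU; the
acceptance script in about one second.

## Known limitations

* Ratio-of-means versus mean-of-ratios: the cohort-mean uptake ratio
  computed from mean SUV_peak and mean reference SUV_mean (20.4/5.6 ≈
  3.64) is not the mean of per-lesion ratios (reported as 3.8 in the
  source cohort); the package computes per-lesion ratios, but the phantom
  defaults only pin the separate means.
* The calibration chain of a real camera is abstracted into the single
  linear factor $S$; no partial-volume or recovery-coefficient modelling.
* No VOI propagation or registration between time points: follow-up VOIs
  are assumed drawn at analogous anatomical positions, as in the manual
  clinical workflow.
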