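# bonetrack

Longitudinal quantitative bone SPECT/CT analysis in R.

Therapy response of osseous metastases is commonly monitored with bone
scintigraphy, and whether a lesion's tracer uptake went up or down between
two scans is usually judged by eye — with substantial disagreement between
readers. Calibrated quantitative SPECT/CT makes the question numeric:
convert counts to activity concentration, normalize to standardized uptake
values (SUV), measure each lesion's SUV_peak at both time points, and
classify the fractional change against a fixed threshold.

`bonetrack` is for imaging scientists and methodologists who want that
pipeline — and the agreement statistics for comparing classification
sources — as tested, scriptable building blocks:

* **Phantom simulation** — paired two-time-point synthetic studies:
  ground-truth SUV maps, activity volumes, Poisson count volumes,
  acquisition metadata, and stochastic (confusion-matrix) visual readers.
* **Quantification** — decay correction `2^(Δt/T½)`, residual-corrected
  net injected activity, counts → kBq/mL → body-weight SUV (1 g/mL
  convention, referenced to injection time), ellipsoidal VOI masks, and
  SUV_max / SUV_mean / SUV_peak (1 mL sphere about the VOI maximum).
* **Classification** — progressive (>+30 %), regressive (>−30 % decrease),
  stable (rest); strict inequalities; absolute-SUV mode and
  reference-ratio mode (lesion SUV_peak / vertebral reference SUV_mean,
  cancelling global bone-metabolism fluctuations).
* **Agreement** — Cohen's kappa `κ = (p0 − pe)/(1 − pe)` from full
  contingency tables *or* from marginal tallies plus discrepancy counts
  (the two are provably identical), Landis–Koch labels, discrepancy
  fractions, Mann–Whitney U (exact or tie-corrected normal), Spearman
  rank correlation.
* **I/O** — NIfTI volumes (RNifti), JSON metadata, CSV VOI/metric/rating
  tables, and a bundled fixture of published two-reader classification
  tallies for 52 metastatic bone lesions.

## Worked example

Simulate a subject with three lesions whose true fractional changes are
+50 %, 0 %, −50 %, quantify both time points, and classify in ratio mode:

```r
library(bonetrack)

spec <- example_phantom_spec(fractional_changes = c(0.5, 0, -0.5))
pair <- make_longitudinal_pair(spec, seeds = c(101L, 102L), noiseless = TRUE)

met1 <- quantify_study(pair$tp1$counts, pair$tp1$meta, pair$vois)
met1[, c("voi_id", "label", "n_voxels", "suv_mean", "suv_max", "suv_peak")]
#>         voi_id     label n_voxels suv_mean suv_max suv_peak
#> 1    lesion_01    lesion      224     20.4    20.4     20.4
#> 2    lesion_02    lesion      223     20.4    20.4     20.4
#> 3    lesion_03    lesion      223     20.4    20.4     20.4
#> 4 ref_vertebra reference      620      5.6     5.6      5.6
```

The painted study conditions (lesion SUV 20.4, reference SUV_mean 5.6)
come back exactly through the counts → concentration → SUV chain. The
ratio-mode classification recovers the true categories; note how the
reference drift from 5.6 to 4.9 shifts every ratio upward without changing
the calls:

```r
met2 <- quantify_study(pair$tp2$counts, pair$tp2$meta, pair$vois)
lesions <- function(m, ref) data.frame(lesion_id = m$voi_id[m$label == "lesion"],
                                       suv_peak = m$suv_peak[m$label == "lesion"],
                                       ref_suv_mean = ref)
calls <- classify_lesions(lesions(met1, met1$suv_mean[met1$label == "reference"]),
                          lesions(met2, met2$suv_mean[met2$label == "reference"]),
                          mode = "ratio")
calls[, c("lesion_id", "value_tp1", "value_tp2", "delta", "category")]
#>   lesion_id value_tp1 value_tp2  delta    category
#> 1 lesion_01      3.64      6.24  0.714 progressive
#> 2 lesion_02      3.64      4.16  0.143      stable
#> 3 lesion_03      3.64      2.08 -0.429  regressive
```

Agreement between two classification sources, reconstructed here directly
from marginal tallies (35/33/36 vs 25/28/51 over 104 pooled lesions with
40 discrepant):

```r
kappa_from_marginals(c(35, 33, 36), c(25, 28, 51), n_agree = 104 - 40, n = 104)
#> Cohen's kappa = 0.421 (moderate); p0 = 0.615, pe = 0.336, n = 104
#>   H0 kappa = 0: z = 6.21, two-sided p = 5.23e-10
```

A kappa of 0.42 means the visual and quantitative readings agree only
moderately once chance agreement (pe = 0.34) is discounted — the central
empirical finding this toolchain exists to quantify.

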