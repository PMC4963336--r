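Package: bonetrack
Title: Longitudinal Quantitative Bone SPECT/CT Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal analysis of skeletal tracer uptake in
    quantitative bone SPECT/CT. Provides a synthetic two-time-point phantom
    generator (ground-truth activity volumes, Poisson count simulation,
    stochastic visual-reader emulation), count-to-SUV quantification with
    decay and residual-activity correction, ellipsoidal volume-of-interest
    extraction of SUV_max, SUV_mean and SUV_peak (1 cm3 peak sub-volume),
    progressive/stable/regressive lesion response classification at a
    configurable fractional-change threshold in absolute-SUV and
    reference-ratio modes, and inter-rater/inter-method agreement analysis
    (Cohen's kappa from contingency tables or marginal summaries,
    Landis-Koch interpretation, Mann-Whitney U, Spearman rank correlation),
    including reconstruction of aggregated inter-method kappa statistics
    from published reader classification tallies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
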