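Package: olfbold
Title: Olfactory Block-Design BOLD fMRI Analysis with Kolmogorov-Smirnov
    Activation Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxelwise analysis of olfactory block-design BOLD fMRI:
    temporal and spatial preprocessing (Gaussian smoothing, discrete-cosine
    high-pass detrending, nuisance-trace regression, zero-phase low-pass
    filtering), nonparametric Kolmogorov-Smirnov two-sample activation
    mapping with false-discovery-rate control and a general-linear-model
    comparator, block-wise relative signal change (dS/S) with habituation
    metrics, temporal signal-to-noise and contrast-to-noise ratios,
    ROI-level group statistics (repeated-measures ANOVA, paired comparisons
    with Cohen's d), and scan-rescan reproducibility (Dice overlap,
    intraclass correlation). Includes a synthetic 4-D BOLD phantom that
    emulates pulsed odor stimulation with bi-phasic, habituating responses,
    negative activation, slow drift, respiratory noise, and
    susceptibility-dropout fields, with ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
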