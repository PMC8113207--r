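Package: dpdquant
Title: Quantitative Cardiac Bone-Tracer SPECT/CT Analysis
Version: 0.1.0
Authors@R: person("dpdquant", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Volume-of-interest quantification of cardiac bone-avid tracer
    (99mTc-DPD) SPECT/CT for transthyretin amyloidosis: decay-corrected
    standardized uptake values, 42 percent isocontour segmentation, the
    compound amyloid burden score DPD_load, apical-sparing ratios from both
    uptake and longitudinal strain, and the cohort statistics (Pearson
    correlations with two-tailed t tests, Kruskal-Wallis across Perugini
    grades) linking uptake to echocardiographic strain and cardiac
    biomarkers. Includes digital cardiac phantom and synthetic cohort
    generators with ground truth for end-to-end validation, and a minimal
    NIfTI-1 reader/writer.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
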