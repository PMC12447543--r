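Package: gazersa
Title: Representational Similarity Between Gaze Density Maps and Visual
    Cortex Voxel Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for relating the spatial distribution of scene-viewing
    fixations to the representational geometry of visual-cortex regions of
    interest. Parses fixation event reports, applies trial- and
    subject-level exclusion rules, builds Gaussian-smoothed fixation
    density maps, constructs representational similarity matrices (RSMs)
    from gaze and from voxel activation patterns, quantifies
    gaze-to-brain representational similarity as the Spearman rank
    correlation between RSMs (optionally partialing out a salience RSM),
    estimates leave-one-out noise ceilings, and performs age-by-ROI mixed
    model inference with estimated marginal means and Holm-corrected post
    hoc contrasts. Includes a synthetic-study generator with planted
    multi-level scene structure for end-to-end validation, and Monte
    Carlo power and family-wise error simulations for the repeated
    measures design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    lme4,
    lmerTest,
    emmeans,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
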