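Package: cortexmicro
Title: Cortical Microstructure and Psychosexual Development Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline relating cortical gray-matter microstructure
    (quantitative T1 relaxation time and mean diffusivity) to age, sexual
    attractions and gender identity in adolescents. Provides vectorized
    scoring of psychosexual questionnaires (attraction magnitude and phase),
    atlas-based ROI summaries of volumetric metric maps (spline-fit histogram
    mode for T1, gray-matter-gated mean for MD), heteroscedasticity-robust
    group comparisons, a clustered random-intercept regression of MD on T1,
    and group-stacked behavior partial least squares with permutation and
    bootstrap inference, together with seeded synthetic-cohort and phantom
    generators so the whole pipeline is testable without participant data.
License: MIT + file LICENSE
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    lme4,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Encoding: UTF-8
Config/testthat/edition: 3
RoxygenNote: 7.3.3
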