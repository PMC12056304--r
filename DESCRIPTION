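Package: PlaqueQuant
Title: Quantitative Image Analysis of Amyloid Plaque Histology
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for quantifying amyloid burden and plaque
    morphology in brightfield and fluorescence histology of amyloidogenic
    mouse models. Separates hematoxylin/DAB/Fast Red stains by optical-density
    unmixing, segments amyloid plaques and blood vessels, and measures per
    plaque area, maximum (Feret) diameter, integrated optical density, and
    box-counting fractal dimension; computes plaque-vessel nearest distances
    with a zero-distance contact convention, two-channel Abeta40/Abeta42 areas
    and Manders-style overlap coefficients, and thioflavin-S fibrillar
    fractions. A hierarchical statistics layer aggregates measurements per
    animal and anatomical region, then per treatment group, and provides
    one-way ANOVA with Fisher LSD post hoc tests, Pearson correlation,
    one-tailed Fisher Z comparison of independent correlations, and behavioral
    metrics (time in center, novel-object discrimination index). A synthetic
    histology generator with per-object ground truth makes every stage
    verifiable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Software, CellBiology, Visualization, Preprocessing
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'PlaqueQuant-package.R'
    'behavior.R'
    'colocalization.R'
    'fractal-fixtures.R'
    'io.R'
    'morphometry.R'
    'pipeline-config.R'
    'pipeline-run.R'
    'render.R'
    'segmentation.R'
    'stats-aggregate.R'
    'stats-tests.R'
    'synthetic-scene.R'
    'utils.R'
    'vascular.R'
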