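Package: eegdens
Title: Channel Density, Head Model and Parcellation Effects on EEG Source Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate how EEG montage density, head-model type and
    cortical parcellation shape group-level differences in source-space power
    and connectivity, modelled on resting-state comparisons between idiopathic
    generalized epilepsy patients and controls. Provides spherical electrode
    layouts with distance-based channel reduction, a three-shell concentric
    sphere forward model, DPSS multitaper cross-spectral estimation, DICS
    beamformer source power and imaginary-coherency connectivity, permutation
    general linear models with threshold-free cluster enhancement and
    family-wise error control, spin-test spatial correlations with Fisher-z
    comparisons, and a seeded synthetic-cohort generator with known
    ground-truth effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'utils.R'
    'dpss.R'
    'spectral.R'
    'forward.R'
    'cohort.R'
    'comparison.R'
    'dics.R'
    'io.R'
    'layout.R'
    'parcellation.R'
    'stats.R'
    'preprocess.R'
    'pipeline.R'
    'sourcespace.R'
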