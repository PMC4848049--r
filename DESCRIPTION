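Package: mapgap
Title: Lesion-Integrity Assessment from Monophasic Action Potentials and
    Catheter Contact Force
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assesses the integrity of linear cardiac ablation lesions from
    co-recorded monophasic action potential (MAP), reference ECG and fiber
    Bragg grating force-sensor signals. Provides per-fiber wavelength-to-force
    calibration, zero-phase band-pass filtering, QRS-referenced beat
    segmentation, per-beat MAP detection with activation-time (AT),
    end-of-repolarization (EOR) and MAP-duration (MAPDUR) metrics, the
    four-consecutive-waveform contact-force rule, and a decision procedure
    that labels each surveyed site conductive, non-conductive, conduction gap
    or indeterminate. A synthetic-signal generator with a force-threshold
    elicitation model makes the full pipeline testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'calibration.R'
    'classification.R'
    'detection.R'
    'io.R'
    'mapgap-package.R'
    'pipeline.R'
    'synthetic-data.R'
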