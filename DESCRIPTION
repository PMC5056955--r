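Package: megconn
Title: Reliability of Stationary Functional-Connectivity Metrics for
    Source-Space MEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing the test-retest reliability of stationary
    functional-connectivity metrics computed from source-space
    magnetoencephalography (MEG) region-of-interest time courses. Implements
    band filtering and analytic-signal decomposition, symmetric
    orthogonalisation for zero-lag source-leakage correction, twelve
    connectivity estimators (phase-locking value, phase lag index, weighted
    phase lag index, phase mutual information, coherence, imaginary coherency,
    partial coherence, imaginary partial coherency, phase slope index, partial
    directed coherence, amplitude envelope correlation and regularised partial
    envelope correlation), and a reliability suite covering split-half group
    consistency, within- and between-subject consistency, and an edge-level
    decomposition of network correlations. A synthetic-data generator produces
    multi-subject, multi-session oscillatory studies with known coupling and a
    controllable zero-lag mixing model, so the whole pipeline can be exercised
    and validated without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'TimeSeriesSet-methods.R'
    'bands.R'
    'filters.R'
    'signal.R'
    'leakage.R'
    'metrics-phase.R'
    'metrics-spectral.R'
    'metrics-ar.R'
    'glasso.R'
    'metrics-amplitude.R'
    'metric-registry.R'
    'synthetic.R'
    'reliability.R'
    'experiment.R'
    'io.R'
    'megconn-package.R'
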