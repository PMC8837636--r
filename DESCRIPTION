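Package: desimilk
Title: Chemometric Authentication of Milk Species from DESI-MS Lipid Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying milk of animal and plant origin and for
    detecting cow-milk adulteration from desorption electrospray ionisation
    mass spectrometry (DESI-MS) lipid fingerprints. Peak lists are binned onto
    a fixed 0.2 Da mass grid (m/z 100-2000), filtered by a per-scan total ion
    count limit, and analysed by PCA with leave-20%-out bootstrap LDA
    classification (5-sigma Mahalanobis outlier rejection), binary OPLS-DA
    with S-plot biomarker selection and Y-permutation validation, and
    per-mixture-level LDA models yielding limits of detection for cow milk
    admixture. A bundled, mass-verified lipid marker table supports
    formula-based monoisotopic and protonated-adduct annotation, and a
    synthetic spectrum generator emulates five-species milk studies so every
    pipeline stage can be exercised without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'desimilk-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'spectra_io.R'
    'preprocessing.R'
    'pca_lda.R'
    'adulteration.R'
    'formula.R'
    'markers.R'
    'oplsda.R'
    'model_io.R'
    'simulate.R'
    'pipeline.R'
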