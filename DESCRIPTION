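Package: gcxgcAlign
Title: Two-Stage Landmark-Based Peak Alignment for GCxGC/TOF-MS Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Aligns peak lists from comprehensive two-dimensional gas
    chromatography time-of-flight mass spectrometry (GCxGC/TOF-MS) across
    samples without user-tuned matching cutoffs. Stage one merges split peak
    entries within each sample, z-score-transforms both retention time
    dimensions, and discovers landmark peaks present in every sample using a
    mixture of two-dimensional retention-time distance and fragment-spectrum
    Pearson correlation, optimising the mixture weight over a fixed candidate
    grid. Stage two derives distance and similarity thresholds from the
    landmark pairs by iterative one-sided Grubbs outlier rejection and aligns
    the remaining peaks pairwise against the reference sample. Includes a
    ChromaTOF-style peak-list reader/writer, an alignment evaluator
    (TPR/PPV/F1 against ground truth), and a synthetic peak-list generator
    with known correspondences.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'similarity.R'
    'preprocess.R'
    'full-alignment.R'
    'partial-alignment.R'
    'evaluation.R'
    'io.R'
    'simulate.R'
    'pipeline.R'
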