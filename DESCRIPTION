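Package: lbpmotion
Title: Movement, Muscle-Activity and Balance Profiling for Non-Specific Low Back Pain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction and exploratory analysis for trunk-movement
    recordings in non-specific low back pain (NSLBP) studies. Covers
    high-density surface EMG cleaning (baseline wander, ECG template
    subtraction, outlier filling), repetition segmentation from force-plate
    stabilization, spatial EMG activity maps (RMS centroid, grid entropy),
    motion-capture trajectory features (range of motion, time to maximum,
    sample entropy, inter/intra-subject variation), statokinesigram and
    ground-reaction-force balance measures, dense-network classifiers with
    subject-disjoint splits, and per-movement exploratory factor analysis
    with ensemble factor-count selection and critical-correlation
    significance gating. A synthetic-cohort generator with planted group
    effects makes every stage testable without access to recorded subjects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    graphics,
    jsonlite,
    signal,
    stats
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
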