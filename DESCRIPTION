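Package: megmark
Title: Normative MEG Band-Power Abnormality Mapping and Markers of Epilepsy Surgery Failure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds normative maps of relative magnetoencephalography (MEG) band
    power from healthy-control cohorts, converts patient region-level spectra
    into maximum-absolute-z abnormality maps, and computes three region-level
    markers of epilepsy surgery failure: the mean abnormality of the resection
    (MA_R), the rank-based distinguishability of resected versus spared tissue
    (D_RS), and the abnormality contribution of the resection (AC_R). Includes
    Welch spectral estimation for parcellated region time series, resection
    labelling from pre/post-operative volumes, cohort-level outcome statistics
    (one-tailed Mann-Whitney AUC, one-sample Wilcoxon signed-rank tests, a
    Monte-Carlo healthy-deviation threshold, optimal ROC thresholds, unified
    multi-marker flagging), a synthetic-cohort generator with known ground
    truth, and delimited-text readers and writers with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
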