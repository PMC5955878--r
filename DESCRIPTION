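Package: ictaltrace
Title: Analysis of Two-Photon Calcium Imaging During Spike-Wave Seizures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for joint analysis of electrocorticography (EEG) and
    two-photon calcium imaging recorded during absence (spike-wave)
    seizures. Provides spike-wave discharge detection and curation on the
    EEG, delta-F/F extraction with a rolling bottom-decile baseline and
    half-Gaussian noise removal, per-ROI ictal/interictal classification,
    seizure-aligned participation testing against circular-shuffle
    permutation nulls, sliding-window reclassification, rate-corrected
    pairwise synchrony, exponential-kernel calcium deconvolution, and
    action-potential detection in patch-clamp voltage traces. A synthetic
    session generator with planted ground truth makes every stage testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
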