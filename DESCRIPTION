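Package: dmdcpp
Title: Clustered Pattern Projection on Dynamic-Mode EEG Descriptors
Version: 0.1.0
Authors@R:
    person("Jane", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Segment-wise dynamic mode decomposition (DMD) descriptors for
    multichannel photic-stimulation EEG, class-specific medoid dictionary
    learning by divisive cosine clustering, prototype-projection features,
    linear support-vector classification under leave-one-subject-out
    validation with majority voting and Wilson score intervals, and
    margin-based subject-level reliability analysis (permutation median-gap
    tests and Cliff's delta). Includes a PCA baseline sharing the same
    descriptors and a synthetic photic-stimulation EEG generator so the
    entire pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
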