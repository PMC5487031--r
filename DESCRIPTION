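Package: ednaqpcr
Title: Detection and Quantification of Aquatic Environmental DNA from qPCR Plate Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for species detection and copy-number quantification from
    TaqMan qPCR assays run on environmental DNA (eDNA) extracted from filtered
    water. Implements log-linear standard-curve calibration with amplification
    efficiency, Poisson single-molecule (most-probable-number) copy estimation,
    replicate-based and statistically defined limits of detection and
    quantification, delta-Ct PCR-inhibition testing with a three-branch
    quantification rule, conversion of per-reaction copy numbers to copies per
    litre of filtered water, in-silico primer/probe specificity screening
    against CO1 sequence collections, and a synthetic plate-data generator for
    end-to-end validation of the whole pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
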