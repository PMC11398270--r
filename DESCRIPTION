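Package: ruminate
Title: Regurgitation Detection and Rumination-Cycle Analysis from Nose-Clip Sensor Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring rumination behavior in dairy cattle from a
    nose-mounted sensor that records nasal differential pressure and triaxial
    acceleration. Provides a seeded simulator of breathing traces with
    regurgitation signatures, distractor motion and streaming gaps; a detector
    that locates regurgitation events from near-zero z-orientation plateaus
    corroborated by a prolonged breath; rumination-cycle statistics with
    outlier-cow flagging and rumination-time summaries; and a validation layer
    that matches sensor events against visual observations within a tolerance
    window, counts true-negative minutes on negative-control periods, corrects
    confusion counts for streaming gaps, and reports sensitivity, specificity,
    and positive/negative predictive values.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
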