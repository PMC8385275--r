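Package: sambiance
Title: Privacy-Preserving Social Ambiance Measurement from Wearable Audio
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to estimate a Social Ambiance Measure (SAM) from continuous
    wearable audio without analysing speech content. Audio is converted into
    per-5-second concurrent-speaker counts by a voice-activity detector,
    filterbank-plus-pitch acoustic features, and an x-vector-style embedding
    network with statistics pooling and centroid-distance scoring. Counts are
    binned into four ambiance levels, aggregated into daily and weekly
    time-budget profiles with a Shannon-entropy summary, and related to
    self-report measures through one-way ANOVA and Gaussian regression with
    Benjamini-Hochberg false-discovery-rate control. A fully synthetic
    overlapping-speech corpus generator (speech-like voices, three noise
    categories, room reverberation) provides labelled training and evaluation
    material, and a phone-call-log module quantifies remote interaction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    digest,
    dplyr,
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
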