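Package: snoreforge
Title: Snore Sound Classification with Swarm-Selected Acoustic Features and Boosted Weighted ELMs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for classifying short snore audio clips by excitation
    site. Extracts acoustic features from six domains (time, spectral,
    wavelet, sparse, eigen and cepstral), performs binary wrapper feature
    selection with golden eagle optimization and (refined) salp swarm
    algorithms, and classifies with weighted extreme learning machines,
    their kernel and composited-kernel forms, multiclass Adaboost
    ensembles, and firefly / capuchin-search tuned variants. Includes a
    synthetic snore-like audio generator, stratified cross-validation with
    unweighted average recall, and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
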