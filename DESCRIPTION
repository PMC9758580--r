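Package: replaysim
Title: Simulating Memory Consolidation by Generative Replay in Layered
    Visual Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Day-night training protocols for studying offline memory
    consolidation in layered convolutional image classifiers. Days train
    the network on labelled images; nights replay internal activations
    captured at the pooling layer ending any convolutional block, either
    veridically (stored activations) or generatively, by fitting one
    multivariate normal distribution per class over downsampled layer
    activations and sampling novel "imagined" representations from it.
    An optional reinforcement-learning scheduler selects which class to
    replay next from the reduction in a chi-square gap between perfect
    and observed classification. A procedural synthetic-category
    generator with tunable inter-class similarity and per-class
    difficulty makes every experiment reproducible on one CPU with no
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
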