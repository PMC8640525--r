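Package: degensim
Title: Simulating Progressive Neurodegeneration in Feed-Forward Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in silico paradigm for modelling neurodegenerative disease,
    in particular posterior cortical atrophy, in trained feed-forward image
    classifiers. Networks trained on a two-level class/superclass hierarchy
    undergo cumulative random ablation of inter-neuron connection weights;
    the package tracks behavioural readouts (accuracy, within-superclass
    error structure) and representational readouts (representational
    dissimilarity matrices, Kendall tau-a decay against the uninjured
    reference, scrambled-RDM noise floors) over the injury course. Includes
    a hierarchical synthetic image generator, a compact trainable
    convolutional classifier, injury engines (weight ablation, node
    ablation, weight randomisation), representational similarity analysis,
    and a reproducible experiment runner with tidy outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
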