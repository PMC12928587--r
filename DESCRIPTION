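Package: subnetlm
Title: Trainable Subnetworks for Masked Protein Language Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns binary masks over the weights of a masked protein language
    model so that the resulting subnetwork loses language-modeling ability on
    one structural category of inputs (a CATH-style sequence category or a
    secondary-structure residue state) while matching the full model everywhere
    else. Masks are trained with a Gumbel-sigmoid relaxation and a
    straight-through estimator under a weighted objective combining a
    KL-to-uniform suppression term, a KL-to-baseline maintenance term, and a
    masked-language-modeling maintenance term with the standard 15% / 80-10-10
    corruption scheme. Includes annotation handling (CATH label truncation,
    DSSP 8-state to 3-state reduction, length filtering, dataset splitting), a
    synthetic classed-sequence testbed with a small trainable transformer
    masked language model, stratified perplexity evaluation, per-layer pruning
    profiles, and paired-t / Kolmogorov-Smirnov statistics for externally
    supplied structure metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
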