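Package: driftDFE
Title: Relative Fitness Effects of Mutations from Laboratory Neutral Drift
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers per-mutation relative fitness effects (Wrel) from deep
    sequencing of gene ensembles subjected to iterative rounds of random
    mutagenesis and purifying selection ("laboratory neutral drift").
    Provides codon-level enumeration of a gene's mutational space, variant
    counting from short ungapped read alignments with sequencing-error
    background subtraction, inversion of the geometric-series selection
    model to assign each mutation a relative fitness and a five-way fitness
    category, distribution-of-fitness-effects (DFE) and drift-dynamics
    summaries (mutational loads, Na/Ns, positional scores, compensatory
    calls), comparisons against external variant-effect predictors and
    structural constraint scores, and a seeded forward simulator of the
    mutagenesis-selection drift so the whole pipeline can be exercised and
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    methods,
    Biostrings,
    Rsamtools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
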