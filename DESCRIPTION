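Package: chimeraML
Title: Machine-Learning-Guided Engineering of Chimeric Enzyme Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and closed-loop optimization of chimeric protein
    libraries built by structure-guided recombination. Provides SCHEMA
    disruption scoring and RASPP breakpoint selection from ensemble-weighted
    residue contact maps, greedy maximally informative seed-set design by
    Gaussian entropy maximization, Gaussian naive Bayes active/inactive
    classification, Gaussian-process regression on one-hot sequence
    encodings with leave-one-out hyperparameter selection, batch-mode
    upper-confidence-bound proposal of new variants with hallucinated
    refits, protein-protein interface charge statistics, gas-chromatography
    internal-standard quantitation, and a synthetic block-additive
    epistatic fitness-landscape simulator so that the whole
    design-test-learn loop can be exercised and validated without a wet
    lab.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    e1071,
    yaml,
    optparse
Config/testthat/edition: 3
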