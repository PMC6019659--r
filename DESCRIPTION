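Package: ssforge
Title: Disulfide Bond Engineering by Geometric Probability Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts residue pairs suitable for engineered disulfide bonds
    from protein structures. Candidate cysteine pairs are scored by three
    probabilities: a geometric probability against empirical distributions
    mined from native disulfides (cross-residue atom distances, inter-plane
    dihedrals and the five cystine chi angles), closeness (superposition
    RMSD) to the nearest native disulfide template, and the loop-closure
    conformational entropy change of the crosslink. A support vector
    machine combines the three scores into a positive/negative call and
    candidates are filtered and ranked. Also provides quasi-harmonic
    conformational entropy and fluctuation statistics for coordinate
    ensembles, and a synthetic structure generator (ideal helices, planted
    cystines, Gaussian ensembles) used for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
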