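Package: skinperm
Title: Topological QSAR Models of Human Skin Permeability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and validates quantitative structure-activity models of the
    human skin permeability coefficient (log Kp, cm/h) from three topological
    descriptors: a cosine-squared transform of the atom-contribution octanol-water
    partition coefficient (A log P), the third-order valence molecular connectivity
    index (X3v), and the Ghose-Viswanadhan-Wendoloski antineoplastic drug-likeness
    indicator (Neoplastic-80). Provides SMILES parsing and H-depleted graph
    construction via Open Babel, Kier-Hall simple and valence connectivity indices
    of order 0-5, dataset curation with structure-based deduplication, descriptor
    pre-filtering, deterministic Kennard-Stone train/test splitting, ordinary
    least-squares fits with full QSAR diagnostics and p-value stepwise selection,
    an epsilon-insensitive support vector regression trained by a maximal-violating
    pair SMO solver with RBF kernel, genetic-algorithm hyperparameter tuning by
    cross-validation, leave-one-out and k-fold cross-validation, and the
    Golbraikh-Tropsha external-validation battery. The published fitted equations
    are available as frozen predictors, and a synthetic data generator emulates the
    compound table for self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
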