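Package: metsite
Title: Site-of-Metabolism and Metabolite Prediction from Reaction-Derived
    Atom-Environment Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts sites of metabolism (SOMs) of drug-like molecules by
    comparing six-layer topological atom-environment count fingerprints
    (Molprint2D style, SYBYL/Tripos atom types) of a query molecule against
    two fingerprint databases derived from curated metabolic reactions: one
    of all substrate atoms and one of annotated reaction-center atoms tagged
    with reaction SMARTS patterns.  Similarity combines an exact-match
    prefix filter with Soergel and Hamming metrics under layer weights; raw
    occurrence ratios are corrected by checking whether each candidate
    reaction SMARTS pattern actually applies at the query atom, and the
    applicable patterns generate ranked metabolite structures.  Includes
    reaction curation, SOM annotation by maximum-common-substructure diff or
    by pattern mapping, a deterministic synthetic reaction-dataset
    generator, and an evaluation suite (top-k accuracy, atom-level ROC AUC,
    metabolite precision/recall, exact-match depth sweep).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    digest,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
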