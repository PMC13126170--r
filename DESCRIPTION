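Package: adomain
Title: Substrate Specificity Prediction for Nonribosomal Peptide Synthetase
    Adenylation Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects adenylation (A) domains in nonribosomal peptide
    synthetase (NRPS) protein sequences with profile hidden Markov models,
    extracts 34-residue extended and 10-residue Stachelhaus active-site
    signatures by position mapping onto a reference scaffold, and converts
    signatures, substrates and superposed structures into numeric features
    (physicochemical property encodings, ECFP-4 fingerprints, active-site
    voxel grids with per-group principal components). Two random-forest
    predictors are provided: a single-label substrate classifier with vote
    confidences, and a domain-by-substrate interaction model that ranks
    arbitrary, including previously unseen, substrates. Includes taxonomy-
    and substrate-stratified train/test splitting, benchmark-style
    evaluation semantics (correct/incorrect/no call/not in model, top-k and
    promiscuity scoring, bootstrap comparisons), per-substrate
    information-gain feature attribution down to individual active-site
    residues, and a synthetic fixture generator with recorded ground truth
    for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ranger,
    bio3d,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
SystemRequirements: HMMER (>= 3.1, hmmbuild/hmmsearch/hmmalign on PATH);
    Python with RDKit on PATH as 'python' (ECFP fingerprints only)
Config/testthat/edition: 3
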