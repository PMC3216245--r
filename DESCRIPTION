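Package: FabryPSSM
Title: Predicting Pharmacological Chaperone Response of Alpha-Galactosidase
    Missense Mutations with Position-Specific Substitution Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds position-specific substitution matrices (PSSMs) from
    multiple alignments of lysosomal alpha-galactosidase (AGAL) homologs and
    uses them to score missense mutations and predict their responsiveness to
    the pharmacological chaperone 1-deoxy-galactonojirimycin (DGJ).
    Implements Henikoff position-based sequence weighting, substitution-prior
    pseudocount smoothing and scaled integer log-odds scoring; a score
    threshold classifier with a twilight zone at -2; the 15 percent-of-wild-type
    activity rule for calling a mutant responsive; and panel evaluation
    statistics (score-bin response rates, exact Fisher tests, Pearson
    correlation, classification accuracy). Ships transcriptions of two
    published AGAL mutation panels plus a synthetic alignment and mutation
    panel generator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
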