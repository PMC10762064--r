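Package: seqmend
Title: Refining De Novo Peptide Sequences by Fragment-Ion Bin
    Reclassification and Evolutionary Rescoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-processing of candidate peptides from de novo tandem
    mass-spectrometry sequencing tools. Implements an amino-acid-gapped
    convolutional network that predicts, for every 1-Da m/z bin, whether
    it holds a singly charged b- or y-ion of the correct peptide; guided
    peptide mutation by weighted random walks on a probability-weighted
    spectrum graph; a peptide-spectrum-match confidence score defined as
    a random-forest estimate of the Levenshtein distance to the correct
    sequence (114 spectrum-similarity, peak-counting and bin-change
    features); and an evolutionary algorithm combining the two. Ships a
    synthetic tryptic-spectrum simulator so that training, scoring and
    search are fully testable at desk scale, plus MGF input/output and
    peptide-level evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    ranger,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
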