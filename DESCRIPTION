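Package: topolabel
Title: Transmembrane Topology Prediction Constrained by Surface-Labeled Lysines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@topolabel.org",
           role = c("aut", "cre"))
Description: Turns surface-biotinylation mass-spectrometry evidence into
    extracellular-position constraints for transmembrane-protein topology
    prediction. Maps modified-peptide observations onto protein sequences,
    aggregates labeled lysine positions with biological-replicate provenance,
    and feeds the resulting constraints into a duration-constrained hidden
    Markov model of membrane topology with hard positional masking, posterior
    decoding and a reliability score. Includes modification-mass bookkeeping
    from elemental compositions, enzyme-specific in-silico digestion, a
    constraint-corruption benchmark simulation quantifying how constraint
    coverage and false-positive contamination change prediction accuracy and
    reliability, sequence-context entropy analyses, and a synthetic-data
    generator emulating replicated labeling experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
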