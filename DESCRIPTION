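Package: glycoscout
Title: Intact Glycopeptide Identification, Glycan De Novo Sequencing and
    Site-Specific Quantification from Tandem Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A search engine for intact N- and O-linked glycopeptides from
    centroided MS/MS spectra. Spectra are triaged by glycan signature
    (oxonium) ions and Y-ion ladders, then identified by complementary
    peptide-based and glycan-based database searches with second-round
    rescoring. False discovery rates are controlled separately at the
    peptide level (shuffled-protein decoys) and the glycan level
    (mass-shifted decoy spectra); glycosylation sites and glycan structures
    carry dedicated confidence scores (A-score, S-score). Spectra whose
    peptide is confidently identified but whose glycan is absent from the
    database are sent to de novo sequencing: a dynamic program over
    monosaccharide residue masses infers the glycan composition and a beam
    search reconstructs the glycan tree from its fragment-ion evidence.
    Label-free quantification aggregates MS1 precursor feature areas into
    per-site glycan profiles. A synthetic-data module generates proteins,
    glycan databases and glycopeptide spectra with known ground truth so
    that every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    xml2
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
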