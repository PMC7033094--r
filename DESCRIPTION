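Package: afpscan
Title: Proteogenomic Identification of Glycine-Rich Antifreeze Protein
    Transcripts from EST Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies antifreeze protein (AFP) transcripts by scanning
    six-frame translations of expressed sequence tag (EST) collections for
    peptide strings derived from tandem mass spectrometry, with isoleucine
    and leucine collapsed as isobaric. Candidate open reading frames are
    characterized by in-silico tryptic digestion, monoisotopic and average
    mass prediction matched against MALDI peak lists (including
    doubly-charged satellite checks), cysteine-excluded molar amino-acid
    composition, and detection of glycine-initial tripeptide-repeat tracts
    typical of springtail AFPs. Pairwise evolutionary comparison is
    supported through global alignment statistics and windowed dot-matrix
    plots with per-region (UTR versus coding) GC content. A seeded
    synthetic-data generator plants a glycine-rich secreted AFP coding
    sequence among decoy ESTs together with simulated peptide detections
    and MALDI peaks, so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
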