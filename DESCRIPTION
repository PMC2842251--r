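Package: uaugscan
Title: MicroRNA Complementarity Scanning of Upstream AUG Motifs in 5'-UTRs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Finds upstream AUG (uAUG) motifs in human 5'-UTRs from pairwise
    human/mouse alignments, classifies their cross-species conservation, and
    scans them for antiparallel complementarity against the 5' and 3' halves
    of mature microRNAs.  Candidate duplexes must contain a minimum run of
    consecutive Watson-Crick or G:U wobble pairs and pass a nearest-neighbor
    free-energy screen at 37 degrees C.  Enrichment of interaction counts is
    assessed against a composition-preserving miRNA shuffle null with a
    Z-test, and gene-level reports join predicted interactions to reporter
    repression annotations and cell-line miRNA expression evidence.  A
    synthetic-data generator plants reverse-complement binding sites on
    uAUGs with known ground truth so that every pipeline stage can be
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
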