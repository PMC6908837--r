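Package: prosip
Title: Proteomic Stable Isotope Probing with Targeted Metagenome Binning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies 13C-labeled peptides and proteins from shotgun
    metaproteomics spectra by scoring enrichment-parameterized isotopologue
    envelopes against observed peak lists, controls error with peptide-level
    target-decoy false discovery rates, infers protein groups by the parsimony
    rule, applies labeled-protein filters for 13CO2 rhizosphere and
    13C-methanol incubation designs, and reconstructs metagenome-assembled
    genomes for the labeled organisms by coverage- and composition-based
    binning seeded on scaffolds that carry labeled proteins. A synthetic-data
    module generates ground-truth communities, proteomes, and centroided
    spectra so every stage runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    mclust,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
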