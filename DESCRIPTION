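Package: ltpepimap
Title: Allergenicity Screening and B-Cell Epitope Mapping for Plant Lipid
    Transfer Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in silico allergenicity assessment pipeline for plant
    nonspecific lipid transfer proteins (nsLTPs) and related small
    proteins.  Implements dual-mode homology screening against a local
    allergen database (full-length global identity and the Codex-style
    80-amino-acid sliding-window local identity), progressive multiple
    sequence alignment with Clustal-style conservation symbols and a
    per-residue percent-conservation score, neighbor-joining phylogeny,
    a propensity-scale panel for consensus linear B-cell epitope
    prediction, shared-epitope (triad/Venn) motif analysis against
    experimentally validated peach-LTP epitopes, and property-distance
    (PD) peptide similarity search in a five-dimensional physicochemical
    descriptor space.  Includes a synthetic LTP-family generator with an
    invariant cysteine scaffold for end-to-end validation without any
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
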