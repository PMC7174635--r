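Package: cassetteScreen
Title: Design and Analysis of Trackable CRISPR Editing-Cassette Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for pooled CRISPR-enabled trackable genome engineering
    screens of bacterial regulators. Selects functional residues to
    mutagenize from protein feature tables and ligand-bound structures
    (distance-cutoff rule), designs 230-nt editing cassettes (spacer, NGG
    PAM choice, homology repair arm with a synonymous PAM-disrupting edit,
    and per-residue synonymous controls), simulates antibiotic selection
    and paired-end amplicon sequencing with known ground truth, merges and
    demultiplexes reads, maps them to cassette genotypes under
    identity-threshold or mismatch-count rules, and calls
    resistance-conferring mutations by log2-fold enrichment against a
    synonymous-control null (mean + k*SD cutoff).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    bio3d,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
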