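Package: natdyn
Title: Comparative Intrinsic Dynamics of GNAT-Fold Acetyltransferase Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Elastic network normal mode analysis of C-alpha traces of
    N-terminal acetyltransferase (NAT) catalytic domains and related
    GNAT-fold proteins. Builds the distance-dependent Hookean spring
    network, computes normal modes, normalized residue fluctuations and
    cross-correlation maps, compares intrinsic dynamics between structures
    with the Bhattacharyya coefficient over a structurally aligned core,
    generates conformers displaced along individual low-frequency modes
    with elastic-energy relaxation in mode space and sliding-window
    all-atom rebuilding, and profiles the cross-section area of the
    ligand-binding tunnel in native and deformed conformers. Ships a
    synthetic-structure generator (ideal-geometry folds, Gaussian
    ensembles, hollow channels) so the whole pipeline runs and is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    ape,
    MASS,
    yaml,
    jsonlite,
    pheatmap,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
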