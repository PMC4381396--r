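Package: somsite
Title: Binding-Site Identification from Docking Poses with 3D Self-Organizing Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies protein binding sites by consensus clustering of
    docked ligand poses. Atomic coordinates of docking poses are summarized
    with a three-dimensional non-periodic Kohonen self-organizing map;
    high-consensus (low U-value) neurons are thresholded with a
    BIC-selected Gaussian mixture model and aggregated into ranked
    consensual clusters that are candidate binding sites. A dual-probe
    solvent-accessibility grid detector characterizes protein cavities and
    neuron densities. Docked fragments can additionally be decomposed into
    circular (Morgan-style) chemical features whose geometric centers are
    mapped and tested for active-site enrichment with randomization
    Z-scores. Includes synthetic generators (hollow receptors with planted
    cavities, pose clouds with planted pockets, small random molecule
    libraries) so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    mclust,
    jsonlite,
    yaml,
    ChemmineR,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
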