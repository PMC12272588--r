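Package: uniscore
Title: Search-Engine-Agnostic Rescoring of Peptide-Spectrum Matches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rescoring of bottom-up proteomics peptide-spectrum matches (PSMs)
    with a simple, search-engine-agnostic score: the number of matched b- and
    y-ions plus the number of residues flanked on both sides by matched ions
    (the matched sequence stretch). Includes MGF peak-list input/output,
    top-N-per-bin spectrum filtering, optional deisotoping and charge
    deconvolution, theoretical b/y fragment masses for modified peptides,
    merging of candidate PSM tables from multiple search engines, a chimeric
    spectrum acceptance rule based on annotated-peak overlap, target-decoy
    false discovery rate control at the PSM, peptide and protein-group levels,
    entrapment-based false discovery proportion estimation, Percolator feature
    export, and a fully seeded synthetic-data generator (toy proteome, tryptic
    digest, pseudo-reversed decoys, shuffled entrapment sequences, noisy and
    chimeric spectra, emulated search-engine candidate tables).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
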