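Package: hcnopes
Title: Neural-Network Potential Energy Surfaces for Tetra-Atomic [H,C,N,O] Isomers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for fitting six-dimensional potential energy surfaces of
    four-atom [H,C,N,O] isomers with artificial neural networks. Provides the
    shared internal-coordinate system and Cartesian conversions, regular
    mesh-grid sampling with chemistry-aware filters, an analytic multi-basin
    surrogate reference surface, three trainable energy models (a molecular
    single-layer sum-of-products network fitted by Levenberg-Marquardt,
    an atom-decomposed symmetry-function network, and a graph-convolutional
    atomic network), cross-basin transfer evaluation, and construction of
    unified multi-isomer training sets with transition-state and
    dihedral-scan augmentation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: graphics, jsonlite, stats, tools, utils, yaml
Suggests: minpack.lm, testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
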