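Package: hexniche
Title: Spatial Microstructure of the Tumor Leading Edge on Visium Hex Lattices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the spatial microstructure of the tumor
    leading edge in Visium-style spot-level transcriptomics: marker-based
    partitioning of spots into tumor side, non-tumor side and stroma;
    quartile-tier multiplicative co-localization scores for two or three
    signals; concave-hull ("onion") stratification of tumor niches with
    per-layer signature profiles and a permutation trend test; and
    hexagonal-neighborhood correlation between enriched focal spots and a
    surrounding response signal. Includes a negative-binomial synthetic
    Visium generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
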