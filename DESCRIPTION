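Package: spatialith
Title: Spatial Intra-Tumour Heterogeneity Analysis and Range-Expansion Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-region (multi-sector) tumour sequencing
    data and for simulating spatial tumour growth. Provides sector phylogenies
    from somatic-mutation presence/absence (Hamming distances, neighbour
    joining, mutation-resampling bootstrap with majority-rule consensus),
    Weir-Cockerham Fst between sector pairs with tumour-purity recalibration
    and pooled per-site isolation-by-distance regression, sector-rarefaction
    curves ranking intra-tumour heterogeneity, sliding-window scans of viral
    integration-site lists for hotspots, refitting of 96-context mutation
    spectra onto known signatures, a 3D lattice agent-based range-expansion
    tumour simulator with sector sampling, and a synthetic multi-sector data
    generator for end-to-end testing without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
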