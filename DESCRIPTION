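Package: centriolr
Title: Quantification of Centriole Group Migration in Olfactory Epithelium
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the migration of centriole groups to the apical
    surface of the olfactory epithelium from fluorescence microscopy. Includes
    a synthetic-scene simulator with ground truth (dendritic-knob puncta with
    attached cilia, 4D time-lapses of migrating groups, paired drug/control
    count tables), 3D multiscale spot detection and counting, filament
    (cilium) tracing and one-to-one centriole-cilium association, single-
    linkage grouping and dendrite-lag measurement, time-lapse group tracking
    with fiducial drift correction and kymographs, epithelial-compartment
    scoring normalized to basal-lamina length, and a paired sign-flip
    permutation test for drug effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    yaml,
    jsonlite,
    igraph,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
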