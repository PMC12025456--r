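Package: fenestra
Title: Force-Volume AFM Analysis of Endothelial Fenestrations and Soft
    Substrates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of atomic force microscopy
    (AFM) force-volume data acquired on fenestrated cells and soft hydrogel
    substrates. Implements Hertz-Sneddon contact-mechanics fitting of
    force-distance curves (spherical and pyramidal indenters), contact-point
    estimation, load-force-dependent topography reconstruction from
    quantitative-imaging scans, fenestration morphometry (pore detection,
    porosity as fenestrations per square micrometre, and the load-dependent
    deformability fold change), amplitude-sweep rheology analysis (linear
    viscoelastic range, storage-modulus averaging, shear-to-Young conversion,
    loss factor), nuclei counting and per-cell endocytosis normalization, and
    group statistics. A synthetic-data module generates force-volume phantoms
    of fenestrated cells with known ground truth so that every stage of the
    pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
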