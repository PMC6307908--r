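Package: xenovasc
Title: Quantitation of Vascularisation and Macrophage Dynamics in
    Embryonic Tumour Xenografts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Volumetric quantitation of tumour-xenograft angiogenesis in
    zebrafish embryos from multichannel confocal z-stacks. Segments graft,
    vessel and macrophage channels by intensity threshold and minimum
    object volume using 3D connected components, computes percentage graft
    vascularisation and its proximal/middle/distal breakdown relative to
    the common cardinal vein, counts graft-associated macrophages, scores
    macrophage presence at angiogenic versus control regions in time-lapse
    movies, classifies tip-cell macrophages by contact duration, compares
    migration speed during and after vessel-tip contact, and routes
    two-group and multi-group comparisons through a normality-gated
    statistical decision tree. Includes a synthetic image generator with
    known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    multcomp,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
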