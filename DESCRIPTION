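Package: phenofield
Title: Multiscale Field Phenotyping from 3D Point Clouds and Multispectral Rasters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for plot-scale crop phenotyping of field
    trials: simulation of labeled field point clouds, multispectral
    reflectance rasters, growth trajectories and genotypes with planted
    QTLs; ground/canopy segmentation of 3D point clouds by a geometric
    baseline or a miniature hierarchical point-set network; per-plot 3D
    canopy height extraction; nitrogen-related vegetation indices (CCCI,
    MSAVI, RVI) with edge-buffered plot masks; Gaussian growth-curve
    fitting with six dynamic traits per signal; and genotype QC, PCA
    covariates and a single-marker association scan with Manhattan/QQ
    exports. All stages are driven by a synthetic field generator so the
    whole pipeline is verifiable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    minpack.lm,
    tiff,
    yaml,
    jsonlite,
    ggplot2,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
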