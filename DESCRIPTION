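Package: landgen
Title: Forward-Time, Individual-Based Landscape Genomic Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-time, individual-based, continuous-space simulation of
    diploid diallelic genomes evolving on multi-layer raster landscapes.
    Species move anisotropically along von Mises (mixture) movement surfaces
    derived from resistance rasters, mate locally within a search radius,
    and die by a combination of logistic density dependence and selection on
    any number of spatially varying polygenic traits. Includes a pre-genomic
    demographic burn-in terminated by a stationarity test battery,
    environmental and demographic change events, full spatial-pedigree
    recording, output writers for VCF, FASTA, CSV, GeoJSON, Shapefile and
    float TIFF rasters, and the spatial population-genetic statistics used
    to analyse such simulations (FST, nucleotide diversity, PCA-based genetic
    distances, partial Mantel tests, multiple matrix regression, and
    barrier-crossing rates).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    foreign,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    vegan,
    yaml
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
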