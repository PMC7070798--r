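Package: vinescan
Title: LiDAR-Based Reconstruction and Shoot-Volume Estimation for Defoliated Vineyards
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates, registers and analyses mobile 2D-LiDAR surveys of
    defoliated (winter) vineyard rows. A parametric scene generator builds
    trellised vine rows with analytically known shoot volume and dry biomass;
    a sensor model produces raw polar scan logs and NMEA 0183 GGA position
    streams; registration fuses both into a georeferenced 3D point cloud;
    filtering (batch cropping, bud-height cut, training-structure masking,
    statistical outlier removal) isolates the vine shoots; shoot volume is
    estimated as the enclosed volume of a 3D alpha shape computed from first
    principles over a Delaunay tetrahedralization; and a statistics layer
    relates scan counts and estimated volumes to pruning dry biomass through
    linear models and ANOVA.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
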