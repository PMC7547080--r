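Package: epilens
Title: Whole-Lens 3D Mapping of the Ocular Lens Epithelium
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for three-dimensional mapping of the lens epithelial cell
    (LEC) monolayer in intact eye lenses imaged as anisotropic confocal
    z-stacks. Detects nuclear centroids with a scale-normalized
    Laplacian-of-Gaussian likelihood map, grayscale-dilation local maxima and
    seeded watershed splitting; fits the near-equatorial plane from three
    user-supplied landmarks at the germinative-zone/meridional-row boundary;
    geometrically determines the anterior pole; realigns tilt-mounted lenses
    and assigns spherical-angle coordinates to every cell on an affinely
    normalized spheroid. Includes transect (region-of-interest) density
    profiling, polar-angle zonal density analysis (central zone, germinative
    zone, meridional rows), and a ground-truthed synthetic lens phantom
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml,
    grDevices,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
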