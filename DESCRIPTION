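Package: leafspray
Title: Droplet-Leaf Interaction Modelling for Precision Herbicide Spraying
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Models the interaction between a herbicide spray and the leaves
    of a small broadleaf weed (an Amaranthus retroflexus-like plant) for
    precision intra-row spraying. Provides drag-free projectile kinematics of
    discretized spray from nozzle to leaf, the droplet impact force, a
    cantilever-beam model of leaf deflection with a leaf deformation index,
    nozzle orifice hydraulics (cone angle, Bernoulli exit velocity, discharge
    flow) and a solver for the spraying-pressure window at which leaves are
    deflected just parallel to the ground, a reduced-order time-domain
    simulation of the spray-plant interaction (lumped modal leaf dynamics,
    discrete particle transport, wall-film growth, four-stage classification),
    spray-coverage statistics on binary stain images (coverage, inter-area
    variance, normalized mean absolute error), and synthetic-data generators
    for parameterized plants, droplet streams and water-sensitive-paper
    stain images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
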