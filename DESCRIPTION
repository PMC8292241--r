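Package: habnet
Title: Generative Models of Animal Habitat Networks with Epidemic
    Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates spatially explicit animal habitat networks on
    rectangular landscapes. Patches receive uniform (or user-supplied)
    coordinates; a complete graph weighted by reciprocal Euclidean
    distance is thinned by a sigmoidal distance-dependent link-removal
    probability, and disconnected components can be rewired with the
    minimum number of links by repeatedly joining the spatially closest
    components. Includes structural metrics (average clustering
    coefficient, modularity, diameter), a grid-sweep engine that fits
    generator parameters to target network metrics, and an agent-based
    movement plus SIR pathogen-transmission simulation on generated
    networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
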