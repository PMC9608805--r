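Package: landplus
Title: Coupled System-Dynamics and Patch-Generating Cellular-Automata
    Simulation of Land-Use Change with Ecosystem-Service Valuation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for scenario analysis of county-scale land-use change.
    A system-dynamics module projects per-class land demand from population
    and economic growth scenarios; a patch-generating cellular automaton
    allocates the demand on a categorical raster using random-forest
    development-potential surfaces learned from observed land expansion,
    neighbourhood effects, transition rules and restriction masks; an
    equivalent-factor module converts land-class areas into
    ecosystem-services values; and a spatial-statistics module quantifies
    cross-scenario disagreement with global Moran's I and Getis-Ord Gi*
    hot/cold spots. A synthetic-landscape generator produces paired
    land-use maps with known transition structure, driver stacks,
    restriction masks and zone tessellations so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, jsonlite, ranger, yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'grid-methods.R'
    'raster-io.R'
    'reference-tables.R'
    'synthetic-data.R'
    'sd-demand.R'
    'plus-allocation.R'
    'esv.R'
    'spatial-stats.R'
    'pipeline.R'
    'landplus-package.R'
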