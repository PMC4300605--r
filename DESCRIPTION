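Package: fluxmapr
Title: Metabolic Network Layouts and Flux Overlay Visualization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A scriptable framework for visualizing genome-scale metabolic
    networks as bipartite reaction-compound graphs. Layouts can be read from
    and written to standard interchange formats (XGMML, SBGN-ML Process
    Description, KGML, CellDesigner-annotated SBML, COBRA/BiGG map files),
    edited (node replication and merging, currency-metabolite typing,
    visibility filters), positioned with a force-directed spring embedder
    that honours pinned nodes, and generated de novo from SBML models or
    their pathway annotations. Phenotype-simulation results - flux
    distributions, genetic conditions (knockouts, over- and
    under-expression), pairwise simulation comparisons and elementary flux
    modes - are painted onto static SVG renderings through an overlay layer
    that controls edge thickness, colour gradients, glyphs and hide filters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    xml2
Suggests:
    rsvg,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
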