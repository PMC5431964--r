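Package: phylohotspot
Title: Phylogenetic Diversity Hotspots and Conservation Gap Analysis on
    Gridded Occurrence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes per-grid-cell species richness, corrected weighted
    endemism, relative phylogenetic diversity and phylogenetic endemism
    from a species-by-cell occurrence matrix and a dated phylogeny;
    identifies top-percentile biodiversity hotspots per metric,
    summarises multi-metric overlap, groups hotspot cells into contiguous
    regions, and classifies conservation gaps against nature-reserve
    coverage. Includes BLADJ-style branch-length age smoothing and a
    synthetic-data generator (gridded landscapes, Yule phylogenies,
    spatially cohesive species ranges) so the full pipeline can be
    exercised without proprietary atlas data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
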