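Package: chwaccess
Title: Geographic Accessibility Modelling for Community Health Worker Deployment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Models the deployment of community health volunteers against
    the primary health centers and supply points that support them. Builds
    a pedestrian cost-distance (friction) raster from land cover, slope via
    Tobler's hiking function, roads, and river-crossing penalties derived
    from D8 flow accumulation and Strahler stream ordering; computes
    least-cost one-way travel times from facilities; summarizes per-worker
    population and surface-area coverage against policy thresholds; and
    evaluates reassignment of workers to their closest facility. Includes a
    seeded synthetic-landscape generator (terrain, settlements, roads,
    Voronoi administrative units, facilities, worker roster) so the full
    pipeline runs and is testable without external geodata.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    sp,
    deldir,
    igraph,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    spatstat.geom
Config/testthat/edition: 3
RoxygenNote: 7.3.3
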