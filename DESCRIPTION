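Package: metarem
Title: Consolidate Ripple Effects Mapping Workshops into a Meta-REM Map
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for consolidating Ripple Effects Mapping (REM) outputs
    from multiple stakeholder workshops into a single verified, time-ranked
    meta-map. Reads per-workshop node and ripple-edge tables, expands
    abbreviated labels through an alias map, identifies and merges duplicate
    nodes across workshops, applies verified dates, excludes undatable nodes
    together with the ripple segments they disconnect, and merges the
    surviving ripples into one time-binned directed graph. Summary analytics
    cover the node accounting chain, ripple-membership influence rankings,
    logic-model tallies and cross-site ripples. The meta-map is exported as
    Graphviz DOT with date-aligned ranks and as JSON for interactive viewers.
    A seeded synthetic-workshop generator with planted ground truth makes the
    whole pipeline testable without access to any workshop data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
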