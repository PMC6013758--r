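Package: contourgraph
Title: Set-Annotated Network Visualization with Contour Overlays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Renders small set-annotated graphs as node-link diagrams with
    rounded contours drawn around overlapping node groups, in the style of
    set-oriented subnetwork visualization tools used for enriched gene-set
    and community analysis.  Layout is computed by stress majorization over
    graph-theoretic distances; spanning graphs of selected groups are folded
    into the distance computation to pull group members together, and the
    same spanning graphs form the skeletons of the group contours.  Node
    glyphs are displaced so labels never overlap.  Networks are read from
    tab-separated edge lists, SIF or GML; typed node and group annotation
    tables use a compact s/f/sl column dialect with pipe-separated
    membership lists.  Scenes are exported as SVG.  A scriptable command
    layer replays published automation workflows, and a synthetic fixture
    generator produces annotated graphs for testing.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    xml2,
    jsonlite,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
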