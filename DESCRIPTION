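Package: somset
Title: Unified Self-Organizing-Map Layout of Set-Annotated Network Modules
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Lays out small annotated network modules (genes, interactions and
    overlapping annotation sets) with a reservation-based self-organizing map
    that treats binary interactions and n-ary annotation sets as components of
    one membership vector space. The trained neuron field yields Euler-diagram
    style contours for each active set, refined by morphological (Minkowski)
    smoothing into nested, ribboned shapes, and the result is rendered as a
    deterministic static SVG with a significance overview pane. Includes
    readers and writers for TSV node tables, SIF interaction lists and GMT set
    memberships, a seeded generator of synthetic modules with realistic
    enrichment characteristics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    polyclip,
    jsonlite,
    RColorBrewer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
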