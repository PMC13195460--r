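Package: tpnet
Title: Transformation-Product Reaction Networks for Suspect Screening
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds and queries directed reaction networks of chemical
    transformation products (TPs) compiled from community datasets.
    Reads predecessor/successor reaction tables and compound tables in
    the "Transformations in PubChem" CSV schemas, applies chemistry-aware
    name normalization with majority-vote display naming, assembles a
    directed multigraph of compounds and reactions, and answers
    shortest-pathway, neighborhood, identifier and SMARTS substructure
    queries under a configurable small-precursor/large-product display
    filter. Computes the full statistics suite (node roles, hub
    compounds, per-dataset reaction-pair uniqueness, mass-difference
    distributions, multistep pathway counts) and exports suspect lists
    in MetFrag and patRoon formats. Includes a deterministic synthetic
    table generator for testing and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stringi,
    stats,
    tools,
    utils,
    ChemmineOB
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
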