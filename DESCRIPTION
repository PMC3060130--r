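Package: cytostd
Title: Flow Cytometry Data Standards: FCS, Gating-ML, CLR and ACS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A coherent implementation of the family of open flow cytometry
    data standards: reading and writing FCS 3.1 list-mode data files (FCS
    2.0/3.0 readable), parametrized scale transformations (linear, log,
    inverse hyperbolic sine, logicle, hyperlog), fluorescence spillover
    compensation, an XML gate-description dialect with a vectorized
    evaluation engine for rectangle, polygon, ellipsoid and Boolean gates in
    a hierarchy, per-event fuzzy Classification Results (CLR) tables in CSV,
    and Archival Cytometry Standard (ACS) ZIP containers with an XML table
    of contents, relations and checksum-based integrity.  Includes a seeded
    generator of PBMC-like synthetic datasets and an end-to-end pipeline
    (preprocessing, manual-style gating, mixture-model clustering, cluster
    matching and comparison) that assembles a complete example container.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    xml2,
    mclust,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
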