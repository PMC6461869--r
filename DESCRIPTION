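Package: tolgrad
Title: Community-Level Salt and pH Tolerance Along Environmental Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies community-level distributions of salt and pH
    tolerance from dose-response growth assays of soil bacterial
    communities, links shifts in these trait distributions to shifts in
    16S-derived community composition, and screens for bioindicator taxa.
    Fits single- and double-logistic dose-response models to
    leucine-incorporation growth data to extract the community trait
    indicators logIC50 (salt tolerance) and pH_opt (pH tolerance);
    provides OTU-table preparation (depth filtering, rarefaction,
    rare-taxon removal), Hellinger/Bray-Curtis compositional analysis,
    distance-based redundancy analysis and Mantel tests linking trait and
    composition spaces, and a Spearman-correlation screen for indicator
    OTUs. Includes a niche-based simulator of microbial communities along
    salinity and pH gradients with known ground truth, and a reproducible
    end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    vegan,
    car,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
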