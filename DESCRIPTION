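Package: pairnet
Title: Cross-Domain Co-Occurrence Networks from Paired Amplicon Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for paired marker-gene amplicon surveys
    (e.g. a eukaryote 18S view and a fungal LSU view over the same
    samples): ASV table filtering, alpha and beta diversity with
    PERMANOVA, SparCC compositional correlation inference, topological
    overlap module detection with dynamic tree cut, module eigenprofiles
    and membership, and a cross-domain ASV-pair association score linking
    putative fungal parasites to their algal hosts. Includes a synthetic
    paired-data generator with planted modules and cross-view coupling
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    withr
Config/testthat/edition: 3
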