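Package: phoscoreg
Title: Phosphosite-Centric Co-Regulation Analysis of Curated Phosphoproteomic Catalogs
Version: 0.1.0
Authors@R: person("phoscoreg", "maintainers", email = "maintainers@phoscoreg.dev", role = c("aut", "cre"))
Description: Tools for meta-analysis of curated phosphoproteomic dataset catalogs:
    Class-1 phosphosite confidence filtering, fold-change/p-value regulation calls,
    predominant-phosphosite ranking, within-protein phosphosite co-occurrence,
    Fisher's-exact-test based identification of phosphosites in other proteins
    (PsOPs) co-regulated with an anchor site, kinase substrate motif scanning in
    +/-7 sequence windows, and overlay of interactor/substrate annotations into an
    exportable anchor-centric phospho-signalling network. Includes a synthetic-data
    generator with planted ground truth for end-to-end benchmarking and a
    pipeline/CLI orchestrating all stages with a reproducible run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
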