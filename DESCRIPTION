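Package: hepascreen
Title: Reporter-Cell High-Content Screening Analysis with Metabolic
    Activation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of fluorescence reporter-cell
    high-content screens for hepatotoxicity pathway profiling. Simulates
    96-well screening plates (well tables and synthetic microscopy
    fields) for four transcription-factor reporter lines (AP1, P53,
    Nrf2, NF-kB) with and without S9 metabolic activation; quantifies
    nuclei, GFP-positive and live cells from three-channel images;
    normalizes treated wells against on-plate positive and negative
    controls; assigns the four-tier pathway activity score; sums scores
    into per-condition hazard calls; classifies compounds by
    S9-dependence; and reports clustered score heatmaps and four-set
    Venn summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    pheatmap,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
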