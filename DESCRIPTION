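Package: oserve
Title: Organ-Specific Expression and Repression Across Vertebrate Ortholog Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and evolutionary analysis of organ-specifically
    expressed or repressed (OSER) orthologous gene clusters across nine
    vertebrate species and six organs. Implements RPKM computation,
    log2/Z-score normalization and expression-rank binning; assembly of
    template-anchored orthologous gene clusters from pairwise homology
    tables; a two-stage OSER caller (one-way ANOVA with Tukey HSD on
    Z-scores, then a 50 percent expression-ratio filter on RPKM, with a
    nervous-tissue rule for brain plus cerebellum); gene-family
    construction over a fourteen-species homology graph with
    phylostratigraphic origin assignment and duplication counting;
    evolutionary-rate estimation as total phylogenetic branch length of
    one-to-one clusters; ChIP peak-to-gene assignment at the 2.5 kb
    proximal/distal boundary with cross-species binding overlap; and a
    synthetic-data generator with known ground truth for end-to-end
    validation of every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    data.table,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
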