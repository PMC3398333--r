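Package: dgexact
Title: Exact Digital Gene Expression Testing and Ripening Expression Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Downstream analysis of tag-count (digital gene expression)
    transcriptome data without biological replicates: RPKM normalization,
    an exact two-library test for differential expression with
    Benjamini-Hochberg false discovery rate screening, sign-quadrant
    ripening-profile classification, Pearson-correlation / Mutual-Rank
    co-expression networks with top-k neighbor retention, KEGG-Orthology
    family-level pathway aggregation with magnitude and regulation coloring,
    and the CIRG color index from CIELAB colorimetry. Includes a
    synthetic-data module that plants known differential-expression
    structure so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
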